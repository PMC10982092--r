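#' Gene length in bits
#'
#' A gene encodes one parameter-covariate pair with `n_options` possible
#' states (option 0 = "not included", options 1..n-1 = the allowed
#' relationship types), so it needs `ceiling(log2(n_options))` bits: 1 bit
#' for a categorical pair (absent/linear), up to 3 bits for a continuous
#' pair testing all four relationship types plus absence.
#'
#' @param n_options Number of states of the pair, at least 2.
#' @return Integer number of bits.
#' @export
#' @examples
#' gene_length(2) # categorical: 1 bit
#' gene_length(5) # absent + 4 relationship types: 3 bits
gene_length <- function(n_options) {
  if (length(n_options) != 1L || is.na(n_options) || n_options < 2) {
    abort("`n_options` must be >= 2: a pair testing no relationship is meaningless.")
  }
  as.integer(ceiling(log2(as.numeric(n_options))))
}

#' Total chromosome length of a search space
#'
#' @param space A [search_space()].
#' @return Integer number of bits, the sum of per-pair gene lengths.
#' @export
chromosome_length <- function(space) {
  stopifnot(inherits(space, "cov_search_space"))
  space$l_chr
}

# ---- bit/gene helpers -------------------------------------------------------
# Chromosomes are plain integer vectors of 0/1, big-endian within each gene.

bits_to_int <- function(bits) {
  as.integer(sum(bits * 2 ^ (rev(seq_along(bits)) - 1)))
}

int_to_bits <- function(value, width) {
  as.integer(rev(as.integer(intToBits(value))[seq_len(width)]))
}

gene_values <- function(chrom, space) {
  p <- space$pairs
  vapply(seq_len(nrow(p)), function(i) {
    bits_to_int(chrom[(p$offset[i] + 1L):(p$offset[i] + p$gene_length[i])])
  }, integer(1))
}

set_gene <- function(chrom, space, i, value) {
  p <- space$pairs
  idx <- (p$offset[i] + 1L):(p$offset[i] + p$gene_length[i])
  chrom[idx] <- int_to_bits(value, p$gene_length[i])
  chrom
}

#' @rdname decode_chromosome
#' @export
chrom_to_string <- function(chrom) paste(chrom, collapse = "")

#' @rdname decode_chromosome
#' @param string A string of '0'/'1' characters.
#' @export
chrom_from_string <- function(string) {
  as.integer(strsplit(string, "")[[1]])
}

#' Decode a chromosome into a covariate model
#'
#' Each gene's binary value selects an option for its pair: 0 means the pair
#' is not included; value `k >= 1` selects the k-th allowed relationship in
#' the pair's declared order. All genes must be coding (value `< n_options`);
#' apply [repair_chromosome()] first after crossover/mutation.
#'
#' @param chrom Integer 0/1 vector of length `space$l_chr`.
#' @param space A [search_space()].
#' @return A tibble of class `cov_model_spec` with columns `parameter`,
#'   `covariate`, `relationship` (the phenotype; zero rows for the base
#'   model).
#' @export
#' @examples
#' sp <- search_space("CL", list(covariate_def("WT", "continuous")))
#' decode_chromosome(c(0L, 0L, 1L), sp)
decode_chromosome <- function(chrom, space) {
  stopifnot(inherits(space, "cov_search_space"))
  if (length(chrom) != space$l_chr) {
    abort(sprintf("chromosome length %d does not match space (l_chr = %d)",
                  length(chrom), space$l_chr))
  }
  vals <- gene_values(chrom, space)
  if (any(vals >= space$pairs$n_options)) {
    abort("chromosome has non-coding genes; run repair_chromosome() first")
  }
  inc <- which(vals > 0L)
  spec <- tibble::tibble(
    parameter = space$pairs$parameter[inc],
    covariate = space$pairs$covariate[inc],
    relationship = vapply(inc, function(i) {
      space$pairs$relationships[[i]][vals[i]]
    }, character(1))
  )
  class(spec) <- c("cov_model_spec", class(spec))
  spec
}

#' Encode a covariate model as a chromosome
#'
#' Inverse of [decode_chromosome()]: builds the canonical bit string whose
#' genes select exactly the given (parameter, covariate, relationship)
#' triples.
#'
#' @param spec A `cov_model_spec` tibble (or any data frame with columns
#'   `parameter`, `covariate`, `relationship`).
#' @param space A [search_space()].
#' @return Integer 0/1 vector of length `space$l_chr`.
#' @export
encode_spec <- function(spec, space) {
  stopifnot(inherits(space, "cov_search_space"))
  chrom <- integer(space$l_chr)
  if (nrow(spec) == 0L) return(chrom)
  for (r in seq_len(nrow(spec))) {
    i <- which(space$pairs$parameter == spec$parameter[r] &
                 space$pairs$covariate == spec$covariate[r])
    if (length(i) != 1L) {
      abort(sprintf("pair %s-%s is not in the search space",
                    spec$parameter[r], spec$covariate[r]))
    }
    k <- match(spec$relationship[r], space$pairs$relationships[[i]])
    if (is.na(k)) {
      abort(sprintf("relationship '%s' not allowed for pair %s-%s",
                    spec$relationship[r], spec$parameter[r], spec$covariate[r]))
    }
    chrom <- set_gene(chrom, space, i, k)
  }
  chrom
}

#' Repair non-coding genes
#'
#' Gene values `>= n_options` do not encode any relationship (they can arise
#' from crossover and mutation, since gene widths are rounded up to whole
#' bits). Each such gene is replaced by the modal value of that gene position
#' among the elite chromosomes of the prior generation (ties broken toward
#' the lowest binary value); when no elite exists yet (initialization), a
#' uniformly random coding value is drawn. Coding genes are never touched.
#'
#' @param chrom Integer 0/1 vector.
#' @param space A [search_space()].
#' @param elite List of coding chromosomes (possibly empty) from the prior
#'   generation's elite set.
#' @return A fully coding chromosome.
#' @export
repair_chromosome <- function(chrom, space, elite = list()) {
  vals <- gene_values(chrom, space)
  bad <- which(vals >= space$pairs$n_options)
  if (length(bad) == 0L) return(chrom)
  elite_vals <- if (length(elite)) {
    do.call(rbind, lapply(elite, gene_values, space = space))
  }
  for (i in bad) {
    n_opt <- space$pairs$n_options[i]
    if (!is.null(elite_vals)) {
      tab <- tabulate(elite_vals[, i] + 1L, nbins = n_opt)
      new_val <- which.max(tab) - 1L # which.max takes the first (lowest) mode
    } else {
      new_val <- sample.int(n_opt, 1L) - 1L
    }
    chrom <- set_gene(chrom, space, i, new_val)
  }
  chrom
}

#' Draw a random coding chromosome
#'
#' Samples each gene uniformly over its coding values, so initialization is
#' unbiased over phenotypes and needs no repair.
#'
#' @param space A [search_space()].
#' @return Integer 0/1 vector of length `space$l_chr`.
#' @export
random_chromosome <- function(space) {
  chrom <- integer(space$l_chr)
  for (i in seq_len(nrow(space$pairs))) {
    chrom <- set_gene(chrom, space, i,
                      sample.int(space$pairs$n_options[i], 1L) - 1L)
  }
  chrom
}

# All coding chromosomes of a space (exhaustive enumeration; small spaces
# only -- used by brute-force verification).
enumerate_coding_chromosomes <- function(space) {
  grids <- lapply(space$pairs$n_options, function(n) 0:(n - 1L))
  combos <- do.call(expand.grid, grids)
  lapply(seq_len(nrow(combos)), function(r) {
    chrom <- integer(space$l_chr)
    for (i in seq_along(grids)) {
      chrom <- set_gene(chrom, space, i, combos[r, i])
    }
    chrom
  })
}
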