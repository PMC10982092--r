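#' Jaccard distance between two binary vectors
#'
#' `Jd(i, j) = (b + c) / (a + b + c)` where `a` counts positions set in
#' both vectors, `b` positions set only in `j`, and `c` positions set only
#' in `i`. Two all-zero vectors have distance 0 by convention.
#'
#' @param i,j Equal-length 0/1 integer vectors.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(0, 1, 1, 0))
jaccard_distance <- function(i, j) {
  if (length(i) != length(j)) abort("vectors have different lengths")
  a <- sum(i == 1L & j == 1L)
  b <- sum(i == 0L & j == 1L)
  cc <- sum(i == 1L & j == 0L)
  if (a + b + cc == 0) return(0)
  (b + cc) / (a + b + cc)
}

# full pairwise Jaccard distance matrix, vectorized via cross-products
jaccard_matrix <- function(chroms) {
  m <- do.call(rbind, chroms)
  ones <- rowSums(m)
  a <- tcrossprod(m)                     # shared 1s
  union <- outer(ones, ones, "+") - a    # a + b + c
  d <- ifelse(union == 0, 0, 1 - a / union)
  diag(d) <- 0
  d
}

#' Clustered initial population
#'
#' Maximizes the heterogeneity of the starting population: draw
#' `oversample_factor * n_chr` random coding chromosomes, deduplicate,
#' compute their Jaccard distance matrix, cluster them agglomeratively
#' (average linkage), cut the dendrogram at `n_chr` clusters and draw one
#' chromosome at random from each cluster. If fewer than `n_chr` distinct
#' candidates exist the population is topped up with fresh random coding
#' chromosomes (with a warning).
#'
#' @param space A [search_space()].
#' @param n_chr Population size (>= 2).
#' @param oversample_factor Candidates per slot (default 20).
#' @param method `"cluster"` (default) or `"random"` for a plain random
#'   initial population of the same size (used for comparison).
#' @return List of `n_chr` coding chromosomes.
#' @export
initial_population <- function(space, n_chr, oversample_factor = 20L,
                               method = c("cluster", "random")) {
  method <- match.arg(method)
  if (n_chr < 2L) abort("`n_chr` must be >= 2")
  if (method == "random") {
    return(lapply(seq_len(n_chr), function(k) random_chromosome(space)))
  }
  n_cand <- oversample_factor * n_chr
  cand <- lapply(seq_len(n_cand), function(k) random_chromosome(space))
  cand <- unique(cand)
  if (length(cand) < n_chr) {
    warn(sprintf(
      "only %d distinct candidates for %d slots; topping up with random chromosomes",
      length(cand), n_chr))
    extra <- n_chr - length(cand)
    pop <- c(cand, lapply(seq_len(extra), function(k) random_chromosome(space)))
    return(pop)
  }
  d <- jaccard_matrix(cand)
  hc <- hclust(stats::as.dist(d), method = "average")
  members <- cutree(hc, k = n_chr)
  pop <- lapply(seq_len(n_chr), function(cl) {
    in_cl <- which(members == cl)
    cand[[in_cl[sample.int(length(in_cl), 1L)]]]
  })
  pop
}
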