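#' Tournament selection
#'
#' Two members are sampled uniformly with replacement; with probability `p_s`
#' the one with the higher fitness wins the tournament, otherwise the other
#' is selected. Fitness ties are resolved by a fair coin.
#'
#' @param population List of chromosomes (integer 0/1 vectors).
#' @param fitnesses Numeric vector of fitness values, same length.
#' @param p_s Selection pressure in `[0, 1]`.
#' @return The selected chromosome.
#' @export
tournament_select <- function(population, fitnesses, p_s) {
  n <- length(population)
  if (n == 0L) abort("empty population")
  idx <- sample.int(n, 2L, replace = TRUE)
  fa <- fitnesses[idx[1]]; fb <- fitnesses[idx[2]]
  if (fa == fb) {
    better <- idx[sample.int(2L, 1L)]
    worse <- better
  } else if (fa > fb) {
    better <- idx[1]; worse <- idx[2]
  } else {
    better <- idx[2]; worse <- idx[1]
  }
  winner <- if (runif(1) < p_s) better else worse
  population[[winner]]
}

#' Build the mating pool
#'
#' Runs `n_chr / 2` tournaments per parent slot, returning `n_chr / 2`
#' parent pairs (so the offspring generation has the same size as the
#' current one).
#'
#' @inheritParams tournament_select
#' @return List of length `n_chr / 2`; each element a list of two parents.
#' @export
make_mating_pool <- function(population, fitnesses, p_s) {
  n <- length(population)
  stopifnot(n %% 2L == 0L)
  lapply(seq_len(n %/% 2L), function(i) {
    list(tournament_select(population, fitnesses, p_s),
         tournament_select(population, fitnesses, p_s))
  })
}

#' Single-point crossover
#'
#' With probability `p_c` the two parents are cut at a single random
#' position (excluding the endpoints, so recombination is non-trivial) and
#' their tails exchanged; otherwise the children are copies of the parents.
#'
#' @param parent_a,parent_b Equal-length chromosomes.
#' @param p_c Crossover probability.
#' @return List of two children.
#' @export
crossover <- function(parent_a, parent_b, p_c) {
  l <- length(parent_a)
  if (length(parent_b) != l) abort("parents have different lengths")
  if (runif(1) >= p_c || l < 2L) {
    return(list(parent_a, parent_b))
  }
  k <- sample.int(l - 1L, 1L) # cut after position k, k in 1..l-1
  list(
    c(parent_a[seq_len(k)], parent_b[(k + 1L):l]),
    c(parent_b[seq_len(k)], parent_a[(k + 1L):l])
  )
}

#' Single-bit inversion mutation
#'
#' Each bit flips independently with probability `p_m`.
#'
#' @param chrom Chromosome.
#' @param p_m Per-bit mutation probability.
#' @return Mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, p_m) {
  flip <- runif(length(chrom)) < p_m
  chrom[flip] <- 1L - chrom[flip]
  chrom
}

#' Elitism
#'
#' Copies the top `round(elite_frac * n_chr)` chromosomes of the evaluated
#' previous generation verbatim into the offspring, replacing the offspring
#' slots in order (a deterministic choice; the offspring are unevaluated, so
#' no slot is "worse" than another yet). Population size is preserved.
#'
#' @param prev_population List of evaluated chromosomes.
#' @param prev_fitnesses Their fitness values.
#' @param offspring List of new chromosomes (same length).
#' @param elite_frac Fraction preserved, in `[0, 1)`.
#' @return List of chromosomes, same length as `offspring`.
#' @export
apply_elitism <- function(prev_population, prev_fitnesses, offspring,
                          elite_frac) {
  n <- length(offspring)
  n_elite <- round(elite_frac * length(prev_population))
  if (n_elite == 0L) return(offspring)
  elite_idx <- order(prev_fitnesses, decreasing = TRUE)[seq_len(n_elite)]
  for (k in seq_len(n_elite)) {
    offspring[[k]] <- prev_population[[elite_idx[k]]]
  }
  offspring
}

# the elite set (chromosomes only), used both by elitism and by gene repair
elite_set <- function(population, fitnesses, elite_frac) {
  n_elite <- round(elite_frac * length(population))
  if (n_elite == 0L) return(list())
  population[order(fitnesses, decreasing = TRUE)[seq_len(n_elite)]]
}
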