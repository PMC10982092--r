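test_that("per-generation fitness statistics use n-1 variance", {
  s <- fitness_statistics(c(1, 1, 1))
  expect_equal(unlist(s), c(mean = 1, range = 0, variance = 0, sd = 0))
  s2 <- fitness_statistics(c(0, 2))
  expect_equal(unlist(s2), c(mean = 1, range = 2, variance = 2, sd = sqrt(2)))
  expect_equal(unlist(fitness_statistics(5)),
               c(mean = 5, range = 0, variance = 0, sd = 0))
  expect_error(fitness_statistics(numeric()), "no fitness")
})

test_that("duplicate chromosomes trigger zero re-evaluations", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  cb <- counting_backend(oracle_backend(target, sp))
  cache <- new.env(parent = emptyenv())
  set.seed(61)
  pop <- c(rep(list(integer(14)), 3),
           lapply(1:3, function(i) random_chromosome(sp)))
  evals <- evaluate_population(pop, sp, cb$fn, cache)
  distinct <- length(unique(vapply(pop, chrom_to_string, character(1))))
  expect_equal(cb$calls$n, distinct)
  # re-evaluating the same population costs nothing further
  evals2 <- evaluate_population(pop, sp, cb$fn, cache)
  expect_equal(cb$calls$n, distinct)
  expect_equal(vapply(evals2, `[[`, numeric(1), "fitness"),
               vapply(evals, `[[`, numeric(1), "fitness"))
})

test_that("backend crashes on one chromosome do not stop evaluation", {
  sp <- worked_space()
  boom <- function(spec, budget = Inf, key = NULL) {
    if (nrow(spec) == 0) stop("estimator exploded")
    list(ofv = -nrow(spec), converged = TRUE, status = "converged",
         runtime = 1, n_theta = 2L)
  }
  cache <- new.env(parent = emptyenv())
  set.seed(62)
  pop <- list(integer(14), random_chromosome(sp))
  evals <- evaluate_population(pop, sp, boom, cache)
  expect_equal(evals[[1]]$status, "failed")
  expect_false(evals[[1]]$converged)
})

test_that("timeout is inactive before generation 2 and uses the 95th percentile", {
  sp <- worked_space()
  sb <- scripted_backend(sp)
  hyper <- ga_hyperparams(n_chr = 8, n_generations = 4, seed = 7,
                          p_m = 0.05)
  res <- run_ga(sp, hyper, sb$fn, dataset = NULL)
  hist <- res$history
  expect_equal(hist$timeout_budget[hist$generation <= 1], c(Inf, Inf))
  # from generation 2 the budget equals the 95th percentile of converged
  # runtimes of all earlier generations
  lt <- res$lookup
  for (g in 2:4) {
    conv <- lt[lt$status == "converged" & lt$generation < g, ]
    expect_equal(hist$timeout_budget[hist$generation == g],
                 unname(quantile(conv$runtime, 0.95)))
  }
  # every timed-out model exceeded the generation budget it ran under
  to <- lt[lt$status == "timeout", ]
  if (nrow(to)) {
    bud <- hist$timeout_budget[match(to$generation, hist$generation)]
    expect_true(all(is.na(to$fitness)))
    expect_true(all(bud < Inf))
  }
})

test_that("sentinel fitness sits strictly below every converged fitness", {
  sp <- worked_space()
  sb <- scripted_backend(sp, fail_pair = c("p1", "c1"))
  hyper <- ga_hyperparams(n_chr = 8, n_generations = 3, seed = 8, p_m = 0.05)
  res <- run_ga(sp, hyper, sb$fn, dataset = NULL)
  conv <- res$lookup$fitness[res$lookup$status == "converged"]
  sentinel <- min(conv) - 1000
  # failed models never enter the best-ever solution
  expect_equal(res$best_key %in%
                 res$lookup$chromosome[res$lookup$status == "converged"], TRUE)
  expect_true(all(sentinel < conv))
})

test_that("the GA with the oracle backend finds the enumerated global optimum", {
  sp <- worked_space()
  target <- tibble::tibble(
    parameter = c("p1", "p1", "p2"),
    covariate = c("c1", "c3", "c2"),
    relationship = c("exponential", "linear", "power"))
  backend <- oracle_backend(target, sp)

  # brute force over every phenotype (covers all 2^14 bitstrings after repair)
  all_coding <- gacovsel:::enumerate_coding_chromosomes(sp)
  fits <- vapply(all_coding, function(ch) {
    spec <- decode_chromosome(ch, sp)
    fitness(backend(spec), spec, covariates = sp$covariates)$fitness
  }, numeric(1))
  best_idx <- which.max(fits)
  expect_equal(length(all_coding), 2500L)
  # optimum is unique and is the target phenotype
  expect_lt(max(fits[-best_idx]), fits[best_idx])
  best_spec <- decode_chromosome(all_coding[[best_idx]], sp)
  expect_equal(dplyr::arrange(tibble::as_tibble(best_spec), parameter, covariate),
               dplyr::arrange(tibble::as_tibble(target), parameter, covariate))

  hyper <- ga_hyperparams(n_chr = 16, n_generations = 25, seed = 123)
  res <- run_ga(sp, hyper, backend, dataset = NULL)
  expect_equal(res$best_fitness, fits[best_idx])
  expect_identical(chrom_from_string(res$best_key), all_coding[[best_idx]])
})

test_that("d = 0 returns the best of the initial population", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  backend <- oracle_backend(target, sp)
  hyper <- ga_hyperparams(n_chr = 8, n_generations = 0, seed = 5)
  res <- run_ga(sp, hyper, backend, dataset = NULL)
  expect_equal(nrow(res$history), 1L)
  expect_equal(res$history$generation, 0L)
  expect_equal(res$best_fitness, max(res$lookup$fitness, na.rm = TRUE))
})

test_that("best-ever fitness is non-decreasing and runs are reproducible", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  backend <- oracle_backend(target, sp)
  hyper <- ga_hyperparams(n_chr = 10, n_generations = 10, seed = 99)
  r1 <- run_ga(sp, hyper, backend, dataset = NULL)
  r2 <- run_ga(sp, hyper, backend, dataset = NULL)
  expect_true(all(diff(r1$history$best_ever) >= 0))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$lookup, r2$lookup)
  expect_identical(r1$best_key, r2$best_key)
})

test_that("worker count does not change results with a deterministic backend", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  backend <- oracle_backend(target, sp)
  h1 <- ga_hyperparams(n_chr = 8, n_generations = 5, seed = 42, n_workers = 1)
  h2 <- ga_hyperparams(n_chr = 8, n_generations = 5, seed = 42, n_workers = 2)
  r1 <- run_ga(sp, h1, backend, dataset = NULL)
  r2 <- run_ga(sp, h2, backend, dataset = NULL)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$lookup, r2$lookup)
})

test_that("a persisted run resumes with extended generations", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  backend <- oracle_backend(target, sp)
  out <- tempfile("garun")
  h <- ga_hyperparams(n_chr = 8, n_generations = 3, seed = 17)
  r1 <- run_ga(sp, h, backend, dataset = NULL, out_dir = out)
  expect_true(file.exists(file.path(out, "generation_stats.csv")))
  expect_true(file.exists(file.path(out, "lookup.csv")))
  r2 <- run_ga_resume(out, backend, extra_generations = 4)
  expect_equal(max(r2$history$generation), 7L)
  # resumed history extends the original run
  expect_identical(r2$history[1:4, ], r1$history)
  expect_gte(r2$best_fitness, r1$best_fitness)
})

test_that("cache size equals distinct chromosomes over a whole run", {
  sp <- worked_space()
  target <- decode_chromosome(chrom_from_string("00100010100000"), sp)
  cb <- counting_backend(oracle_backend(target, sp))
  hyper <- ga_hyperparams(n_chr = 10, n_generations = 8, seed = 31)
  res <- run_ga(sp, hyper, cb$fn, dataset = NULL)
  expect_equal(cb$calls$n, nrow(res$lookup))
  expect_equal(anyDuplicated(res$lookup$chromosome), 0L)
})
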