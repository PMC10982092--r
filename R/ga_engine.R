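#' Per-generation fitness statistics
#'
#' @param values Non-empty numeric vector of fitness values.
#' @return Named list `mean`, `range` (max - min), `variance` (denominator
#'   `n - 1`; 0 for a single value), `sd`.
#' @export
fitness_statistics <- function(values) {
  if (length(values) == 0L) abort("no fitness values")
  v <- if (length(values) > 1L) var(values) else 0
  list(mean = mean(values), range = max(values) - min(values),
       variance = v, sd = sqrt(v))
}

#' Evaluate a population through a backend with caching
#'
#' Distinct chromosomes are evaluated once per run: the evaluated-model
#' lookup table (`cache`) is consulted by bitstring key and duplicates reuse
#' the stored result. New models are dispatched to the backend (optionally
#' in parallel; results are independent of evaluation order because backends
#' are seeded per chromosome). Backend errors on a chromosome are recorded
#' as non-convergence. Models whose runtime budget is exceeded carry status
#' `"timeout"`. Fitness is attached by [run_ga()], which knows the run-level
#' sentinel for unconverged models.
#'
#' @param population List of coding chromosomes.
#' @param space The [search_space()].
#' @param backend Backend function `f(spec, budget, key)`.
#' @param cache Environment keyed by bitstring (created by [run_ga()]).
#' @param budget Runtime budget forwarded to the backend (`Inf` = no
#'   timeout).
#' @param covariate_table Per-subject covariates for the correlation
#'   penalty, or `NULL`.
#' @param weight Fitness penalty weight (default 3.84).
#' @param n_workers Parallel workers for new evaluations.
#' @param generation Generation index recorded for new cache entries.
#' @return List (one element per member) of evaluation records: `key`,
#'   `converged`, `fitness` (NA when unconverged), `ofv`, `n_c`, `ic`,
#'   `runtime`, `status`, `new` (logical: evaluated now, not a cache hit).
#' @export
evaluate_population <- function(population, space, backend, cache,
                                budget = Inf, covariate_table = NULL,
                                weight = 3.84, n_workers = 1L,
                                generation = 0L) {
  keys <- vapply(population, chrom_to_string, character(1))
  miss <- unique(keys[!vapply(keys, function(k) !is.null(cache[[k]]), logical(1))])

  eval_one <- function(key) {
    chrom <- chrom_from_string(key)
    spec <- decode_chromosome(chrom, space)
    res <- tryCatch(backend(spec, budget = budget, key = key),
                    error = function(e) {
                      list(ofv = NA_real_, converged = FALSE,
                           status = "failed", runtime = 0,
                           n_theta = NA_integer_)
                    })
    fv <- fitness(res, spec, covariate_table, space$covariates, weight)
    list(key = key, converged = fv$converged, fitness = fv$fitness,
         ofv = fv$obj, n_c = fv$n_c, ic = fv$ic,
         runtime = res$runtime %||% 0, status = res$status %||%
           if (fv$converged) "converged" else "failed",
         generation = generation)
  }

  new_entries <- if (n_workers > 1L && length(miss) > 1L) {
    parallel::mclapply(miss, eval_one, mc.cores = n_workers)
  } else {
    lapply(miss, eval_one)
  }
  for (e in new_entries) cache[[e$key]] <- e

  lapply(seq_along(keys), function(i) {
    e <- cache[[keys[i]]]
    e$new <- keys[i] %in% miss && match(keys[i], keys) == i
    e
  })
}

#' Run the genetic algorithm
#'
#' The full search loop: clustered (or random) initialization, fitness
#' evaluation through the backend with the evaluated-model cache, then per
#' generation tournament selection, single-point crossover, single-bit
#' mutation, gene repair against the previous elite, and elitism. From
#' generation 2 onward, models are given a runtime budget equal to the 95th
#' percentile of the runtimes of all previously converged models (updated
#' every generation); models exceeding it, failing, or crashing receive a
#' sentinel fitness 1000 below the worst converged fitness seen in the run.
#' The returned solution is the best-ever evaluated model over the whole
#' search, not merely the last generation's best.
#'
#' @param space A [search_space()].
#' @param hyper A [ga_hyperparams()].
#' @param backend Backend function (see [fo_backend()], [oracle_backend()]).
#' @param dataset Optional `pk_dataset`; supplies the covariate table for
#'   the correlation penalty (`NULL` disables the penalty, e.g. with the
#'   oracle backend).
#' @param weight Fitness penalty weight (default 3.84).
#' @param init_method `"cluster"` (default) or `"random"`.
#' @param out_dir Optional run directory: per-generation statistics and the
#'   lookup table are flushed there as CSV at the end of every generation,
#'   plus a state file enabling [run_ga_resume()].
#' @param verbose Print a line per generation.
#' @return An object of class `ga_fit`: `best_spec`, `best_fitness`,
#'   `best_ofv`, `best_key`, `history` (per-generation statistics tibble),
#'   `lookup` (evaluated-model tibble), `n_backend_calls`, `space`, `hyper`.
#' @export
run_ga <- function(space, hyper, backend, dataset = NULL, weight = 3.84,
                   init_method = "cluster", out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(space, "cov_search_space"),
            inherits(hyper, "ga_hyperparams"))
  set.seed(hyper$seed)
  state <- list(
    space = space, hyper = hyper, weight = weight,
    covariate_table = if (!is.null(dataset)) pk_covariate_table(dataset),
    cache = new.env(parent = emptyenv()),
    history = list(), population = NULL, fitnesses = NULL,
    next_gen = 0L, out_dir = out_dir, verbose = verbose,
    init_method = init_method
  )
  ga_loop(state, backend, end_gen = hyper$n_generations)
}

#' Resume a persisted run with more generations
#'
#' Continues a run started with `run_ga(..., out_dir = )` for
#' `extra_generations` further generations, reusing the persisted
#' population, cache and RNG state.
#'
#' @param out_dir Run directory written by [run_ga()].
#' @param backend The backend function (backends hold data/closures and are
#'   not persisted).
#' @param extra_generations Number of additional generations.
#' @return A `ga_fit` object covering the whole (extended) run.
#' @export
run_ga_resume <- function(out_dir, backend, extra_generations) {
  state_path <- file.path(out_dir, "ga_state.rds")
  if (!file.exists(state_path)) {
    abort(sprintf("no persisted state at '%s'", state_path))
  }
  saved <- readRDS(state_path)
  assign(".Random.seed", saved$random_seed, envir = globalenv())
  state <- saved$state
  state$cache <- list2env(saved$cache_entries, parent = emptyenv())
  state$out_dir <- out_dir
  ga_loop(state, backend, end_gen = state$next_gen - 1L + extra_generations)
}

ga_loop <- function(state, backend, end_gen) {
  hyper <- state$hyper
  space <- state$space

  for (gen in state$next_gen:end_gen) {
    if (gen == 0L) {
      pop <- initial_population(space, hyper$n_chr, hyper$oversample_factor,
                                method = state$init_method)
    } else {
      elite <- elite_set(state$population, state$fitnesses, hyper$elite_frac)
      pool <- make_mating_pool(state$population, state$fitnesses, hyper$p_s)
      offspring <- list()
      for (pair in pool) {
        kids <- crossover(pair[[1]], pair[[2]], hyper$p_c)
        offspring <- c(offspring, lapply(kids, mutate_chromosome, p_m = hyper$p_m))
      }
      offspring <- lapply(offspring, repair_chromosome, space = space,
                          elite = elite)
      pop <- apply_elitism(state$population, state$fitnesses, offspring,
                           hyper$elite_frac)
    }

    budget <- timeout_budget(state$cache, gen)
    evals <- evaluate_population(pop, space, backend, state$cache,
                                 budget = budget,
                                 covariate_table = state$covariate_table,
                                 weight = state$weight,
                                 n_workers = hyper$n_workers,
                                 generation = gen)

    conv_fit <- run_converged_fitnesses(state$cache)
    if (length(conv_fit) == 0L) {
      abort(sprintf("all models failed up to generation %d; check backend/data", gen))
    }
    sentinel <- min(conv_fit) - 1000
    fits <- vapply(evals, function(e) {
      if (e$converged) e$fitness else sentinel
    }, numeric(1))
    if (!any(vapply(evals, `[[`, logical(1), "converged"))) {
      abort(sprintf("all models of generation %d failed", gen))
    }

    st <- fitness_statistics(fits)
    best_ever <- max(conv_fit)
    state$history[[gen + 1L]] <- tibble::tibble(
      generation = gen,
      n_new_evals = sum(vapply(evals, `[[`, logical(1), "new")),
      n_converged = sum(vapply(evals, `[[`, logical(1), "converged")),
      timeout_budget = budget,
      mean = st$mean, range = st$range, variance = st$variance, sd = st$sd,
      best = max(fits), best_ever = best_ever
    )
    state$population <- pop
    state$fitnesses <- fits
    state$next_gen <- gen + 1L
    if (state$verbose) {
      message(sprintf("generation %3d | mean %10.3f | best %10.3f | best-ever %10.3f",
                      gen, st$mean, max(fits), best_ever))
    }
    flush_logs(state)
  }

  ga_result(state)
}

timeout_budget <- function(cache, gen) {
  if (gen < 2L) return(Inf)
  rts <- unlist(eapply(cache, function(e) {
    if (e$converged && e$generation < gen) e$runtime else NULL
  }), use.names = FALSE)
  if (length(rts) == 0L) return(Inf)
  unname(quantile(rts, 0.95))
}

run_converged_fitnesses <- function(cache) {
  unlist(eapply(cache, function(e) if (e$converged) e$fitness else NULL),
         use.names = FALSE)
}

lookup_table <- function(cache) {
  entries <- as.list(cache)
  if (length(entries) == 0L) {
    return(tibble::tibble(chromosome = character(), fitness = numeric(),
                          ofv = numeric(), n_c = integer(), ic = numeric(),
                          runtime = numeric(), status = character(),
                          generation = integer()))
  }
  tb <- tibble::tibble(
    chromosome = unname(vapply(entries, `[[`, character(1), "key")),
    fitness = unname(vapply(entries, `[[`, numeric(1), "fitness")),
    ofv = unname(vapply(entries, `[[`, numeric(1), "ofv")),
    n_c = unname(vapply(entries, function(e) as.integer(e$n_c), integer(1))),
    ic = unname(vapply(entries, `[[`, numeric(1), "ic")),
    runtime = unname(vapply(entries, `[[`, numeric(1), "runtime")),
    status = unname(vapply(entries, `[[`, character(1), "status")),
    generation = unname(vapply(entries, function(e) as.integer(e$generation),
                               integer(1)))
  )
  dplyr::arrange(tb, .data$generation, .data$chromosome)
}

ga_result <- function(state) {
  lt <- lookup_table(state$cache)
  conv <- dplyr::filter(lt, .data$status == "converged")
  if (nrow(conv) == 0L) abort("no converged model in the whole run")
  best <- conv[which.max(conv$fitness), ]
  structure(
    list(
      best_spec = decode_chromosome(chrom_from_string(best$chromosome),
                                    state$space),
      best_key = best$chromosome,
      best_fitness = best$fitness,
      best_ofv = best$ofv,
      history = dplyr::bind_rows(state$history),
      lookup = lt,
      n_backend_calls = nrow(lt),
      space = state$space, hyper = state$hyper
    ),
    class = "ga_fit"
  )
}

flush_logs <- function(state) {
  if (is.null(state$out_dir)) return(invisible())
  dir.create(state$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(dplyr::bind_rows(state$history)),
            file.path(state$out_dir, "generation_stats.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(lookup_table(state$cache)),
            file.path(state$out_dir, "lookup.csv"), row.names = FALSE)
  persist <- state
  persist$cache <- NULL
  saveRDS(list(state = persist, cache_entries = as.list(state$cache),
               random_seed = get(".Random.seed", envir = globalenv())),
          file.path(state$out_dir, "ga_state.rds"))
  invisible()
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> %d generations | %d models evaluated | best fitness %.3f\n",
              max(x$history$generation), x$n_backend_calls, x$best_fitness))
  if (nrow(x$best_spec) == 0L) {
    cat("best model: base model (no covariates)\n")
  } else {
    cat("best model:\n")
    print(tibble::as_tibble(x$best_spec))
  }
  invisible(x)
}
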