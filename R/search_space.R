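#' Declare a candidate covariate
#'
#' A covariate definition fixes the kind (continuous or categorical), the
#' centering reference used by the relationship functions and, for categorical
#' covariates, the category labels. The reference of a continuous covariate
#' defaults to the dataset median at fit time when left `NA`; the reference of
#' a categorical covariate defaults to its most common category.
#'
#' @param name Covariate name (must match a dataset column).
#' @param kind `"continuous"` or `"categorical"`.
#' @param reference Centering value (continuous) or reference category label
#'   (categorical). `NA` means "resolve from the dataset".
#' @param categories Character vector of category labels (categorical only,
#'   at least two).
#' @return An object of class `covariate_def`.
#' @export
#' @examples
#' covariate_def("BMI", "continuous")
#' covariate_def("SEX", "categorical", categories = c("0", "1"))
covariate_def <- function(name, kind = c("continuous", "categorical"),
                          reference = NA, categories = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  if (kind == "continuous") {
    if (!is.null(categories)) {
      abort(sprintf("continuous covariate '%s' must not declare categories", name))
    }
  } else {
    categories <- as.character(categories)
    if (length(categories) < 2L) {
      abort(sprintf("categorical covariate '%s' needs at least 2 categories", name))
    }
    if (anyDuplicated(categories)) {
      abort(sprintf("categorical covariate '%s' has duplicated categories", name))
    }
    if (!is.na(reference) && !as.character(reference) %in% categories) {
      abort(sprintf("reference category '%s' is not a category of '%s'",
                    reference, name))
    }
  }
  structure(
    list(name = name, kind = kind, reference = reference,
         categories = categories),
    class = "covariate_def"
  )
}

#' Build a covariate search space
#'
#' The search space is the ordered grid of parameter-covariate pairs together
#' with the relationship types allowed for each pair. Its pair order is frozen
#' (parameters in declared order, covariates in declared order within each
#' parameter) because it defines the genotype-phenotype map of the GA: gene
#' `k` of every chromosome always refers to pair `k`.
#'
#' Each pair carries `n_options = 1 + length(relationships)`; option 0 is
#' "not included" and options `1..n-1` are the allowed relationships in
#' declared order. Categorical pairs may only use the linear relationship,
#' so they always have two options and occupy one bit.
#'
#' @param parameters Character vector of model parameter names (e.g.
#'   `c("CL", "V")`).
#' @param covariates List of [covariate_def()] objects.
#' @param pairs Optional tibble/data frame with columns `parameter`,
#'   `covariate` and a list-column `relationships`; when omitted every
#'   covariate is tested on every parameter with all relationships allowed
#'   for its kind.
#' @return An object of class `cov_search_space` with a `pairs` tibble
#'   (`parameter`, `covariate`, `relationships`, `n_options`, `gene_length`,
#'   `offset`) and the total chromosome length `l_chr`.
#' @seealso [chromosome_length()], [decode_chromosome()]
#' @export
#' @examples
#' sp <- search_space(
#'   parameters = c("CL", "V"),
#'   covariates = list(
#'     covariate_def("WT", "continuous"),
#'     covariate_def("SEX", "categorical", categories = c("0", "1"))
#'   )
#' )
#' sp$l_chr
search_space <- function(parameters, covariates, pairs = NULL) {
  parameters <- as.character(parameters)
  if (length(parameters) == 0L || anyDuplicated(parameters)) {
    abort("`parameters` must be a non-empty set of unique names.")
  }
  if (!all(vapply(covariates, inherits, logical(1), "covariate_def"))) {
    abort("`covariates` must be a list of covariate_def objects.")
  }
  cov_names <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) abort("duplicated covariate names")
  names(covariates) <- cov_names

  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(parameter = parameters, covariate = cov_names)
    pairs$relationships <- purrr::map(pairs$covariate, function(cv) {
      if (covariates[[cv]]$kind == "continuous") CONTINUOUS_RELATIONSHIPS
      else CATEGORICAL_RELATIONSHIPS
    })
  } else {
    pairs <- tibble::as_tibble(pairs)
  }
  validate_pairs(pairs, parameters, covariates)

  # frozen ordering: declared parameter order, declared covariate order within
  pairs <- pairs[order(match(pairs$parameter, parameters),
                       match(pairs$covariate, cov_names)), ]
  pairs$n_options <- vapply(pairs$relationships, length, integer(1)) + 1L
  pairs$gene_length <- vapply(pairs$n_options, gene_length, integer(1))
  pairs$offset <- c(0L, cumsum(head(pairs$gene_length, -1L)))

  structure(
    list(parameters = parameters, covariates = covariates, pairs = pairs,
         l_chr = sum(pairs$gene_length)),
    class = "cov_search_space"
  )
}

validate_pairs <- function(pairs, parameters, covariates) {
  req <- c("parameter", "covariate", "relationships")
  if (!all(req %in% names(pairs))) {
    abort("`pairs` needs columns parameter, covariate, relationships")
  }
  if (anyDuplicated(pairs[c("parameter", "covariate")])) {
    abort("duplicated parameter-covariate pair")
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$parameter[i]; cv <- pairs$covariate[i]
    rel <- pairs$relationships[[i]]
    if (!p %in% parameters) abort(sprintf("unknown parameter '%s' in pairs", p))
    if (!cv %in% names(covariates)) abort(sprintf("unknown covariate '%s' in pairs", cv))
    if (length(rel) == 0L) {
      abort(sprintf("pair %s-%s allows no relationship; drop the pair instead", p, cv))
    }
    if (anyDuplicated(rel)) abort(sprintf("pair %s-%s lists a relationship twice", p, cv))
    allowed <- if (covariates[[cv]]$kind == "continuous") {
      CONTINUOUS_RELATIONSHIPS
    } else {
      CATEGORICAL_RELATIONSHIPS
    }
    bad <- setdiff(rel, allowed)
    if (length(bad)) {
      abort(sprintf("pair %s-%s: relationship '%s' not allowed for a %s covariate",
                    p, cv, bad[1], covariates[[cv]]$kind))
    }
  }
  invisible(pairs)
}

#' @export
print.cov_search_space <- function(x, ...) {
  cat(sprintf("<cov_search_space> %d parameter(s), %d pair(s), l_chr = %d bits\n",
              length(x$parameters), nrow(x$pairs), x$l_chr))
  df <- x$pairs
  df$relationships <- vapply(df$relationships, paste, character(1), collapse = ",")
  print(tibble::as_tibble(df), n = 20)
  invisible(x)
}

#' GA hyper-parameters
#'
#' Defaults are the values used throughout the simulated evaluation study:
#' selection pressure 0.75, crossover probability 0.7, mutation probability
#' 0.025, 10% elitism, 30 chromosomes, 50 generations, and a 20x oversample
#' when building the clustered initial population.
#'
#' @param p_s Tournament selection pressure in `[0, 1]`.
#' @param p_c Crossover probability in `[0, 1]`.
#' @param p_m Per-bit mutation probability in `[0, 1]`.
#' @param elite_frac Fraction of the population copied unchanged into the
#'   next generation, in `[0, 1)`.
#' @param n_chr Population size; must be even (pairwise mating).
#' @param n_generations Number of generations `d`.
#' @param seed Integer RNG seed for the whole run.
#' @param n_workers Number of parallel workers the engine may use.
#' @param oversample_factor Candidates per population slot drawn before
#'   clustering at initialization.
#' @return A list of class `ga_hyperparams`.
#' @export
ga_hyperparams <- function(p_s = 0.75, p_c = 0.7, p_m = 0.025,
                           elite_frac = 0.10, n_chr = 30L,
                           n_generations = 50L, seed = 1L,
                           n_workers = 1L, oversample_factor = 20L) {
  stopifnot(p_s >= 0, p_s <= 1, p_c >= 0, p_c <= 1, p_m >= 0, p_m <= 1,
            elite_frac >= 0, elite_frac < 1)
  n_chr <- as.integer(n_chr)
  if (n_chr < 2L || n_chr %% 2L != 0L) {
    abort("`n_chr` must be a positive even integer (pairwise mating).")
  }
  n_generations <- as.integer(n_generations)
  if (n_generations < 0L) abort("`n_generations` must be >= 0")
  if (oversample_factor < 1L) abort("`oversample_factor` must be >= 1")
  structure(
    list(p_s = p_s, p_c = p_c, p_m = p_m, elite_frac = elite_frac,
         n_chr = n_chr, n_generations = n_generations, seed = as.integer(seed),
         n_workers = as.integer(n_workers),
         oversample_factor = as.integer(oversample_factor)),
    class = "ga_hyperparams"
  )
}

#' Load a search configuration file
#'
#' Reads a YAML configuration declaring the model parameters, the candidate
#' covariates, optionally an explicit pair table, the GA hyper-parameters and
#' the estimation backend. See the README for the schema; minimally:
#'
#' ```yaml
#' parameters: [CL, V]
#' covariates:
#'   - {name: BMI, kind: continuous}
#'   - {name: SEX, kind: categorical, categories: ["0", "1"]}
#' ga: {n_chr: 30, n_generations: 50, seed: 1}
#' backend: fo
#' ```
#'
#' When `pairs:` is omitted, every covariate is tested on every parameter
#' with every relationship its kind allows.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `space` ([search_space()]), `ga`
#'   ([ga_hyperparams()]) and `backend` (a string).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$parameters) || is.null(cfg$covariates)) {
    abort("config must declare `parameters` and `covariates`")
  }
  covs <- purrr::map(cfg$covariates, function(cv) {
    covariate_def(
      name = cv$name,
      kind = cv$kind %||% "continuous",
      reference = cv$reference %||% NA,
      categories = cv$categories
    )
  })
  pairs <- NULL
  if (!is.null(cfg$pairs)) {
    pairs <- tibble::tibble(
      parameter = vapply(cfg$pairs, `[[`, character(1), "parameter"),
      covariate = vapply(cfg$pairs, `[[`, character(1), "covariate"),
      relationships = purrr::map(cfg$pairs, function(p) {
        unlist(p$relationships)
      })
    )
    known <- c(CONTINUOUS_RELATIONSHIPS, CATEGORICAL_RELATIONSHIPS)
    bad <- setdiff(unique(unlist(pairs$relationships)), known)
    if (length(bad)) {
      abort(sprintf("unknown relationship name '%s' in config", bad[1]))
    }
  }
  space <- search_space(unlist(cfg$parameters), covs, pairs)
  ga <- do.call(ga_hyperparams, cfg$ga %||% list())
  backend <- cfg$backend %||% "fo"
  list(space = space, ga = ga, backend = backend)
}

#' Serialize a search space for provenance
#'
#' Writes (or returns) a JSON description of the frozen pair ordering so a
#' run's genotype-phenotype map can be archived next to its logs; reloading
#' via [space_from_json()] reproduces an identical map.
#'
#' @param space A `cov_search_space`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
space_to_json <- function(space, path = NULL) {
  stopifnot(inherits(space, "cov_search_space"))
  obj <- list(
    parameters = space$parameters,
    covariates = purrr::map(unname(space$covariates), function(cv) {
      list(name = cv$name, kind = cv$kind,
           reference = if (is.na(cv$reference)) NULL else cv$reference,
           categories = cv$categories)
    }),
    pairs = purrr::pmap(
      space$pairs[c("parameter", "covariate", "relationships")],
      function(parameter, covariate, relationships) {
        list(parameter = parameter, covariate = covariate,
             relationships = as.list(relationships))
      }
    )
  )
  json <- jsonlite_write(obj)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# yaml-based stable serialization fallback keeps jsonlite in Suggests
jsonlite_write <- function(obj) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  } else {
    yaml::as.yaml(obj)
  }
}

#' @rdname space_to_json
#' @param json JSON string or path to a JSON file produced by
#'   [space_to_json()].
#' @export
space_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("space_from_json() needs the jsonlite package")
  }
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  covs <- purrr::map(obj$covariates, function(cv) {
    covariate_def(cv$name, cv$kind, cv$reference %||% NA,
                  categories = unlist(cv$categories))
  })
  pairs <- tibble::tibble(
    parameter = vapply(obj$pairs, `[[`, character(1), "parameter"),
    covariate = vapply(obj$pairs, `[[`, character(1), "covariate"),
    relationships = purrr::map(obj$pairs, function(p) unlist(p$relationships))
  )
  search_space(unlist(obj$parameters), covs, pairs)
}
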