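#' Stepwise covariate modeling (SCM) comparator
#'
#' Greedy forward inclusion / backward elimination over the same search
#' space the GA explores. Forward: at each step every not-yet-included
#' (pair, relationship) candidate is fitted on top of the current model, and
#' the one with the largest drop in objective function value is added if
#' that drop exceeds the chi-square critical value at `alpha_fwd` with as
#' many degrees of freedom as the candidate has coefficients. Backward: the
#' included term whose removal raises the OFV the least is removed while
#' that rise stays below the critical value at `alpha_bwd`. A pair carries
#' at most one relationship at a time.
#'
#' `relationship_order` permutes the order in which relationship types are
#' tried and breaks ties among equal-drop candidates (first in order wins),
#' which is exactly the order-dependence the method is known for when many
#' alternative shapes are tested per pair.
#'
#' @param space A [search_space()].
#' @param dataset A `pk_dataset`.
#' @param backend Backend function (e.g. [fo_backend()]).
#' @param alpha_fwd,alpha_bwd Significance thresholds for inclusion
#'   (default 0.05) and retention (default 0.01).
#' @param relationship_order Character permutation of the relationship
#'   names; default the canonical order.
#' @return A list of class `scm_fit`: `final_spec`, `steps` (tibble with
#'   `step`, `direction`, `parameter`, `covariate`, `relationship`,
#'   `delta_ofv`, `df`, `critical`, `accepted`), `base_ofv`, `final_ofv`,
#'   `final_n_theta`.
#' @export
run_scm <- function(space, dataset, backend, alpha_fwd = 0.05,
                    alpha_bwd = 0.01,
                    relationship_order = CONTINUOUS_RELATIONSHIPS) {
  stopifnot(inherits(space, "cov_search_space"))
  rel_rank <- function(rel) match(rel, c(relationship_order, "linear"))

  fit_spec <- function(spec) {
    tryCatch(backend(spec, budget = Inf, key = NULL), error = function(e) NULL)
  }
  current <- empty_spec()
  base_fit <- fit_spec(current)
  if (is.null(base_fit) || !isTRUE(base_fit$converged)) {
    abort("base model failed to fit; SCM cannot start")
  }
  current_ofv <- base_fit$ofv
  steps <- list()
  step_i <- 0L

  candidate_rows <- function(current) {
    used <- paste(current$parameter, current$covariate)
    out <- list()
    for (i in seq_len(nrow(space$pairs))) {
      pr <- space$pairs[i, ]
      if (paste(pr$parameter, pr$covariate) %in% used) next
      rels <- pr$relationships[[1]]
      rels <- rels[order(rel_rank(rels))]
      for (rel in rels) {
        out[[length(out) + 1L]] <- tibble::tibble(
          parameter = pr$parameter, covariate = pr$covariate,
          relationship = rel)
      }
    }
    out
  }

  term_df <- function(row) {
    relationship_theta_count(row$relationship,
                             space$covariates[[row$covariate]]$categories)
  }

  # ---- forward inclusion ----
  repeat {
    cands <- candidate_rows(current)
    if (length(cands) == 0L) break
    best <- NULL
    for (cand in cands) {
      trial <- dplyr::bind_rows(current, cand)
      fit <- fit_spec(trial)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        warn(sprintf("candidate %s-%s (%s) failed; skipped",
                     cand$parameter, cand$covariate, cand$relationship))
        next
      }
      d_ofv <- current_ofv - fit$ofv
      df <- term_df(cand)
      crit <- qchisq(1 - alpha_fwd, df)
      step_i <- step_i + 1L
      steps[[step_i]] <- tibble::tibble(
        step = step_i, direction = "forward", parameter = cand$parameter,
        covariate = cand$covariate, relationship = cand$relationship,
        delta_ofv = d_ofv, df = df, critical = crit,
        accepted = FALSE)
      if (d_ofv > crit &&
          (is.null(best) || d_ofv > best$d_ofv + 1e-12)) {
        best <- list(cand = cand, fit = fit, d_ofv = d_ofv, step = step_i)
      }
    }
    if (is.null(best)) break
    steps[[best$step]]$accepted <- TRUE
    current <- dplyr::bind_rows(current, best$cand)
    current_ofv <- best$fit$ofv
  }

  # ---- backward elimination ----
  repeat {
    if (nrow(current) == 0L) break
    worst <- NULL
    for (r in seq_len(nrow(current))) {
      trial <- current[-r, ]
      fit <- fit_spec(trial)
      if (is.null(fit) || !isTRUE(fit$converged)) next
      rise <- fit$ofv - current_ofv
      df <- term_df(current[r, ])
      crit <- qchisq(1 - alpha_bwd, df)
      if (rise < crit && (is.null(worst) || rise < worst$rise - 1e-12)) {
        worst <- list(r = r, fit = fit, rise = rise, df = df, crit = crit)
      }
    }
    if (is.null(worst)) break
    step_i <- step_i + 1L
    steps[[step_i]] <- tibble::tibble(
      step = step_i, direction = "backward",
      parameter = current$parameter[worst$r],
      covariate = current$covariate[worst$r],
      relationship = current$relationship[worst$r],
      delta_ofv = worst$rise, df = worst$df, critical = worst$crit,
      accepted = TRUE)
    current <- current[-worst$r, ]
    current_ofv <- worst$fit$ofv
  }

  final_fit <- fit_spec(current)
  structure(
    list(final_spec = current,
         steps = dplyr::bind_rows(steps),
         base_ofv = base_fit$ofv,
         final_ofv = final_fit$ofv,
         final_n_theta = final_fit$n_theta),
    class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  cat(sprintf("<scm_fit> base OFV %.3f -> final OFV %.3f | %d term(s)\n",
              x$base_ofv, x$final_ofv, nrow(x$final_spec)))
  if (nrow(x$final_spec)) print(tibble::as_tibble(x$final_spec))
  invisible(x)
}
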