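#' Deterministic oracle backend
#'
#' A test double for verifying the search loop without any estimation: the
#' pseudo objective function value scores a candidate phenotype against a
#' fixed target model, so that the global fitness optimum is exactly (and
#' uniquely) the target. Per search-space pair, a candidate scores
#' `-match_bonus` when it selects the target's option for a pair the target
#' includes, and `+wrong_penalty` when it includes a term the target does
#' not have (or the wrong relationship). With the default weights every
#' deviation from the target strictly worsens fitness even after the
#' chi-square coefficient penalty. Runtime is 0, so the timeout policy never
#' fires.
#'
#' @param target_spec The target `cov_model_spec`.
#' @param space The [search_space()] (must contain every target pair).
#' @param match_bonus,wrong_penalty Positive score weights (defaults 30 and
#'   10).
#' @return A backend function `f(spec, budget, key)` returning an instant,
#'   always-converged fit result.
#' @export
oracle_backend <- function(target_spec, space, match_bonus = 30,
                           wrong_penalty = 10) {
  stopifnot(inherits(space, "cov_search_space"))
  target_key <- spec_pair_key(target_spec)
  # verify target is representable (errors if not)
  invisible(encode_spec(target_spec, space))
  force(match_bonus); force(wrong_penalty)

  function(spec, budget = Inf, key = NULL) {
    cand <- spec_pair_key(spec)
    obj <- 0
    for (pk in names(cand)) {
      if (!is.null(target_key[[pk]]) && identical(cand[[pk]], target_key[[pk]])) {
        obj <- obj - match_bonus
      } else {
        obj <- obj + wrong_penalty
      }
    }
    n_theta <- 2L + theta_count(spec, space$covariates)
    list(ofv = obj, estimates = NULL, converged = TRUE, status = "converged",
         runtime = 0, n_theta = n_theta)
  }
}

spec_pair_key <- function(spec) {
  if (nrow(spec) == 0L) return(structure(list(), names = character()))
  setNames(as.list(spec$relationship),
           paste(spec$parameter, spec$covariate, sep = "\r"))
}
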