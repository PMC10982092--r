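#' Correlation penalty of a covariate model
#'
#' Highly correlated continuous covariates placed on the same parameter are
#' redundant; this penalty sums the absolute pairwise Pearson correlations
#' (across subjects) of the continuous covariates included on each
#' parameter:
#' `ic = 1/2 * sum_k sum_{i != j} |corr_{i,j}|`, i.e. each unordered pair
#' counted once. Categorical covariates and pairs on different parameters
#' contribute nothing. A constant covariate has no defined correlation; its
#' pairs contribute 0 with a warning.
#'
#' @param spec A `cov_model_spec`.
#' @param covariate_table Data frame with one row per subject and one column
#'   per covariate (baseline values).
#' @param covariates Named list of [covariate_def()]s used to identify
#'   continuous covariates; defaults to treating every numeric column as
#'   continuous when `NULL`.
#' @return Non-negative penalty value.
#' @export
#' @examples
#' tab <- data.frame(WT = c(60, 70, 80, 95), BMI = c(20, 23, 26, 31))
#' spec <- tibble::tibble(parameter = "CL", covariate = c("WT", "BMI"),
#'                        relationship = "linear")
#' correlation_penalty(spec, tab)
correlation_penalty <- function(spec, covariate_table, covariates = NULL) {
  if (nrow(spec) == 0L) return(0)
  is_continuous <- function(cv) {
    if (!is.null(covariates)) covariates[[cv]]$kind == "continuous"
    else is.numeric(covariate_table[[cv]])
  }
  ic <- 0
  for (p in unique(spec$parameter)) {
    covs <- spec$covariate[spec$parameter == p]
    covs <- covs[vapply(covs, is_continuous, logical(1))]
    if (length(covs) < 2L) next
    for (i in seq_len(length(covs) - 1L)) {
      for (j in (i + 1L):length(covs)) {
        xi <- covariate_table[[covs[i]]]
        xj <- covariate_table[[covs[j]]]
        if (sd(xi) == 0 || sd(xj) == 0) {
          warn(sprintf("constant covariate in pair (%s, %s); contributes 0",
                       covs[i], covs[j]))
          next
        }
        ic <- ic + abs(cor(xi, xj))
      }
    }
  }
  ic
}

#' GA fitness of an evaluated model
#'
#' For a converged fit the fitness is
#' `fit = -(obj + 3.84 * (N_c + ic))`, where `obj` is the objective function
#' value (-2 log-likelihood scale), `N_c` the number of covariate
#' coefficients of the candidate ([theta_count()]; structural parameters are
#' excluded because they are common to every candidate), `ic` the
#' [correlation_penalty()], and 3.84 the chi-square quantile at significance
#' 0.05 with 1 degree of freedom. Failed or timed-out fits receive a sentinel
#' fitness assigned by the engine, strictly below every converged fitness.
#'
#' @param result A backend fit result (list with at least `ofv` and
#'   `converged`).
#' @param spec The candidate `cov_model_spec`.
#' @param covariate_table Per-subject covariate data (see
#'   [correlation_penalty()]); `NULL` skips the correlation penalty (ic = 0).
#' @param covariates Named list of [covariate_def()]s.
#' @param weight Penalty weight; default 3.84.
#' @return A list of class `fitness_value` with `fitness`, `obj`, `n_c`,
#'   `ic`, `converged`.
#' @export
fitness <- function(result, spec, covariate_table = NULL, covariates = NULL,
                    weight = 3.84) {
  conv <- isTRUE(result$converged)
  n_c <- if (is.null(covariates)) {
    # without defs assume 1 theta per term except piecewise
    if (nrow(spec)) sum(ifelse(spec$relationship == "piecewise_linear", 2L, 1L)) else 0L
  } else {
    theta_count(spec, covariates)
  }
  ic <- if (is.null(covariate_table)) 0 else {
    correlation_penalty(spec, covariate_table, covariates)
  }
  fit <- if (conv) -(result$ofv + weight * (n_c + ic)) else NA_real_
  structure(
    list(fitness = fit, obj = if (conv) result$ofv else NA_real_,
         n_c = n_c, ic = ic, converged = conv),
    class = "fitness_value"
  )
}

#' Akaike information criterion from an objective function value
#'
#' `AIC = OFV + 2 * n_theta`, with `n_theta` the number of fixed-effect
#' parameters (structural plus covariate coefficients).
#'
#' @param ofv Objective function value (-2 log-likelihood scale).
#' @param n_theta Number of fixed-effect parameters, `>= 0`.
#' @return AIC value.
#' @export
#' @examples
#' aic(-6388.597, 2)
aic <- function(ofv, n_theta) {
  stopifnot(is.finite(ofv), n_theta >= 0)
  ofv + 2 * n_theta
}
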