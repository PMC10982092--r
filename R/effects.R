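#' A single parameter-covariate effect term
#'
#' Relationship functions follow the stepwise-covariate-modeling conventions
#' of PsN, centered at a reference value `x_ref` (the dataset median unless
#' overridden):
#' \describe{
#'   \item{linear}{`1 + theta1 * (x - x_ref)`}
#'   \item{exponential}{`exp(theta1 * (x - x_ref))`}
#'   \item{power}{`(x / x_ref)^theta1` (requires `x, x_ref > 0`)}
#'   \item{piecewise_linear}{`1 + theta1 * (x - x_ref)` for `x <= x_ref`,
#'     `1 + theta2 * (x - x_ref)` above it (two coefficients, "hockey
#'     stick"; continuous at the breakpoint)}
#'   \item{categorical linear}{multiplier 1 for the reference category and
#'     `1 + theta_c` for each other category `c` (one coefficient per
#'     non-reference category)}
#' }
#'
#' @param relationship One of `"linear"`, `"exponential"`,
#'   `"piecewise_linear"`, `"power"`.
#' @param theta Numeric coefficient vector; its required length is given by
#'   [relationship_theta_count()].
#' @param reference Centering value (continuous) or reference category
#'   (categorical).
#' @param categories Category labels (categorical terms only); thetas map to
#'   `setdiff(categories, reference)` in order.
#' @return An object of class `effect_term`.
#' @export
#' @examples
#' eff <- effect_term("exponential", theta = 0.232, reference = 25)
#' effect_multiplier(eff, 27)
effect_term <- function(relationship, theta, reference, categories = NULL) {
  n_needed <- relationship_theta_count(relationship, categories)
  if (length(theta) != n_needed) {
    abort(sprintf("relationship '%s' needs %d coefficient(s), got %d",
                  relationship, n_needed, length(theta)))
  }
  structure(
    list(relationship = relationship, theta = as.numeric(theta),
         reference = reference, categories = categories),
    class = "effect_term"
  )
}

#' Coefficients required by a relationship type
#'
#' Linear, exponential and power relationships use one coefficient; the
#' piece-wise linear ("hockey stick") relationship uses two (one slope per
#' side of the breakpoint); a categorical linear relationship uses one
#' coefficient per non-reference category.
#'
#' @param relationship Relationship name.
#' @param categories Category labels for categorical terms, `NULL` otherwise.
#' @return Integer count.
#' @export
relationship_theta_count <- function(relationship, categories = NULL) {
  if (!is.null(categories)) {
    if (relationship != "linear") {
      abort("categorical covariates only support the linear relationship")
    }
    return(length(categories) - 1L)
  }
  switch(relationship,
    linear = 1L, exponential = 1L, power = 1L, piecewise_linear = 2L,
    abort(sprintf("unknown relationship '%s'", relationship))
  )
}

#' Evaluate one covariate multiplier
#'
#' @param term An [effect_term()].
#' @param x Covariate value(s): numeric for continuous terms, category labels
#'   for categorical terms. Vectorized.
#' @return Numeric multiplier(s).
#' @export
effect_multiplier <- function(term, x) {
  stopifnot(inherits(term, "effect_term"))
  th <- term$theta
  if (!is.null(term$categories)) {
    x <- as.character(x)
    bad <- setdiff(unique(x), term$categories)
    if (length(bad)) abort(sprintf("unknown category '%s'", bad[1]))
    others <- setdiff(term$categories, as.character(term$reference))
    mult <- rep(1, length(x))
    for (k in seq_along(others)) {
      mult[x == others[k]] <- 1 + th[k]
    }
    return(mult)
  }
  if (any(!is.finite(x))) abort("non-finite continuous covariate value")
  ref <- term$reference
  switch(term$relationship,
    linear = 1 + th[1] * (x - ref),
    exponential = exp(th[1] * (x - ref)),
    power = {
      if (ref <= 0 || any(x <= 0)) {
        abort("power relationship requires positive covariate and reference")
      }
      (x / ref) ^ th[1]
    },
    piecewise_linear = ifelse(x <= ref,
                              1 + th[1] * (x - ref),
                              1 + th[2] * (x - ref)),
    abort(sprintf("unknown relationship '%s'", term$relationship))
  )
}

#' Combine covariate effects on one parameter
#'
#' The effect of multiple covariates on a single parameter is multiplicative:
#' the typical value is the base parameter times the product of the
#' individual multipliers. Non-positive products are possible for linear
#' terms with extreme coefficients and are flagged with a warning (the
#' estimator treats them as inadmissible).
#'
#' @param base_param Positive base (typical) parameter value.
#' @param terms List of [effect_term()]s acting on this parameter.
#' @param cov_values Named list/vector of covariate values, one entry per
#'   term (names matching `names(terms)`), or a vector recycled positionally.
#' @return Positive numeric parameter value(s).
#' @export
combine_effects <- function(base_param, terms, cov_values) {
  stopifnot(base_param > 0)
  if (length(terms) == 0L) return(base_param)
  mult <- 1
  for (k in seq_along(terms)) {
    xv <- if (!is.null(names(terms)) && !is.null(names(cov_values))) {
      cov_values[[names(terms)[k]]]
    } else {
      cov_values[[k]]
    }
    mult <- mult * effect_multiplier(terms[[k]], xv)
  }
  out <- base_param * mult
  if (any(out <= 0)) {
    warn("combined covariate effect produced a non-positive parameter value")
  }
  out
}

#' Number of covariate coefficients of a model
#'
#' Counts the coefficients required by a decoded covariate model (`N_c` in
#' the fitness function): 1 per linear/exponential/power term, 2 per
#' piece-wise linear term, `n_categories - 1` per categorical term.
#' Structural parameters and random-effect/error parameters are not counted.
#'
#' @param spec A `cov_model_spec` (from [decode_chromosome()]).
#' @param covariates Named list of [covariate_def()]s (e.g.
#'   `space$covariates`).
#' @return Integer count.
#' @export
theta_count <- function(spec, covariates) {
  if (nrow(spec) == 0L) return(0L)
  sum(vapply(seq_len(nrow(spec)), function(r) {
    cv <- covariates[[spec$covariate[r]]]
    relationship_theta_count(spec$relationship[r], cv$categories)
  }, integer(1)))
}
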