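#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GA run
#'
#' @param x A `ga_fit` from [run_ga()].
#' @param what `"history"` (default; one row per generation) or `"lookup"`
#'   (one row per evaluated model).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ga_fit <- function(x, what = c("history", "lookup"), ...) {
  what <- match.arg(what)
  if (what == "history") x$history else x$lookup
}

#' @rdname tidy.ga_fit
#' @export
glance.ga_fit <- function(x, ...) {
  tibble::tibble(
    generations = max(x$history$generation),
    models_evaluated = x$n_backend_calls,
    best_fitness = x$best_fitness,
    best_ofv = x$best_ofv,
    best_n_terms = nrow(x$best_spec),
    l_chr = x$space$l_chr
  )
}

#' Tidy an FO fit
#'
#' @param x An `fo_fit` from [fit_model()].
#' @param ... Unused.
#' @return One row per estimated parameter (`term`, `estimate`).
#' @export
tidy.fo_fit <- function(x, ...) {
  if (is.null(x$estimates)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname tidy.fo_fit
#' @export
glance.fo_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, aic = if (x$converged) aic(x$ofv, x$n_theta) else NA_real_,
                 n_theta = x$n_theta, converged = x$converged,
                 status = x$status, evaluations = x$runtime)
}

#' Tidy an SCM run
#'
#' @param x An `scm_fit` from [run_scm()].
#' @param ... Unused.
#' @return The step record tibble.
#' @export
tidy.scm_fit <- function(x, ...) x$steps

#' @rdname tidy.scm_fit
#' @export
glance.scm_fit <- function(x, ...) {
  tibble::tibble(base_ofv = x$base_ofv, final_ofv = x$final_ofv,
                 n_terms = nrow(x$final_spec),
                 aic = aic(x$final_ofv, x$final_n_theta))
}

#' Plot GA convergence
#'
#' Mean and best-ever fitness per generation.
#'
#' @param object A `ga_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$history[c("generation", "mean", "best_ever")],
    cols = c("mean", "best_ever"), names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "fitness",
                  colour = NULL,
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}

#' Plot goodness of fit of an FO fit
#'
#' Observed concentrations against the typical-value predictions of the
#' fitted model.
#'
#' @param object An `fo_fit`.
#' @param dataset The `pk_dataset` the model was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fo_fit <- function(object, dataset, ...) {
  if (!object$converged) abort("cannot plot an unconverged fit")
  ctx <- fo_context(object$spec, dataset, refs = object$refs)
  theta <- object$estimates[seq_len(object$n_theta)]
  mult <- fo_multipliers(ctx, theta)
  cl_i <- theta[1] * mult$cl
  v_i <- theta[2] * mult$v
  i <- ctx$sub_idx
  pred <- ctx$dose[i] / v_i[i] * exp(-cl_i[i] * ctx$t / v_i[i])
  df <- tibble::tibble(pred = pred, dv = ctx$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$dv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "population prediction", y = "observed",
                  title = "Observed vs predicted") +
    ggplot2::theme_minimal()
}
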