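# Internal first-order (FO) estimator for the one-compartment iv-bolus
# model. The marginal likelihood is the exact Gaussian likelihood of the
# model linearized around eta = 0:
#   y_i ~ N(f_i, G_i Omega G_i' + R_i),  R_i = diag(sa^2 + sp^2 f_ij^2)
# with f the typical-value prediction and G = df/deta at 0. The per-subject
# determinant and quadratic form are computed by the Woodbury identity on the
# 2x2 capacitance matrix (valid for any PSD Omega, including 0), which keeps
# the objective loop-free across subjects.

# Precompute everything that does not depend on parameter values.
fo_context <- function(spec, dataset, covariates = NULL, refs = NULL) {
  obs <- pk_observations(dataset)
  covtab <- pk_covariate_table(dataset)
  doses <- pk_doses(dataset)
  covtab <- dplyr::left_join(covtab, doses, by = "ID")
  if (any(is.na(covtab$dose))) abort("every subject needs a dose record")
  if (any(obs$TIME < 0)) abort("negative observation time")

  sub_idx <- match(obs$ID, covtab$ID)
  is_categorical <- function(cv) {
    if (!is.null(covariates)) return(covariates[[cv]]$kind == "categorical")
    length(unique(covtab[[cv]])) <= 2L || !is.numeric(covtab[[cv]])
  }
  if (is.null(refs)) {
    refs <- covariate_references(
      covtab, unique(spec$covariate),
      categorical = if (nrow(spec)) {
        spec$covariate[vapply(spec$covariate, is_categorical, logical(1))]
      } else character()
    )
  }

  terms <- list()
  theta_names <- c("CL", "V")
  pos <- 3L
  if (nrow(spec)) {
    for (r in seq_len(nrow(spec))) {
      cv <- spec$covariate[r]
      x <- covtab[[cv]]
      if (is.null(x)) abort(sprintf("covariate '%s' missing from dataset", cv))
      if (is_categorical(cv)) {
        cats <- sort(unique(as.character(x)))
        others <- setdiff(cats, as.character(refs[[cv]]))
        ind <- vapply(others, function(cc) as.numeric(as.character(x) == cc),
                      numeric(nrow(covtab)))
        ind <- matrix(ind, nrow = nrow(covtab))
        k <- length(others)
        terms[[r]] <- list(type = "categorical", parameter = spec$parameter[r],
                           idx = pos:(pos + k - 1L), ind = ind)
        theta_names <- c(theta_names, paste0(spec$parameter[r], ":", cv,
                                             if (k > 1L) paste0(":", others) else ""))
        pos <- pos + k
      } else {
        ref <- refs[[cv]]
        k <- if (spec$relationship[r] == "piecewise_linear") 2L else 1L
        terms[[r]] <- list(type = spec$relationship[r],
                           parameter = spec$parameter[r],
                           idx = pos:(pos + k - 1L),
                           xc = x - ref,
                           xratio = if (spec$relationship[r] == "power") x / ref)
        theta_names <- c(theta_names, paste0(spec$parameter[r], ":", cv,
                                             if (k > 1L) paste0(":", 1:2) else ""))
        pos <- pos + k
      }
    }
  }

  list(
    spec = spec, refs = refs, terms = terms, theta_names = theta_names,
    n_theta = pos - 1L, n_sub = nrow(covtab), n_obs = nrow(obs),
    y = obs$DV, t = obs$TIME, sub_idx = sub_idx, dose = covtab$dose,
    covtab = covtab
  )
}

# per-subject typical-value multipliers for CL and V given covariate thetas
fo_multipliers <- function(ctx, theta) {
  m_cl <- rep(1, ctx$n_sub)
  m_v <- rep(1, ctx$n_sub)
  for (term in ctx$terms) {
    th <- theta[term$idx]
    m <- switch(term$type,
      linear = 1 + th * term$xc,
      exponential = exp(th * term$xc),
      power = term$xratio ^ th,
      piecewise_linear = 1 + ifelse(term$xc <= 0, th[1], th[2]) * term$xc,
      categorical = 1 + as.vector(term$ind %*% th)
    )
    if (term$parameter == "CL") m_cl <- m_cl * m else m_v <- m_v * m
  }
  list(cl = m_cl, v = m_v)
}

fo_ofv <- function(ctx, theta, omega, sigma) {
  mult <- fo_multipliers(ctx, theta)
  cl_i <- theta[1] * mult$cl
  v_i <- theta[2] * mult$v
  if (any(!is.finite(cl_i)) || any(!is.finite(v_i)) ||
      any(cl_i <= 0) || any(v_i <= 0)) {
    return(Inf) # inadmissible multiplier (e.g. linear term crossing zero)
  }
  i <- ctx$sub_idx
  w <- cl_i[i] * ctx$t / v_i[i]            # CL*t/V per observation
  f <- ctx$dose[i] / v_i[i] * exp(-w)
  if (any(!is.finite(f))) return(Inf)
  g1 <- -f * w                              # df/deta_CL at 0
  g2 <- f * (w - 1)                         # df/deta_V at 0
  R <- sigma[1]^2 + sigma[2]^2 * f^2
  if (any(R <= 0)) return(Inf)
  iR <- 1 / R
  r <- ctx$y - f

  s <- rowsum(cbind(g1 * g1 * iR, g1 * g2 * iR, g2 * g2 * iR,
                    g1 * r * iR, g2 * r * iR), ctx$sub_idx)
  a11 <- s[, 1]; a12 <- s[, 2]; a22 <- s[, 3]; u1 <- s[, 4]; u2 <- s[, 5]

  o11 <- omega[1, 1]; o12 <- omega[1, 2]; o22 <- omega[2, 2]
  b11 <- 1 + o11 * a11 + o12 * a12
  b12 <- o11 * a12 + o12 * a22
  b21 <- o12 * a11 + o22 * a12
  b22 <- 1 + o12 * a12 + o22 * a22
  detB <- b11 * b22 - b12 * b21
  if (any(!is.finite(detB)) || any(detB <= 0)) return(Inf)
  # M = B^{-1} Omega; quadratic-form correction u' M u
  m11 <- (b22 * o11 - b12 * o12) / detB
  m12 <- (b22 * o12 - b12 * o22) / detB
  m21 <- (-b21 * o11 + b11 * o12) / detB
  m22 <- (-b21 * o12 + b11 * o22) / detB
  quad <- u1 * u1 * m11 + u1 * u2 * (m12 + m21) + u2 * u2 * m22

  sum(log(R)) + sum(log(detB)) + sum(r * r * iR) - sum(quad) +
    ctx$n_obs * log(2 * pi)
}

#' First-order marginal objective function
#'
#' Minus twice the marginal log-likelihood (all normalization constants
#' included) of the one-compartment iv model linearized around zero random
#' effects. With `omega = 0` and `sigma[2] = 0` it reduces to weighted least
#' squares, `sum((y - f)^2 / sa^2 + log sa^2) + n * log(2 * pi)`.
#'
#' @param theta Fixed effects: `c(CL, V, <covariate coefficients>)` in the
#'   order given by [spec_theta_names()].
#' @param omega 2x2 positive semi-definite covariance of the log-normal
#'   random effects on CL and V.
#' @param sigma `c(sigma_add, sigma_prop)` residual SDs, both `>= 0`.
#' @param spec Candidate `cov_model_spec`.
#' @param dataset A `pk_dataset` tibble.
#' @param covariates Optional named list of [covariate_def()]s (to identify
#'   categorical covariates); inferred from the data when `NULL`.
#' @param refs Optional list of centering references; dataset medians / modal
#'   category when `NULL`.
#' @return The objective function value (a single number; `Inf` for
#'   inadmissible parameters such as a linear multiplier crossing zero).
#' @export
fo_objective <- function(theta, omega, sigma, spec, dataset,
                         covariates = NULL, refs = NULL) {
  if (any(theta[1:2] <= 0)) abort("structural parameters CL, V must be positive")
  if (any(sigma < 0) || all(sigma == 0)) abort("need a non-degenerate residual error")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) abort("omega must be positive semi-definite")
  ctx <- fo_context(spec, dataset, covariates, refs)
  if (length(theta) != ctx$n_theta) {
    abort(sprintf("theta must have length %d (%s)", ctx$n_theta,
                  paste(ctx$theta_names, collapse = ", ")))
  }
  fo_ofv(ctx, theta, omega, sigma)
}

#' Fixed-effect layout of a candidate model
#'
#' @inheritParams fo_objective
#' @return Character vector naming the entries of `theta`: `CL`, `V`, then
#'   one entry per covariate coefficient in spec row order.
#' @export
spec_theta_names <- function(spec, dataset, covariates = NULL) {
  fo_context(spec, dataset, covariates)$theta_names
}

# pack/unpack the unconstrained optimizer vector:
# (log CL, log V, cov thetas, log L11, L21, log L22, log sa, log sp)
fo_unpack <- function(p, n_cov) {
  theta <- c(exp(p[1]), exp(p[2]),
             if (n_cov > 0) p[2 + seq_len(n_cov)] else numeric())
  q <- p[(2 + n_cov + 1):length(p)]
  L <- matrix(c(exp(q[1]), q[2], 0, exp(q[3])), 2, 2)
  list(theta = theta, omega = L %*% t(L), sigma = c(exp(q[4]), exp(q[5])))
}

# run a function with the global RNG stream protected and locally seeded
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# deterministic 32-bit polynomial hash of a bitstring key
chrom_hash <- function(key) {
  if (is.null(key)) return(0L)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Fit a candidate covariate model by FO estimation
#'
#' Minimizes [fo_objective()] over unconstrained transforms (log structural
#' parameters, raw covariate coefficients, log-Cholesky random-effect
#' covariance, log residual SDs) with `nlminb`, from a naive-pooled
#' log-linear starting point plus seeded jittered restarts. Runtime is
#' reported as the number of objective evaluations, the deterministic unit
#' the GA timeout policy uses for this backend.
#'
#' @inheritParams fo_objective
#' @param settings List of fit settings: `n_starts` (default 3), `seed`
#'   (default 0; jitter stream), `eval_budget` (default `Inf`; exceeding it
#'   aborts the fit with status `"timeout"`), `eval_max`/`iter_max` per
#'   `nlminb` start (defaults 500/200), `rel_tol` (`nlminb` relative
#'   tolerance, default 1e-8), and optionally `warm_start` (a `par` vector
#'   from a previous fit supplying structural/variance starting values;
#'   covariate coefficients then start at zero).
#' @return A list of class `fo_fit`: `ofv`, `estimates` (named vector with
#'   structural, covariate, random-effect and residual parameters),
#'   `converged`, `status` (`"converged"`, `"failed"` or `"timeout"`),
#'   `runtime` (objective evaluations), `n_theta` (fixed-effect count),
#'   `spec`, `refs`, `theta_names`.
#' @export
#' @examples
#' set.seed(42)
#' d <- simulate_pk(n = 30, scenario = "sparse3")
#' base <- fit_model(empty_spec(), d)
#' base$ofv
fit_model <- function(spec, dataset, settings = list(), covariates = NULL,
                      refs = NULL) {
  s <- modifyList(list(n_starts = 3L, seed = 0L, eval_budget = Inf,
                       eval_max = 500L, iter_max = 200L, rel_tol = 1e-8),
                  settings)
  ctx <- fo_context(spec, dataset, covariates, refs)
  n_cov <- ctx$n_theta - 2L
  if (ctx$n_sub < ctx$n_theta + 5L) {
    abort(sprintf("need at least %d subjects to fit %d fixed effects",
                  ctx$n_theta + 5L, ctx$n_theta))
  }

  if (!is.null(s$warm_start)) {
    # structural + variance components from a previous (e.g. base-model) fit;
    # covariate coefficients start at zero
    p0 <- c(s$warm_start[1:2], rep(0, n_cov), s$warm_start[-(1:2)])
  } else {
    # naive-pooled starting values from a log-linear regression
    pos <- ctx$y > 0
    lfit <- stats::lm.fit(cbind(1, ctx$t[pos]), log(ctx$y[pos]))
    k0 <- max(-lfit$coefficients[2], 1e-3)
    v0 <- max(mean(ctx$dose) / exp(lfit$coefficients[1]), 1e-3)
    cl0 <- k0 * v0
    p0 <- c(log(cl0), log(v0), rep(0, n_cov),
            log(sqrt(0.1)), 0, log(sqrt(0.1)), log(0.1), log(0.1))
  }

  count <- 0L
  timed_out <- FALSE
  fn <- function(p) {
    count <<- count + 1L
    if (count > s$eval_budget) {
      stop(structure(class = c("fo_timeout", "error", "condition"),
                     list(message = "evaluation budget exceeded", call = NULL)))
    }
    u <- fo_unpack(p, n_cov)
    val <- fo_ofv(ctx, u$theta, u$omega, u$sigma)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- list(p0)
  if (s$n_starts > 1L) {
    jitter_seed <- (s$seed + chrom_hash(attr(spec, "key"))) %% 2147483647
    jitters <- with_local_seed(jitter_seed, function() {
      lapply(seq_len(s$n_starts - 1L), function(k) {
        p0 + c(rnorm(2, 0, 0.3), rep(0, n_cov), rnorm(3, 0, 0.3), rnorm(2, 0, 0.5))
      })
    })
    starts <- c(starts, jitters)
  }

  best <- NULL
  for (p_start in starts) {
    res <- tryCatch(
      nlminb(p_start, fn,
             control = list(eval.max = s$eval_max, iter.max = s$iter_max,
                            rel.tol = s$rel_tol)),
      fo_timeout = function(e) { timed_out <<- TRUE; NULL },
      error = function(e) NULL
    )
    if (timed_out) break
    if (!is.null(res) && is.finite(res$objective) && res$objective < 1e10 &&
        (is.null(best) || res$objective < best$objective)) {
      best <- res
    }
  }

  if (is.null(best)) {
    status <- if (timed_out) "timeout" else "failed"
    return(structure(
      list(ofv = NA_real_, estimates = NULL, converged = FALSE,
           status = status, runtime = count, n_theta = ctx$n_theta,
           spec = spec, refs = ctx$refs, theta_names = ctx$theta_names),
      class = "fo_fit"))
  }

  u <- fo_unpack(best$par, n_cov)
  om <- u$omega
  var_par <- best$par[(2 + n_cov + 1):length(best$par)]
  est <- c(setNames(u$theta, ctx$theta_names),
           omega_CL = om[1, 1], omega_V = om[2, 2],
           omega_corr = om[1, 2] / sqrt(om[1, 1] * om[2, 2]),
           sigma_add = u$sigma[1], sigma_prop = u$sigma[2])
  structure(
    list(ofv = best$objective, estimates = est, converged = TRUE,
         status = "converged", runtime = count, n_theta = ctx$n_theta,
         nlminb_code = best$convergence, spec = spec, refs = ctx$refs,
         theta_names = ctx$theta_names,
         par = c(best$par[1:2], var_par)),
    class = "fo_fit")
}

#' The empty (base) covariate model
#'
#' @return A zero-row `cov_model_spec`.
#' @export
empty_spec <- function() {
  spec <- tibble::tibble(parameter = character(), covariate = character(),
                         relationship = character())
  class(spec) <- c("cov_model_spec", class(spec))
  spec
}

#' @export
print.fo_fit <- function(x, ...) {
  cat(sprintf("<fo_fit> status: %s | OFV: %s | fixed effects: %d | evals: %d\n",
              x$status, format(x$ofv), x$n_theta, x$runtime))
  if (!is.null(x$estimates)) {
    print(round(x$estimates, 4))
  }
  invisible(x)
}

#' FO estimation backend for the GA engine
#'
#' Wraps [fit_model()] into the backend contract the engine uses: a function
#' `f(spec, budget, key)` returning a fit result. The jitter stream of each
#' fit is seeded from `seed` plus a hash of the chromosome key, so results
#' do not depend on evaluation order or on the number of workers.
#'
#' Inside a search the backend defaults to a single start and a relative
#' convergence tolerance of `1e-6`: candidate ranking needs objective
#' differences of order 1 (the 3.84 penalty unit), orders of magnitude above
#' that tolerance, and the looser settings cut the evaluation count several
#' fold. Standalone [fit_model()] keeps its tighter defaults.
#'
#' @param dataset A `pk_dataset`.
#' @param covariates Optional named list of [covariate_def()]s.
#' @param settings Fit settings forwarded to [fit_model()]; defaults here
#'   are `n_starts = 1`, `rel_tol = 1e-6`.
#' @param seed Base seed for per-model jitter.
#' @return A backend function.
#' @export
fo_backend <- function(dataset, covariates = NULL, settings = list(),
                       seed = 0L) {
  settings <- modifyList(list(n_starts = 1L, rel_tol = 1e-6), settings)
  force(dataset); force(covariates); force(seed)
  warm <- NULL # structural/variance start shared across candidates (lazy)
  function(spec, budget = Inf, key = NULL) {
    attr(spec, "key") <- key
    if (is.null(warm)) {
      base <- fit_model(empty_spec(), dataset,
                        settings = modifyList(settings, list(seed = seed)),
                        covariates = covariates)
      if (isTRUE(base$converged)) warm <<- base$par
    }
    st <- modifyList(settings, list(eval_budget = budget, seed = seed,
                                    warm_start = warm))
    fit_model(spec, dataset, settings = st, covariates = covariates)
  }
}
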