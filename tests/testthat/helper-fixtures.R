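# Shared fixtures and independent oracles.

# Worked-example space: two parameters, two continuous covariates with all
# four relationship forms, one binary categorical covariate; 14 bits.
worked_space <- function() {
  search_space(
    parameters = c("p1", "p2"),
    covariates = list(
      covariate_def("c1", "continuous"),
      covariate_def("c2", "continuous"),
      covariate_def("c3", "categorical", categories = c("0", "1"))
    )
  )
}

# The simulated evaluation study's full space: CL and V, seven continuous
# covariates (all four forms) plus binary SEX; 44 bits.
sim_study_space <- function() {
  search_space(
    parameters = c("CL", "V"),
    covariates = list(
      covariate_def("AGE", "continuous"),
      covariate_def("BMI", "continuous"),
      covariate_def("BSA", "continuous"),
      covariate_def("CR", "continuous"),
      covariate_def("CRCL", "continuous"),
      covariate_def("HT", "continuous"),
      covariate_def("WT", "continuous"),
      covariate_def("SEX", "categorical", categories = c("0", "1"))
    )
  )
}

# Build a pk_dataset by hand (no simulator) for estimator tests.
manual_pk_dataset <- function(covtab, times, dose, dv_matrix) {
  n <- nrow(covtab)
  obs <- do.call(rbind, lapply(seq_len(n), function(s) {
    data.frame(ID = covtab$ID[s], TIME = times, EVID = 0L, AMT = 0,
               DV = dv_matrix[s, ], MDV = 0L)
  }))
  doses <- data.frame(ID = covtab$ID, TIME = 0, EVID = 1L, AMT = dose,
                      DV = NA_real_, MDV = 1L)
  out <- dplyr::left_join(dplyr::bind_rows(doses, obs),
                          covtab, by = "ID")
  out <- dplyr::arrange(out, ID, TIME, dplyr::desc(EVID))
  structure(tibble::as_tibble(out),
            class = c("pk_dataset", class(tibble::tibble())),
            covariate_names = setdiff(names(covtab), "ID"))
}

# Independent brute-force marginal likelihood of the eta-linearized model:
# per subject, numerically integrate N(y; f + G eta, R) N(eta; 0, Omega)
# over eta by adaptive tensor-product Gauss-Hermite quadrature (nodes
# centered and scaled by the integrand's curvature, computed with base
# dense linear algebra -- no shared code with the closed-form objective).
# Predictions and sensitivities are recomputed here from the model formulas.
gh_marginal_ofv <- function(theta, omega, sigma, spec, dataset,
                            n_nodes = 30) {
  gh <- pracma::gaussHermite(n_nodes)
  covtab <- pk_covariate_table(dataset)
  doses <- pk_doses(dataset)
  obs <- pk_observations(dataset)
  refs <- lapply(setdiff(names(covtab), "ID"), function(cv) median(covtab[[cv]]))
  names(refs) <- setdiff(names(covtab), "ID")

  total <- 0
  for (s in seq_len(nrow(covtab))) {
    id <- covtab$ID[s]
    o <- obs[obs$ID == id, ]
    D <- doses$dose[doses$ID == id]
    mult <- c(CL = 1, V = 1)
    ti <- 3L
    if (nrow(spec)) {
      for (r in seq_len(nrow(spec))) {
        term <- effect_term(spec$relationship[r],
                            theta[ti], refs[[spec$covariate[r]]])
        mult[spec$parameter[r]] <- mult[spec$parameter[r]] *
          effect_multiplier(term, covtab[[spec$covariate[r]]][s])
        ti <- ti + 1L
      }
    }
    cl_tv <- theta[1] * mult["CL"]
    v_tv <- theta[2] * mult["V"]
    w <- cl_tv * o$TIME / v_tv
    f0 <- D / v_tv * exp(-w)
    g <- cbind(-f0 * w, f0 * (w - 1))
    R <- sigma[1]^2 + sigma[2]^2 * f0^2
    r0 <- o$DV - f0

    # adapt nodes to the posterior of the linear-Gaussian integrand
    curv <- solve(omega) + t(g) %*% diag(1 / R, nrow(o)) %*% g
    P <- solve(curv)
    mu <- as.vector(P %*% (t(g) %*% (r0 / R)))
    Lp <- t(chol(P))

    val <- 0
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        z <- c(gh$x[i], gh$x[j])
        eta <- mu + sqrt(2) * as.vector(Lp %*% z)
        resid <- r0 - as.vector(g %*% eta)
        ll <- -0.5 * sum(resid^2 / R) - 0.5 * sum(log(2 * pi * R)) -
          0.5 * sum(eta * solve(omega, eta)) - log(2 * pi) -
          0.5 * as.numeric(determinant(omega)$modulus)
        val <- val + gh$w[i] * gh$w[j] * exp(ll + sum(z^2)) *
          2 * sqrt(det(P))
      }
    }
    total <- total - 2 * log(val)
  }
  total
}

# Independent correlation-penalty oracle: absolute Pearson correlation
# matrix per parameter, off-diagonal sum halved.
ic_oracle <- function(spec, covtab) {
  tot <- 0
  for (p in unique(spec$parameter)) {
    covs <- spec$covariate[spec$parameter == p]
    covs <- covs[vapply(covs, function(cv) is.numeric(covtab[[cv]]), logical(1))]
    if (length(covs) < 2) next
    cm <- abs(cor(as.matrix(covtab[covs])))
    tot <- tot + (sum(cm) - length(covs)) / 2
  }
  tot
}

# A counting backend wrapper for cache tests.
counting_backend <- function(backend) {
  calls <- new.env()
  calls$n <- 0L
  fn <- function(spec, budget = Inf, key = NULL) {
    calls$n <- calls$n + 1L
    backend(spec, budget = budget, key = key)
  }
  list(fn = fn, calls = calls)
}

# Backend with scripted runtimes/failures for timeout & sentinel tests:
# runtime equals the number of included terms times 10; chromosomes whose
# decoded model includes `fail_pair` never converge.
scripted_backend <- function(space, fail_pair = NULL) {
  seen_budgets <- new.env(); seen_budgets$log <- list()
  fn <- function(spec, budget = Inf, key = NULL) {
    seen_budgets$log[[length(seen_budgets$log) + 1L]] <- budget
    rt <- 10 * nrow(spec) + 5
    if (!is.null(fail_pair) && nrow(spec) &&
        any(spec$parameter == fail_pair[1] & spec$covariate == fail_pair[2])) {
      return(list(ofv = NA_real_, converged = FALSE, status = "failed",
                  runtime = 0, n_theta = NA_integer_))
    }
    if (rt > budget) {
      return(list(ofv = NA_real_, converged = FALSE, status = "timeout",
                  runtime = budget, n_theta = NA_integer_))
    }
    list(ofv = -10 * nrow(spec), converged = TRUE, status = "converged",
         runtime = rt, n_theta = 2L + nrow(spec))
  }
  list(fn = fn, budgets = seen_budgets)
}
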