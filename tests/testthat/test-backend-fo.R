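make_toy_dataset <- function(n = 3, times = c(0.5, 2, 8), dose = 100,
                             cl = 0.6, v = 2.0, noise = 0) {
  covtab <- data.frame(ID = seq_len(n),
                       WT = seq(60, 90, length.out = n))
  f <- outer(rep(1, n), dose / v * exp(-cl / v * times))
  if (noise > 0) f <- f + matrix(rnorm(length(f), 0, noise), nrow = n)
  manual_pk_dataset(covtab, times, dose, f)
}

test_that("FO objective reduces to weighted least squares when eta vanishes", {
  d <- make_toy_dataset(n = 4)
  obs <- pk_observations(d)
  sa <- 0.3
  theta <- c(0.7, 1.8)
  ofv <- fo_objective(theta, omega = matrix(0, 2, 2), sigma = c(sa, 0),
                      spec = empty_spec(), dataset = d)
  f <- 100 / theta[2] * exp(-theta[1] / theta[2] * obs$TIME)
  manual <- sum((obs$DV - f)^2 / sa^2) + nrow(obs) * log(sa^2) +
    nrow(obs) * log(2 * pi)
  expect_equal(ofv, manual, tolerance = 1e-12)
})

test_that("perfect data is minimized at the generating parameters", {
  d <- make_toy_dataset(cl = 0.6, v = 2.0)
  at_truth <- fo_objective(c(0.6, 2.0), matrix(0, 2, 2), c(0.1, 0),
                           empty_spec(), d)
  for (th in list(c(0.7, 2.0), c(0.6, 2.3), c(0.5, 1.8))) {
    expect_gt(fo_objective(th, matrix(0, 2, 2), c(0.1, 0), empty_spec(), d),
              at_truth)
  }
})

test_that("FO objective matches Gauss-Hermite quadrature of the linearized model", {
  set.seed(71)
  d <- make_toy_dataset(n = 3, noise = 0.4)
  omega <- matrix(c(0.02, 0.004, 0.004, 0.03), 2, 2)
  sigma <- c(0.3, 0.05)
  ofv <- fo_objective(c(0.6, 2.0), omega, sigma, empty_spec(), d)
  gh <- gh_marginal_ofv(c(0.6, 2.0), omega, sigma, empty_spec(), d)
  expect_equal(ofv, gh, tolerance = 1e-6)

  # with a covariate effect included
  spec <- tibble::tibble(parameter = "CL", covariate = "WT",
                         relationship = "exponential")
  class(spec) <- c("cov_model_spec", class(spec))
  ofv2 <- fo_objective(c(0.6, 2.0, 0.01), omega, sigma, spec, d)
  gh2 <- gh_marginal_ofv(c(0.6, 2.0, 0.01), omega, sigma, spec, d)
  expect_equal(ofv2, gh2, tolerance = 1e-6)
})

test_that("invalid parameters are rejected", {
  d <- make_toy_dataset()
  expect_error(fo_objective(c(-1, 2), matrix(0, 2, 2), c(0.1, 0),
                            empty_spec(), d), "positive")
  bad_omega <- matrix(c(1, 2, 2, 1), 2, 2) # indefinite
  expect_error(fo_objective(c(0.6, 2), bad_omega, c(0.1, 0),
                            empty_spec(), d), "semi-definite")
  expect_error(fo_objective(c(0.6, 2), matrix(0, 2, 2), c(0, 0),
                            empty_spec(), d), "residual")
})

test_that("near-noiseless data recovers the generating parameters within 1%", {
  set.seed(72)
  tv <- sim_true_values()
  tv$theta[] <- 0
  tv$omega <- diag(c(1e-10, 1e-10))
  tv$sigma_add <- 0.005; tv$sigma_prop <- 1e-8
  tv$CL <- 0.6; tv$V <- 2.0
  d <- simulate_pk(n = 20, scenario = "rich", true_spec = sim_true_spec()[0, ],
                   true_values = tv)
  fit <- fit_model(empty_spec(), d)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["CL"]] - 0.6) / 0.6, 0.01)
  expect_lt(abs(fit$estimates[["V"]] - 2.0) / 2.0, 0.01)
})

test_that("nested models never fit worse than their parent", {
  set.seed(73)
  d <- simulate_pk(n = 40, scenario = "sparse5")
  base <- fit_model(empty_spec(), d)
  spec <- tibble::tibble(parameter = c("CL", "V"),
                         covariate = c("BMI", "SEX"),
                         relationship = c("exponential", "linear"))
  class(spec) <- c("cov_model_spec", class(spec))
  full <- fit_model(spec, d)
  expect_true(base$converged && full$converged)
  expect_gte(base$ofv - full$ofv, -0.5) # likelihood monotone up to tolerance
})

test_that("too few subjects for the parameter count is refused", {
  d <- make_toy_dataset(n = 4)
  spec <- tibble::tibble(parameter = "CL", covariate = "WT",
                         relationship = "piecewise_linear")
  class(spec) <- c("cov_model_spec", class(spec))
  expect_error(fit_model(spec, d), "subjects")
})

test_that("an exhausted evaluation budget yields a timeout status", {
  set.seed(74)
  d <- simulate_pk(n = 20, scenario = "sparse3")
  fit <- fit_model(empty_spec(), d, settings = list(eval_budget = 10))
  expect_false(fit$converged)
  expect_equal(fit$status, "timeout")
})

test_that("backend fits are independent of evaluation order (keyed jitter)", {
  set.seed(75)
  d <- simulate_pk(n = 20, scenario = "sparse3")
  bk <- fo_backend(d, seed = 5, settings = list(n_starts = 3))
  spec <- tibble::tibble(parameter = "CL", covariate = "BMI",
                         relationship = "linear")
  class(spec) <- c("cov_model_spec", class(spec))
  a <- bk(empty_spec(), key = "000")
  b <- bk(spec, key = "001")
  a2 <- bk(empty_spec(), key = "000")
  expect_equal(a$ofv, a2$ofv)
  expect_identical(a$estimates, a2$estimates)
})
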