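# A deterministic synthetic backend for exercising the stepwise logic
# without estimation: the OFV drops by a scripted amount per included term.
scripted_scm_backend <- function(space, gains) {
  function(spec, budget = Inf, key = NULL) {
    ofv <- 1000
    if (nrow(spec)) {
      for (r in seq_len(nrow(spec))) {
        k <- paste(spec$parameter[r], spec$covariate[r], spec$relationship[r])
        ofv <- ofv - (gains[[k]] %||% 0)
      }
    }
    n_theta <- 2L + theta_count(spec, space$covariates)
    list(ofv = ofv, converged = TRUE, status = "converged", runtime = 0,
         n_theta = n_theta)
  }
}

scm_space <- function() {
  search_space(
    "CL",
    list(covariate_def("WT", "continuous"),
         covariate_def("AGE", "continuous")),
    pairs = tibble::tibble(
      parameter = "CL", covariate = c("WT", "AGE"),
      relationships = list(c("linear", "exponential"),
                           c("linear", "exponential"))))
}

test_that("forward inclusion requires the chi-square critical drop", {
  sp <- scm_space()
  # WT-linear improves by 10 (> 3.84); AGE terms by 2 (< 3.84)
  bk <- scripted_scm_backend(sp, list("CL WT linear" = 10,
                                      "CL AGE linear" = 2,
                                      "CL AGE exponential" = 2))
  res <- run_scm(sp, dataset = NULL, backend = bk)
  expect_equal(nrow(res$final_spec), 1L)
  expect_equal(res$final_spec$covariate, "WT")
  expect_equal(res$final_spec$relationship, "linear")
  acc <- res$steps[res$steps$accepted & res$steps$direction == "forward", ]
  expect_equal(nrow(acc), 1L)
  expect_gt(acc$delta_ofv, qchisq(0.95, 1))
})

test_that("backward elimination drops terms below the stricter threshold", {
  sp <- scm_space()
  # both included forward (gains 10 and 5); AGE's 5 < 6.63 -> removed backward
  bk <- scripted_scm_backend(sp, list("CL WT linear" = 10,
                                      "CL AGE linear" = 5))
  res <- run_scm(sp, dataset = NULL, backend = bk)
  expect_equal(res$final_spec$covariate, "WT")
  bwd <- res$steps[res$steps$direction == "backward", ]
  expect_equal(bwd$covariate, "AGE")
  expect_lt(bwd$delta_ofv, qchisq(0.99, 1))
})

test_that("the final model never fits worse than the base model", {
  sp <- scm_space()
  bk <- scripted_scm_backend(sp, list("CL WT exponential" = 20,
                                      "CL AGE linear" = 8))
  res <- run_scm(sp, dataset = NULL, backend = bk)
  expect_lte(res$final_ofv, res$base_ofv)
})

test_that("relationship order breaks ties and can change the selected model", {
  sp <- scm_space()
  # linear and exponential WT forms give identical drops: first-in-order wins
  bk <- scripted_scm_backend(sp, list("CL WT linear" = 10,
                                      "CL WT exponential" = 10))
  r1 <- run_scm(sp, NULL, bk,
                relationship_order = c("linear", "exponential",
                                       "piecewise_linear", "power"))
  r2 <- run_scm(sp, NULL, bk,
                relationship_order = c("exponential", "linear",
                                       "piecewise_linear", "power"))
  expect_equal(r1$final_spec$relationship, "linear")
  expect_equal(r2$final_spec$relationship, "exponential")
  expect_false(identical(r1$final_spec, r2$final_spec))
})

test_that("stepwise search on simulated data finds a strong true effect", {
  set.seed(91)
  d <- simulate_pk(n = 40, scenario = "sparse5")
  sp <- search_space(
    c("CL", "V"),
    list(covariate_def("BMI", "continuous"),
         covariate_def("SEX", "categorical", categories = c("0", "1"))),
    pairs = tibble::tibble(
      parameter = c("CL", "V"), covariate = c("BMI", "SEX"),
      relationships = list("exponential", "linear")))
  bk <- fo_backend(d, covariates = sp$covariates, seed = 91)
  res <- run_scm(sp, d, bk)
  expect_true(any(res$final_spec$parameter == "CL" &
                    res$final_spec$covariate == "BMI"))
  expect_lte(res$final_ofv, res$base_ofv)
})

test_that("multi-coefficient candidates use matching degrees of freedom", {
  sp <- search_space(
    "CL", list(covariate_def("WT", "continuous")),
    pairs = tibble::tibble(parameter = "CL", covariate = "WT",
                           relationships = list("piecewise_linear")))
  # drop of 5: exceeds the 1-df cutoff 3.84 but not the 2-df cutoff 5.99
  bk <- scripted_scm_backend(sp, list("CL WT piecewise_linear" = 5))
  res <- run_scm(sp, NULL, bk)
  expect_equal(nrow(res$final_spec), 0L)
  fwd <- res$steps[res$steps$direction == "forward", ]
  expect_equal(fwd$df, 2L)
  expect_false(any(fwd$accepted))
})
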