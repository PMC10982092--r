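#' Default covariate distribution parameters
#'
#' The evaluation study samples SEX from a fair Bernoulli, AGE from a normal
#' distribution and BMI, CR (serum creatinine) and HT from log-normal
#' distributions, conditionally independent given SEX, with the HT location
#' sex-specific. WT, BSA and CRCL are then derived deterministically:
#' `WT = BMI * HT^2`, `BSA = sqrt(HT * 100 * WT / 3600)` and CRCL from the
#' creatinine-clearance formula (Cockcroft-Gault
#' `(140 - AGE) * WT / (72 * CR)` by default; an `"as_printed"` variant
#' `140 * AGE * WT / (72 * CR)` is available).
#'
#' @return A list of distribution parameters accepted by
#'   [sample_covariates()].
#' @export
covariate_sim_params <- function() {
  list(
    sex_prob = 0.5,               # P(SEX = 1), 1 = male
    age_mean = 45, age_sd = 12,   # years
    bmi_meanlog = log(25), bmi_sdlog = 0.15,  # kg/m^2
    cr_meanlog = log(0.9), cr_sdlog = 0.20,   # mg/dL
    ht_meanlog_male = log(1.75), ht_meanlog_female = log(1.62),
    ht_sdlog = 0.04,              # meters
    crcl_formula = "cockcroft_gault"
  )
}

#' Sample baseline covariate profiles
#'
#' @param n Number of subjects.
#' @param params Distribution parameters; see [covariate_sim_params()].
#' @return Tibble with columns `ID`, `SEX`, `AGE`, `BMI`, `CR`, `HT` and the
#'   derived `WT`, `BSA`, `CRCL`.
#' @export
#' @examples
#' set.seed(1)
#' sample_covariates(5)
sample_covariates <- function(n, params = covariate_sim_params()) {
  if (n < 1L) abort("`n` must be >= 1")
  params <- modifyList(covariate_sim_params(), params)
  with(params, {
    if (sex_prob < 0 || sex_prob > 1) abort("sex_prob must be in [0, 1]")
    if (age_sd <= 0 || bmi_sdlog <= 0 || cr_sdlog <= 0 || ht_sdlog <= 0) {
      abort("distribution scale parameters must be positive")
    }
    sex <- rbinom(n, 1L, sex_prob)
    age <- rnorm(n, age_mean, age_sd)
    bmi <- rlnorm(n, bmi_meanlog, bmi_sdlog)
    cr <- rlnorm(n, cr_meanlog, cr_sdlog)
    ht <- rlnorm(n, ifelse(sex == 1L, ht_meanlog_male, ht_meanlog_female),
                 ht_sdlog)
    wt <- bmi * ht^2
    bsa <- sqrt(ht * 100 * wt / 3600)
    crcl <- crcl_value(age, wt, cr, crcl_formula)
    tibble::tibble(ID = seq_len(n), SEX = sex, AGE = age, BMI = bmi, CR = cr,
                   HT = ht, WT = wt, BSA = bsa, CRCL = crcl)
  })
}

#' Creatinine clearance
#'
#' @param age,wt,cr Age (years), weight (kg), serum creatinine (mg/dL).
#' @param formula `"cockcroft_gault"` for `(140 - AGE) * WT / (72 * CR)` or
#'   `"as_printed"` for `140 * AGE * WT / (72 * CR)`.
#' @return Clearance values (mL/min).
#' @export
crcl_value <- function(age, wt, cr, formula = c("cockcroft_gault", "as_printed")) {
  formula <- match.arg(formula)
  switch(formula,
    cockcroft_gault = (140 - age) * wt / (72 * cr),
    as_printed = 140 * age * wt / (72 * cr)
  )
}

#' True covariate model of the evaluation study
#'
#' CRCL and BMI act exponentially on clearance; BSA exponentially and SEX
#' linearly on volume.
#'
#' @return A `cov_model_spec` tibble.
#' @export
sim_true_spec <- function() {
  spec <- tibble::tibble(
    parameter = c("CL", "CL", "V", "V"),
    covariate = c("CRCL", "BMI", "BSA", "SEX"),
    relationship = c("exponential", "exponential", "exponential", "linear")
  )
  class(spec) <- c("cov_model_spec", class(spec))
  spec
}

#' Generating parameter values of the evaluation study
#'
#' Structural, covariate-effect, random-effect and residual-error values used
#' by [simulate_pk()] by default. The random-effect entry is the 2x2
#' covariance of the log-normal inter-individual effects on CL and V
#' (variances 0.2 and 0.25, correlation 0.0497); residual error is combined
#' (additive SD 0.106, proportional SD `sqrt(0.00036)`). The CRCL
#' coefficient is expressed per mL/min of Cockcroft-Gault clearance.
#'
#' @return A list with `CL`, `V`, `theta` (named by `"parameter:covariate"`),
#'   `omega`, `sigma_add`, `sigma_prop`.
#' @export
sim_true_values <- function() {
  om <- diag(c(0.2, 0.25))
  om[1, 2] <- om[2, 1] <- 0.0497 * sqrt(0.2 * 0.25)
  list(
    CL = 0.608, V = 2.28,
    theta = c("CL:CRCL" = 0.01, "CL:BMI" = 0.224,
              "V:BSA" = 0.0676, "V:SEX" = -0.347),
    omega = om,
    sigma_add = 0.106,
    sigma_prop = sqrt(0.00036)
  )
}

#' Sampling designs of the evaluation study
#'
#' @param scenario `"rich"` (8 samples at 0.25, 0.5, 1, 2, 3, 6, 10, 24 h),
#'   `"sparse5"` (0.25, 0.5, 2, 6, 24 h) or `"sparse3"` (0.25, 2, 6 h).
#' @return Numeric vector of sampling times (hours post dose).
#' @export
scenario_times <- function(scenario = c("rich", "sparse5", "sparse3")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    rich = c(0.25, 0.5, 1, 2, 3, 6, 10, 24),
    sparse5 = c(0.25, 0.5, 2, 6, 24),
    sparse3 = c(0.25, 2, 6)
  )
}

#' Simulate a population PK dataset
#'
#' One-compartment model with linear elimination after a single intravenous
#' bolus: `f(t) = (Dose / V_i) * exp(-(CL_i / V_i) * t)`. Individual
#' parameters are the typical values times the multiplicative covariate
#' effects of `true_spec` times `exp(eta)`, with `eta` bivariate normal with
#' covariance `omega`. Observations carry combined residual error:
#' `y = f * (1 + eps_prop) + eps_add`. Negative simulated concentrations are
#' retained (realistic assay noise) and counted in
#' `attr(x, "n_negative_dv")`.
#'
#' Continuous covariate effects are centered at the sample median of the
#' simulated covariate; the SEX reference is the most common category.
#'
#' @param n Number of subjects (default 200).
#' @param scenario Sampling design, see [scenario_times()].
#' @param profiles Optional pre-sampled covariate tibble from
#'   [sample_covariates()]; sampled fresh when `NULL`.
#' @param true_spec Covariate model used for generation (default
#'   [sim_true_spec()]).
#' @param true_values Generating parameter values (default
#'   [sim_true_values()]).
#' @param dose IV bolus amount (default 100, amount units).
#' @param cov_params Covariate distribution parameters for fresh sampling.
#' @return A tibble of class `pk_dataset` in NONMEM-style long format
#'   (columns `ID`, `TIME`, `EVID`, `AMT`, `DV`, `MDV` plus covariates),
#'   with attributes `covariate_names`, `scenario`, `true_spec`,
#'   `true_values`, `refs`, `dose`, `n_negative_dv`.
#' @export
#' @examples
#' set.seed(7)
#' d <- simulate_pk(n = 10, scenario = "sparse3")
#' nrow(dplyr::filter(d, EVID == 0))
simulate_pk <- function(n = 200L, scenario = c("rich", "sparse5", "sparse3"),
                        profiles = NULL, true_spec = sim_true_spec(),
                        true_values = sim_true_values(), dose = 100,
                        cov_params = covariate_sim_params()) {
  scenario <- match.arg(scenario)
  times <- scenario_times(scenario)
  if (is.null(profiles)) profiles <- sample_covariates(n, cov_params)
  n <- nrow(profiles)

  refs <- covariate_references(profiles,
                               unique(c(true_spec$covariate, "SEX")))
  terms <- build_effect_terms(true_spec, true_values$theta, refs, profiles)

  # typical values with covariate effects, then log-normal IIV
  cl_tv <- rep(true_values$CL, n)
  v_tv <- rep(true_values$V, n)
  for (r in seq_len(nrow(true_spec))) {
    mult <- effect_multiplier(terms[[r]], profiles[[true_spec$covariate[r]]])
    if (true_spec$parameter[r] == "CL") cl_tv <- cl_tv * mult
    else v_tv <- v_tv * mult
  }
  ev <- eigen(true_values$omega, symmetric = TRUE)
  om_root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  eta <- matrix(rnorm(2 * n), ncol = 2) %*% om_root
  cl_i <- cl_tv * exp(eta[, 1])
  v_i <- v_tv * exp(eta[, 2])

  obs <- tidyr::expand_grid(ID = profiles$ID, TIME = times)
  idx <- match(obs$ID, profiles$ID)
  f <- dose / v_i[idx] * exp(-(cl_i[idx] / v_i[idx]) * obs$TIME)
  y <- f * (1 + rnorm(nrow(obs), 0, true_values$sigma_prop)) +
    rnorm(nrow(obs), 0, true_values$sigma_add)

  obs$EVID <- 0L; obs$AMT <- 0; obs$DV <- y; obs$MDV <- 0L
  doses <- tibble::tibble(ID = profiles$ID, TIME = 0, EVID = 1L, AMT = dose,
                          DV = NA_real_, MDV = 1L)
  out <- dplyr::bind_rows(doses, obs)
  out <- dplyr::left_join(out, profiles, by = "ID")
  out <- dplyr::arrange(out, .data$ID, .data$TIME, dplyr::desc(.data$EVID))

  structure(
    out,
    class = c("pk_dataset", class(out)),
    covariate_names = setdiff(names(profiles), "ID"),
    scenario = scenario,
    true_spec = true_spec,
    true_values = true_values,
    refs = refs,
    dose = dose,
    n_negative_dv = sum(y < 0)
  )
}

# reference values per covariate: median for numeric, most common category
# (ties to the lexicographically first) for categorical-looking columns
covariate_references <- function(covariate_table, covs,
                                 categorical = "SEX") {
  refs <- list()
  for (cv in covs) {
    x <- covariate_table[[cv]]
    if (cv %in% categorical || !is.numeric(x)) {
      tab <- sort(table(as.character(x)), decreasing = TRUE)
      refs[[cv]] <- names(tab)[1]
    } else {
      refs[[cv]] <- median(x)
    }
  }
  refs
}

# effect_term list for a spec given named theta values ("param:cov" keys,
# piecewise/categorical entries may be length > 1)
build_effect_terms <- function(spec, theta, refs, covariate_table,
                               categorical = "SEX") {
  lapply(seq_len(nrow(spec)), function(r) {
    key <- paste0(spec$parameter[r], ":", spec$covariate[r])
    th <- theta[grepl(paste0("^", key, "($|:)"), names(theta))]
    cv <- spec$covariate[r]
    if (cv %in% categorical || !is.numeric(covariate_table[[cv]])) {
      cats <- sort(unique(as.character(covariate_table[[cv]])))
      effect_term("linear", th, reference = refs[[cv]], categories = cats)
    } else {
      effect_term(spec$relationship[r], th, reference = refs[[cv]])
    }
  })
}

#' Read/write NONMEM-style CSV datasets
#'
#' `write_pk_csv()` writes the long-format dataset with `#`-prefixed header
#' comments recording the scenario metadata; `read_pk_csv()` reads such a
#' file back into a `pk_dataset` tibble.
#'
#' @param data A `pk_dataset` tibble.
#' @param path File path.
#' @return `read_pk_csv()` returns the tibble; `write_pk_csv()` the path,
#'   invisibly.
#' @export
write_pk_csv <- function(data, path) {
  meta <- c(
    sprintf("# scenario: %s", attr(data, "scenario") %||% "unknown"),
    sprintf("# dose: %s", attr(data, "dose") %||% "unknown"),
    sprintf("# covariates: %s",
            paste(attr(data, "covariate_names") %||% character(), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(as.data.frame(data), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pk_csv
#' @export
read_pk_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- grep("^#", lines, value = TRUE)
  df <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  covs <- sub("^# covariates: ", "", grep("^# covariates:", meta, value = TRUE))
  covs <- if (length(covs) && nzchar(covs)) strsplit(covs, ",")[[1]] else {
    setdiff(names(df), c("ID", "TIME", "EVID", "AMT", "DV", "MDV"))
  }
  structure(df, class = c("pk_dataset", class(df)),
            covariate_names = covs,
            scenario = sub("^# scenario: ", "",
                           grep("^# scenario:", meta, value = TRUE))[1] %||% NA)
}

# ---- accessors --------------------------------------------------------------

#' Dataset accessors
#'
#' `pk_observations()` returns the observation rows (`EVID == 0`),
#' `pk_covariate_table()` one row per subject with the baseline covariates,
#' and `pk_doses()` the per-subject bolus amount.
#'
#' @param data A `pk_dataset` tibble.
#' @return A tibble.
#' @export
pk_observations <- function(data) {
  dplyr::filter(data, .data$EVID == 0)
}

#' @rdname pk_observations
#' @export
pk_covariate_table <- function(data) {
  covs <- attr(data, "covariate_names") %||%
    setdiff(names(data), c("ID", "TIME", "EVID", "AMT", "DV", "MDV"))
  dplyr::distinct(dplyr::select(data, dplyr::all_of(c("ID", covs))),
                  .data$ID, .keep_all = TRUE)
}

#' @rdname pk_observations
#' @export
pk_doses <- function(data) {
  d <- dplyr::filter(data, .data$EVID == 1)
  dplyr::summarise(dplyr::group_by(d, .data$ID), dose = sum(.data$AMT),
                   .groups = "drop")
}
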