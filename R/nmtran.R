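# NM-TRAN control-stream generation. The base template (NONMEM 7.x,
# ADVAN1/TRANS2) carries {{PK_BLOCK}} and {{THETA_BLOCK}} placeholders that
# are filled deterministically from a decoded covariate model, so identical
# inputs yield byte-identical files (generation only; never executed here).

#' Default base control-stream template
#'
#' @return Path to the packaged ADVAN1/TRANS2 template.
#' @export
nmtran_base_template <- function() {
  system.file("extdata", "base_advan1.mod", package = "gacovsel",
              mustWork = TRUE)
}

#' Write an NM-TRAN control stream for a candidate model
#'
#' Builds the `$PK` block implementing the candidate's multiplicative
#' covariate model on the typical values (`TVCL`, `TVV`), with
#' `CL = TVCL*EXP(ETA(1))`, `V = TVV*EXP(ETA(2))`, and sizes the `$THETA`
#' records to the candidate (one initial estimate line per fixed effect;
#' piece-wise linear terms emit two THETA records, categorical terms one per
#' non-reference category). Covariate terms are emitted in the search
#' space's canonical pair order, so the output is invariant to the order in
#' which the model's rows are listed.
#'
#' @param spec A `cov_model_spec`.
#' @param space The [search_space()] (fixes pair order and covariate kinds).
#' @param refs Named list of centering references (medians / reference
#'   categories). Required for any included continuous covariate.
#' @param base_template Path to a template containing `{{PK_BLOCK}}` and
#'   `{{THETA_BLOCK}}` placeholders.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The control-stream text (a single string), invisibly when
#'   written to `path`.
#' @export
#' @examples
#' sp <- search_space(
#'   c("CL", "V"),
#'   list(covariate_def("WT", "continuous", reference = 70),
#'        covariate_def("SEX", "categorical", categories = c("0", "1"),
#'                      reference = "0"))
#' )
#' cat(write_nmtran(sim_true_spec()[0, ], sp, refs = list()))
write_nmtran <- function(spec, space, refs = list(),
                         base_template = nmtran_base_template(),
                         path = NULL) {
  stopifnot(inherits(space, "cov_search_space"))
  template <- paste(readLines(base_template), collapse = "\n")

  # canonical order: sort spec rows by the space's frozen pair order
  if (nrow(spec)) {
    ord <- order(match(paste(spec$parameter, spec$covariate),
                       paste(space$pairs$parameter, space$pairs$covariate)))
    spec <- spec[ord, ]
  }
  input_line <- grep("^\\$INPUT", strsplit(template, "\n")[[1]], value = TRUE)
  declared <- if (length(input_line)) strsplit(sub("^\\$INPUT ", "", input_line[1]),
                                               "\\s+")[[1]] else character()
  missing_cov <- setdiff(unique(spec$covariate), declared)
  if (length(input_line) && length(missing_cov)) {
    abort(sprintf("covariate '%s' is not declared in the template $INPUT",
                  missing_cov[1]))
  }

  params <- space$parameters
  theta_i <- length(params) # THETA(1..n_par) are the typical values
  pk <- character()
  thetas <- sprintf("(0, 1)     ; TV%s", params)
  param_expr <- setNames(as.list(sprintf("THETA(%d)", seq_along(params))),
                         params)

  for (r in seq_len(nrow(spec))) {
    p <- spec$parameter[r]; cv <- spec$covariate[r]
    rel <- spec$relationship[r]
    cvdef <- space$covariates[[cv]]
    if (cvdef$kind == "categorical") {
      ref <- as.character(refs[[cv]] %||% cvdef$reference)
      others <- setdiff(cvdef$categories, ref)
      for (cc in others) {
        theta_i <- theta_i + 1L
        flag <- sprintf("%sEQ%s", cv, cc)
        pk <- c(pk, sprintf("%s = 0", flag),
                sprintf("IF (%s.EQ.%s) %s = 1", cv, cc, flag))
        param_expr[[p]] <- sprintf("%s*(1+THETA(%d)*%s)", param_expr[[p]],
                                   theta_i, flag)
        thetas <- c(thetas, sprintf("(-0.99,0.1); %s on %s (%s=%s)", cv, p, cv, cc))
      }
    } else {
      ref <- refs[[cv]] %||% cvdef$reference
      if (is.null(ref) || is.na(ref)) {
        abort(sprintf("no centering reference for continuous covariate '%s'", cv))
      }
      refs_s <- format(ref, trim = TRUE)
      if (rel == "linear") {
        theta_i <- theta_i + 1L
        param_expr[[p]] <- sprintf("%s*(1+THETA(%d)*(%s-%s))", param_expr[[p]],
                                   theta_i, cv, refs_s)
        thetas <- c(thetas, sprintf("0.01       ; %s on %s (linear)", cv, p))
      } else if (rel == "exponential") {
        theta_i <- theta_i + 1L
        param_expr[[p]] <- sprintf("%s*EXP(THETA(%d)*(%s-%s))", param_expr[[p]],
                                   theta_i, cv, refs_s)
        thetas <- c(thetas, sprintf("0.01       ; %s on %s (exponential)", cv, p))
      } else if (rel == "power") {
        theta_i <- theta_i + 1L
        param_expr[[p]] <- sprintf("%s*(%s/%s)**THETA(%d)", param_expr[[p]],
                                   cv, refs_s, theta_i)
        thetas <- c(thetas, sprintf("0.01       ; %s on %s (power)", cv, p))
      } else if (rel == "piecewise_linear") {
        lo <- theta_i + 1L; hi <- theta_i + 2L; theta_i <- hi
        pk <- c(pk,
                sprintf("%sLO = MIN(%s-%s,0)", cv, cv, refs_s),
                sprintf("%sHI = MAX(%s-%s,0)", cv, cv, refs_s))
        param_expr[[p]] <- sprintf("%s*(1+THETA(%d)*%sLO+THETA(%d)*%sHI)",
                                   param_expr[[p]], lo, cv, hi, cv)
        thetas <- c(thetas,
                    sprintf("0.01       ; %s on %s (piece-wise linear-1)", cv, p),
                    sprintf("0.01       ; %s on %s (piece-wise linear-2)", cv, p))
      } else {
        abort(sprintf("unknown relationship '%s'", rel))
      }
    }
  }

  for (k in seq_along(params)) {
    pk <- c(pk,
            sprintf("TV%s = %s", params[k], param_expr[[params[k]]]),
            sprintf("%s = TV%s*EXP(ETA(%d))", params[k], params[k], k))
  }
  if ("V" %in% params) pk <- c(pk, "S1 = V")

  out <- sub("{{PK_BLOCK}}", paste(pk, collapse = "\n"), template, fixed = TRUE)
  out <- sub("{{THETA_BLOCK}}", paste(thetas, collapse = "\n"), out, fixed = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
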