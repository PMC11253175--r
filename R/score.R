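# Score evaluation: linear predictor (esp), logistic event probability,
# sex-dispatched S-MECKI score, standardized coefficients.

# Extract the 6 covariate columns of one or more patient records as a matrix
# in canonical order, with finiteness validation naming the offending field.
covariate_matrix <- function(patients) {
  cov <- smecki_covariates()
  if (is.null(dim(patients))) patients <- as.data.frame(as.list(patients))
  missing_cols <- setdiff(cov, names(patients))
  if (length(missing_cols) > 0) {
    stop("patient record is missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(patients)[, cov, drop = FALSE])
  storage.mode(x) <- "double"
  for (j in cov) {
    if (any(!is.finite(x[, j]))) {
      stop("non-finite value in covariate `", j, "`", call. = FALSE)
    }
  }
  check_plausibility(x)
  x
}

# Plausibility warnings only; the score applies no exclusions.
check_plausibility <- function(x) {
  if (any(x[, "na"] < 100 | x[, "na"] > 160)) {
    warning("sodium value(s) outside the 100-160 mmol/L plausibility band",
            call. = FALSE)
  }
  if (any(x[, "lvef"] <= 0 | x[, "lvef"] > 100)) {
    warning("LVEF value(s) outside (0, 100] %", call. = FALSE)
  }
  pos <- c("hb", "mdrd", "vevco2_slope", "peakvo2_pct")
  for (j in pos) {
    if (any(x[, j] <= 0)) {
      warning("non-positive value(s) in covariate `", j, "`", call. = FALSE)
    }
  }
  invisible(x)
}

#' Linear predictor (esp) of the logistic score
#'
#' Computes \code{intercept + sum(beta_i * covariate_i)} over the six MECKI
#' covariates in canonical order. Exact floating arithmetic, no clipping.
#'
#' @param patients A patient record (named list / one-row data frame) or a
#'   cohort data frame with columns \code{peakvo2_pct, vevco2_slope, hb, na,
#'   lvef, mdrd}.
#' @param coeffs A \code{\link{coefficient_set}}.
#' @return Numeric vector of linear predictors, one per record.
#' @examples
#' p0 <- list(peakvo2_pct = 0, vevco2_slope = 0, hb = 0, na = 0,
#'            lvef = 0, mdrd = 0)
#' suppressWarnings(linear_predictor(p0, smecki_coefficients("F")))  # 4.1116831
#' @export
linear_predictor <- function(patients, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  x <- covariate_matrix(patients)
  b <- coeffs$coefficients
  drop(b[["intercept"]] + x %*% b[smecki_covariates()])
}

#' Logistic event probability
#'
#' Maps a linear predictor to \code{exp(esp)/(1 + exp(esp))} via
#' \code{\link[stats]{plogis}}, which is numerically stable across the whole
#' double range (no overflow, no premature underflow to 0 at esp = -50).
#'
#' @param esp Numeric vector of finite linear predictors.
#' @return Probabilities in the open interval (0, 1) up to double precision.
#' @examples
#' event_probability(0)        # 0.5
#' event_probability(log(3))   # 0.75
#' @export
event_probability <- function(esp) {
  if (!is.numeric(esp) || any(!is.finite(esp))) {
    stop("`esp` must be finite numeric", call. = FALSE)
  }
  plogis(esp)
}

#' S-MECKI event probability for a patient
#'
#' Dispatches on the patient's sex to the built-in female or male coefficient
#' set and returns the 2-year composite event probability
#' \code{event_probability(linear_predictor(patient, coeffs[sex]))}.
#'
#' @param patients Patient record(s) with a \code{sex} field in
#'   \code{c("F", "M")} plus the six covariates.
#' @return Numeric vector of event probabilities.
#' @export
s_mecki_score <- function(patients) {
  if (is.null(dim(patients))) patients <- as.data.frame(as.list(patients))
  patients <- as.data.frame(patients)
  if (is.null(patients$sex)) stop("patient record has no `sex` field",
                                  call. = FALSE)
  sex <- as.character(patients$sex)
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad) > 0) {
    stop("unknown sex label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- numeric(nrow(patients))
  for (s in intersect(c("F", "M"), unique(sex))) {
    idx <- sex == s
    out[idx] <- event_probability(
      linear_predictor(patients[idx, , drop = FALSE], smecki_coefficients(s))
    )
  }
  out
}

#' Standardized coefficient
#'
#' Expresses a logistic coefficient per standard deviation of its covariate:
#' \code{beta * covariate_sd}. This is the convention used for the
#' standardized-weight ranking of the score's variables.
#'
#' @param beta Numeric coefficient(s) on the raw covariate scale.
#' @param covariate_sd Positive standard deviation(s) of the covariate.
#' @return \code{beta * covariate_sd}.
#' @examples
#' standardized_beta(-0.0597067, 3.3)  # male sodium, about -0.197
#' @export
standardized_beta <- function(beta, covariate_sd) {
  if (!is.numeric(covariate_sd) || any(!is.finite(covariate_sd)) ||
      any(covariate_sd <= 0)) {
    stop("`covariate_sd` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop("`beta` must be finite numeric", call. = FALSE)
  }
  beta * covariate_sd
}
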