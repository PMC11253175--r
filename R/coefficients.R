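# Built-in S-MECKI coefficient sets at full printed precision.
# Canonical covariate order: peakvo2_pct, vevco2_slope, hb, na, lvef, mdrd.
.smecki_builtin <- list(
  F = c(intercept    =  4.1116831,
        peakvo2_pct  = -0.0341452,
        vevco2_slope =  0.0252531,
        hb           = -0.1724513,
        na           = -0.0175751,
        lvef         = -0.0279113,
        mdrd         = -0.0090766),
  M = c(intercept    =  9.790738,
        peakvo2_pct  = -0.0472631,
        vevco2_slope =  0.0285722,
        hb           = -0.0789262,
        na           = -0.0597067,
        lvef         = -0.0368194,
        mdrd         = -0.0110881)
)

#' Construct a coefficient set for the logistic score
#'
#' A coefficient set holds the intercept and the six covariate weights of the
#' MECKI-type logistic score, in the canonical covariate order
#' \code{(peakvo2_pct, vevco2_slope, hb, na, lvef, mdrd)}.
#'
#' @param coefficients Named numeric vector of length 7 with names
#'   \code{c("intercept", "peakvo2_pct", "vevco2_slope", "hb", "na", "lvef",
#'   "mdrd")} (any order; stored canonically).
#' @param sex_label One of \code{"F"}, \code{"M"}, \code{"pooled"}.
#' @param provenance Free-text description of where the values come from.
#' @return An object of class \code{coefficient_set}.
#' @examples
#' cs <- coefficient_set(
#'   c(intercept = -3, peakvo2_pct = -0.03, vevco2_slope = 0.02,
#'     hb = -0.1, na = -0.02, lvef = -0.03, mdrd = -0.01),
#'   sex_label = "pooled")
#' @export
coefficient_set <- function(coefficients, sex_label = c("pooled", "F", "M"),
                            provenance = "") {
  sex_label <- match.arg(sex_label)
  nm <- smecki_coef_names()
  if (!is.numeric(coefficients) || length(coefficients) != 7L) {
    stop("`coefficients` must be a numeric vector of length 7", call. = FALSE)
  }
  if (is.null(names(coefficients)) || !setequal(names(coefficients), nm)) {
    stop("`coefficients` must be named: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  coefficients <- coefficients[nm]
  if (!all(is.finite(coefficients))) {
    stop("all 7 coefficient values must be finite", call. = FALSE)
  }
  structure(
    list(sex_label = sex_label, coefficients = coefficients,
         provenance = provenance),
    class = "coefficient_set"
  )
}

#' Built-in sex-specific S-MECKI coefficient sets
#'
#' Returns the published female or male coefficient set of the
#' sex-recalibrated MECKI score, stored at full printed precision
#' (female intercept 4.1116831, male intercept 9.790738).
#'
#' @param sex \code{"F"} or \code{"M"}.
#' @return A \code{\link{coefficient_set}}.
#' @examples
#' smecki_coefficients("F")$coefficients[["intercept"]]  # 4.1116831
#' @export
smecki_coefficients <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  coefficient_set(.smecki_builtin[[sex]], sex_label = sex,
                  provenance = "built-in S-MECKI set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Coefficient set (", x$sex_label, ")\n", sep = "")
  print(x$coefficients)
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Write a coefficient set to JSON or YAML
#'
#' Keys follow the canonical covariate order, so files interchange with any
#' implementation of the score.
#'
#' @param x A \code{\link{coefficient_set}}.
#' @param path Output file path; format inferred from the extension
#'   (\code{.json}, \code{.yaml}/\code{.yml}) unless given.
#' @param format \code{"json"} or \code{"yaml"}.
#' @return \code{path}, invisibly.
#' @export
write_coefficients <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "coefficient_set"))
  format <- format %||% infer_format(path)
  payload <- list(
    sex_label = x$sex_label,
    coefficients = as.list(x$coefficients),
    provenance = x$provenance
  )
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (format == "yaml") {
    yaml::write_yaml(payload, path, precision = 17)
  } else {
    stop("unknown format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Read a coefficient set from JSON or YAML
#'
#' @param path File written by \code{\link{write_coefficients}} (or any file
#'   with the same keys).
#' @param format \code{"json"} or \code{"yaml"}; inferred from the extension
#'   by default.
#' @return A \code{\link{coefficient_set}}.
#' @export
read_coefficients <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  payload <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (format == "yaml") {
    yaml::read_yaml(path)
  } else {
    stop("unknown format: ", format, call. = FALSE)
  }
  coefficient_set(unlist(payload$coefficients),
                  sex_label = payload$sex_label %||% "pooled",
                  provenance = payload$provenance %||% "")
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "json",
         yaml = "yaml",
         yml = "yaml",
         stop("cannot infer format from extension: .", ext, call. = FALSE))
}
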