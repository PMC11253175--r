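# Synthetic cohort generation: per-sex truncated-normal covariates with the
# registry's published means/SDs as defaults, events drawn from the logistic
# score under a specified "true" coefficient set per sex.

.default_moments <- list(
  F = list(mean = c(peakvo2_pct = 63.2, vevco2_slope = 33.5, hb = 12.7,
                    na = 139.6, lvef = 36.4, mdrd = 68.6),
           sd   = c(peakvo2_pct = 18.3, vevco2_slope = 7.7, hb = 1.4,
                    na = 3.0, lvef = 11.4, mdrd = 24.6)),
  M = list(mean = c(peakvo2_pct = 54.6, vevco2_slope = 33.2, hb = 13.7,
                    na = 139.4, lvef = 32.3, mdrd = 72.3),
           sd   = c(peakvo2_pct = 17.0, vevco2_slope = 7.9, hb = 1.7,
                    na = 3.3, lvef = 10.0, mdrd = 24.2))
)

# Physiologic floors/ceilings intersected with mean +/- 4 SD.
.physio_bounds <- list(
  lower = c(peakvo2_pct = 1e-6, vevco2_slope = 1e-6, hb = 1e-6,
            na = 110, lvef = 1e-6, mdrd = 1e-6),
  upper = c(peakvo2_pct = Inf, vevco2_slope = Inf, hb = Inf,
            na = 160, lvef = 100, mdrd = Inf)
)

default_bounds <- function(mean, sd) {
  lower <- pmax(mean - 4 * sd, .physio_bounds$lower[names(mean)])
  upper <- pmin(mean + 4 * sd, .physio_bounds$upper[names(mean)])
  list(lower = lower, upper = upper)
}

#' Specification of a synthetic two-sex cohort
#'
#' Defaults reproduce the registry population: 1,444 women and 6,456 men,
#' per-sex covariate means and SDs as published (e.g. female peak VO2
#' 63.2 +/- 18.3 \% predicted, male 54.6 +/- 17.0), identity correlation, and
#' events generated from the built-in sex-specific S-MECKI coefficient sets.
#' Covariates are truncated at mean +/- 4 SD intersected with physiologic
#' bounds (all positive; Na in [110, 160]; LVEF in (0, 100]).
#'
#' @param n_female,n_male Cohort sizes per sex.
#' @param means,sds Optional named lists \code{list(F = , M = )} of named
#'   6-vectors overriding the default covariate moments.
#' @param correlation Optional named list \code{list(F = , M = )} of 6x6
#'   correlation matrices (default identity). Must be symmetric positive
#'   semi-definite with unit diagonal.
#' @param bounds Optional named list \code{list(F = list(lower=, upper=),
#'   M = ...)} of truncation bounds; bounds must contain the mean.
#' @param true_coefficients Named list \code{list(F = , M = )} of
#'   \code{\link{coefficient_set}} objects used to generate events.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_female = 1444, n_male = 6456,
                        means = NULL, sds = NULL,
                        correlation = NULL, bounds = NULL,
                        true_coefficients = list(F = smecki_coefficients("F"),
                                                 M = smecki_coefficients("M")),
                        seed = 1L) {
  cov <- smecki_covariates()
  stopifnot(n_female >= 0, n_male >= 0)
  spec <- list(n = c(F = as.integer(n_female), M = as.integer(n_male)),
               seed = as.integer(seed), sexes = list())
  for (s in c("F", "M")) {
    m <- (means[[s]] %||% .default_moments[[s]]$mean)[cov]
    sdv <- (sds[[s]] %||% .default_moments[[s]]$sd)[cov]
    if (any(!is.finite(m)) || any(!is.finite(sdv)) || any(sdv <= 0)) {
      stop("means must be finite and SDs positive for sex ", s, call. = FALSE)
    }
    bb <- bounds[[s]] %||% default_bounds(m, sdv)
    bb$lower <- bb$lower[cov]; bb$upper <- bb$upper[cov]
    if (any(bb$lower > m) || any(bb$upper < m)) {
      stop("truncation bounds must contain the mean for sex ", s,
           call. = FALSE)
    }
    R <- correlation[[s]] %||% diag(6)
    R <- unname(as.matrix(R))
    if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)) ||
        !isTRUE(all.equal(unname(diag(R)), rep(1, 6), tolerance = 1e-10))) {
      stop("correlation matrix must be symmetric with unit diagonal",
           call. = FALSE)
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrix must be positive semi-definite", call. = FALSE)
    }
    tc <- true_coefficients[[s]]
    stopifnot(inherits(tc, "coefficient_set"))
    spec$sexes[[s]] <- list(mean = m, sd = sdv, bounds = bb,
                            correlation = R, coefficients = tc)
  }
  structure(spec, class = "cohort_spec")
}

# Truncated correlated normals by rejection from the untruncated
# distribution (acceptance is near 1 at +/- 4 SD).
sample_covariates <- function(n, mean, sd, R, bounds) {
  cov <- names(mean)
  L <- chol(R + diag(1e-12, 6))
  out <- matrix(NA_real_, 0, 6, dimnames = list(NULL, cov))
  while (nrow(out) < n) {
    m <- max(16L, ceiling(1.2 * (n - nrow(out))))
    Z <- matrix(rnorm(m * 6), m, 6) %*% L
    X <- sweep(sweep(Z, 2, sd, `*`), 2, mean, `+`)
    colnames(X) <- cov
    keep <- rep(TRUE, m)
    for (j in cov) {
      keep <- keep & X[, j] >= bounds$lower[[j]] & X[, j] <= bounds$upper[[j]]
    }
    out <- rbind(out, X[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic cohort
#'
#' Draws covariates from per-sex (optionally correlated) truncated normals
#' and events as Bernoulli draws from the logistic probability of the spec's
#' true coefficient set for that sex. Deterministic given the spec's seed.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Optional integer overriding \code{spec$seed}.
#' @return Data frame with columns \code{id, sex, lvef, hb, mdrd, na,
#'   vevco2_slope, peakvo2_pct, event}; the seed used is attached as
#'   attribute \code{"seed"}.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_female = 50, n_male = 50, seed = 7))
#' table(cohort$sex)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  pieces <- list()
  for (s in c("F", "M")) {
    n <- spec$n[[s]]
    if (n == 0L) next
    sx <- spec$sexes[[s]]
    X <- sample_covariates(n, sx$mean, sx$sd, sx$correlation, sx$bounds)
    b <- sx$coefficients$coefficients
    esp <- b[["intercept"]] + drop(X %*% b[smecki_covariates()])
    event <- as.integer(runif(n) < plogis(esp))
    pieces[[s]] <- data.frame(
      id = sprintf("%s%05d", s, seq_len(n)),
      sex = s,
      lvef = X[, "lvef"], hb = X[, "hb"], mdrd = X[, "mdrd"], na = X[, "na"],
      vevco2_slope = X[, "vevco2_slope"], peakvo2_pct = X[, "peakvo2_pct"],
      event = event,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(id = character(), sex = character(), lvef = numeric(),
                      hb = numeric(), mdrd = numeric(), na = numeric(),
                      vevco2_slope = numeric(), peakvo2_pct = numeric(),
                      event = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

cohort_columns <- function() {
  c("id", "sex", "lvef", "hb", "mdrd", "na", "vevco2_slope", "peakvo2_pct",
    "event")
}

validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cohort$event %in% c(0L, 1L))) {
    stop("`event` must be binary 0/1", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("F", "M"))) {
    stop("`sex` must be 'F' or 'M'", call. = FALSE)
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Fixed header \code{id, sex, lvef, hb, mdrd, na, vevco2_slope, peakvo2_pct,
#' event}; the generation seed (if known) is recorded as a \code{# seed:}
#' comment line that \code{\link{read_cohort}} understands.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.csv(cohort[, cohort_columns()], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV with the fixed cohort header (comma-separated, UTF-8,
#'   decimal point). Rows failing validation are reported with line numbers.
#' @return Cohort data frame; any recorded seed is attached as attribute
#'   \code{"seed"}.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- NULL
  if (grepl("^# seed:", first)) {
    seed <- as.integer(sub("^# seed:\\s*", "", first))
  }
  cohort <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns(), c("id", "sex"))
  bad <- !complete.cases(cohort[, num_cols]) |
    !apply(sapply(cohort[num_cols], is.finite), 1, all) |
    !(cohort$event %in% c(0, 1)) | !(cohort$sex %in% c("F", "M"))
  if (any(bad)) {
    offset <- if (is.null(seed)) 1L else 2L  # header (+ seed comment) lines
    stop("unparseable or invalid cohort row(s) at line(s): ",
         paste(which(bad) + offset, collapse = ", "), call. = FALSE)
  }
  cohort$event <- as.integer(cohort$event)
  attr(cohort, "seed") <- seed
  cohort
}
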