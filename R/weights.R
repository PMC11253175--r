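# Repeated half-split cross-validated coefficient estimation and the
# confidence-interval based sex-difference classification of the weights.

#' Randomly split a cohort in half
#'
#' Simple random (optionally outcome-stratified) disjoint partition into a
#' training half of size \code{ceiling(n/2)} and a testing half of size
#' \code{floor(n/2)}; the training half takes the extra record when n is odd.
#' Uses the current RNG state, so the split is reproducible under
#' \code{set.seed}.
#'
#' @param cohort Data frame of patient rows.
#' @param stratified If \code{TRUE}, split event and non-event rows
#'   separately (off by default; the estimation procedure uses plain random
#'   halves).
#' @return \code{list(training = , testing = )} of row indices.
#' @export
half_split <- function(cohort, stratified = FALSE) {
  n <- nrow(cohort)
  if (is.null(n) || n < 2L) {
    stop("cohort must have at least 2 records to split", call. = FALSE)
  }
  if (!stratified) {
    training <- sort(sample.int(n, ceiling(n / 2)))
  } else {
    idx1 <- which(cohort$event == 1L)
    idx0 <- which(cohort$event == 0L)
    take <- function(ix) if (length(ix) >= 2L) {
      sample(ix, ceiling(length(ix) / 2))
    } else ix
    training <- sort(c(take(idx1), take(idx0)))
    # keep the ceil/floor size contract under stratification
    extra <- length(training) - ceiling(n / 2)
    if (extra > 0) training <- training[-sample.int(length(training), extra)]
  }
  list(training = training, testing = setdiff(seq_len(n), training))
}

# Ridge-penalised IRLS used when the unpenalised fit fails to converge or
# shows (quasi-)complete separation; lambda applies to non-intercept terms.
irls_ridge <- function(X, y, lambda = 1e-4, maxit = 200L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit the six-covariate logistic model
#'
#' Maximum-likelihood logistic regression of the binary event on the six
#' MECKI covariates (intercept first, canonical order) by iteratively
#' reweighted least squares. If the fit does not converge or shows
#' (quasi-)complete separation, the model is refitted with a small L2
#' penalty (\code{lambda = 1e-4} on non-intercept terms) and flagged.
#'
#' @param x Numeric matrix of covariates (columns in canonical order, no
#'   intercept column), or a cohort data frame.
#' @param y Binary outcome vector.
#' @param penalty L2 penalty used by the fallback refit.
#' @return \code{list(coefficients, converged, flagged)} with 7 named
#'   coefficients.
#' @export
fit_logistic <- function(x, y, penalty = 1e-4) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, smecki_covariates(), drop = FALSE])
  }
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("x and y sizes differ", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: all events or all non-events", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) {
    stop("covariate matrix is not full column rank", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100L))
  )
  separated <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  flagged <- !fit$converged || fit$boundary || separated ||
    any(!is.finite(fit$coefficients))
  beta <- fit$coefficients
  if (flagged) beta <- irls_ridge(X, y, lambda = penalty)
  names(beta) <- if (ncol(x) == length(smecki_covariates())) {
    smecki_coef_names()
  } else c("intercept", colnames(x))
  list(coefficients = beta, converged = fit$converged && !separated,
       flagged = flagged)
}

#' Repeated half-split cross-validated coefficient estimation
#'
#' The single-sex cohort is randomly divided in half \code{n_reps} times
#' (default 200). In each repetition the logistic coefficients are estimated
#' on the training half and the fitted linear predictor is scored on the
#' testing half by AUC. The arithmetic mean of the repetition betas is the
#' recalibrated weight for each variable; 95\% intervals are the empirical
#' 2.5th/97.5th percentiles of the repetition distribution (a
#' confidence-interval-of-the-mean variant is also reported).
#'
#' @param cohort Single-sex cohort data frame.
#' @param n_reps Number of random half-splits.
#' @param master_seed Integer; repetition i uses an independent stream seeded
#'   deterministically from \code{(master_seed, i)}, so repetitions are
#'   order-independent and individually reproducible.
#' @param stratified Stratify splits by outcome (off by default).
#' @param interval \code{"percentile"} (default) or \code{"mean"}: which
#'   interval \code{ci_lower}/\code{ci_upper} expose (both are stored).
#' @return Object of class \code{cv_result}: \code{beta_matrix}
#'   (\code{n_reps x 7}), \code{mean_betas}, \code{ci_lower}, \code{ci_upper},
#'   \code{ci_percentile}, \code{ci_mean}, \code{test_aucs}, \code{n_failed},
#'   \code{n_flagged}, \code{seed}.
#' @export
cv_recalibrate <- function(cohort, n_reps = 200L, master_seed = 1L,
                           stratified = FALSE,
                           interval = c("percentile", "mean")) {
  interval <- match.arg(interval)
  validate_cohort(cohort)
  if (length(unique(cohort$sex)) != 1L) {
    stop("cv_recalibrate expects a single-sex cohort; split by sex first",
         call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  n <- nrow(cohort)
  n_events <- sum(cohort$event)
  if (n_events / 2 < 10 * 7) {
    warning("fewer than 10 events per parameter expected in a training half (",
            floor(n_events / 2), " events for 7 parameters); estimates will ",
            "be noisy", call. = FALSE)
  }
  x <- as.matrix(cohort[, smecki_covariates(), drop = FALSE])
  y <- cohort$event
  beta_matrix <- matrix(NA_real_, n_reps, 7L,
                        dimnames = list(NULL, smecki_coef_names()))
  test_aucs <- rep(NA_real_, n_reps)
  flagged <- logical(n_reps)
  failed <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(derive_seed(master_seed, i))
    sp <- half_split(cohort, stratified = stratified)
    res <- tryCatch(
      fit_logistic(x[sp$training, , drop = FALSE], y[sp$training]),
      error = function(e) NULL
    )
    if (is.null(res)) {
      failed[i] <- TRUE
      next
    }
    beta_matrix[i, ] <- res$coefficients
    flagged[i] <- res$flagged
    lp_test <- res$coefficients[1L] +
      drop(x[sp$testing, , drop = FALSE] %*% res$coefficients[-1L])
    test_aucs[i] <- tryCatch(auc(lp_test, y[sp$testing]),
                             error = function(e) NA_real_)
  }
  n_failed <- sum(failed)
  if (n_failed > 0.25 * n_reps) {
    stop("more than 25% of repetitions failed to fit; cohort too small or ",
         "degenerate", call. = FALSE)
  }
  ok <- !failed
  mean_betas <- colMeans(beta_matrix[ok, , drop = FALSE])
  ci_percentile <- apply(beta_matrix[ok, , drop = FALSE], 2, quantile,
                         probs = c(0.025, 0.975), names = FALSE)
  m <- sum(ok)
  se <- apply(beta_matrix[ok, , drop = FALSE], 2, sd) / sqrt(m)
  tcrit <- if (m > 1) qt(0.975, m - 1) else 0
  ci_mean <- rbind(mean_betas - tcrit * se, mean_betas + tcrit * se)
  chosen <- if (interval == "percentile") ci_percentile else ci_mean
  structure(list(
    n_reps = n_reps,
    beta_matrix = beta_matrix,
    mean_betas = mean_betas,
    ci_lower = chosen[1L, ], ci_upper = chosen[2L, ],
    ci_percentile = ci_percentile, ci_mean = ci_mean,
    interval = interval,
    test_aucs = test_aucs[ok & !is.na(test_aucs)],
    test_aucs_by_rep = test_aucs,
    n_failed = n_failed, n_flagged = sum(flagged),
    seed = as.integer(master_seed)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Half-split cross-validated coefficients (", x$n_reps, " repetitions, ",
      x$n_failed, " failed, ", x$n_flagged, " penalised)\n", sep = "")
  tab <- data.frame(mean = x$mean_betas, ci_lower = x$ci_lower,
                    ci_upper = x$ci_upper)
  print(round(tab, 5))
  cat("mean held-out AUC:", round(mean(x$test_aucs), 4), "\n")
  invisible(x)
}

#' Classify a sex difference in one weight
#'
#' Returns \code{"="} when the two 95\% intervals overlap (touching endpoints
#' count as overlap), otherwise \code{">"} if the female weight is larger in
#' absolute value than the male weight, and \code{"<"} if it is smaller.
#'
#' @param ci_female,ci_male Length-2 numeric intervals (any order;
#'   normalized internally).
#' @param mean_f,mean_m The corresponding mean weights.
#' @return One of \code{"<"}, \code{"="}, \code{">"}.
#' @examples
#' compare_weights(c(-0.186, -0.158), c(-0.084, -0.073), -0.172, -0.078)  # ">"
#' @export
compare_weights <- function(ci_female, ci_male, mean_f, mean_m) {
  norm <- function(ci) {
    ci <- as.numeric(ci)
    if (length(ci) != 2L || any(!is.finite(ci))) {
      stop("interval must be two finite numbers", call. = FALSE)
    }
    sort(ci)
  }
  ci_f <- norm(ci_female)
  ci_m <- norm(ci_male)
  if (mean_f < ci_f[1] || mean_f > ci_f[2] ||
      mean_m < ci_m[1] || mean_m > ci_m[2]) {
    stop("interval does not contain its mean", call. = FALSE)
  }
  if (ci_f[1] <= ci_m[2] && ci_m[1] <= ci_f[2]) return("=")
  if (abs(mean_f) > abs(mean_m)) ">" else "<"
}

#' Sex-difference table for two cross-validation results
#'
#' Applies \code{\link{compare_weights}} coefficient-wise to the female and
#' male \code{\link{cv_recalibrate}} results.
#'
#' @param cv_female,cv_male \code{cv_result} objects.
#' @return Data frame with female/male means, intervals, and the
#'   \code{"<"}/\code{"="}/\code{">"} symbol per coefficient.
#' @export
weight_comparison_table <- function(cv_female, cv_male) {
  stopifnot(inherits(cv_female, "cv_result"), inherits(cv_male, "cv_result"))
  nm <- smecki_coef_names()
  symbol <- vapply(nm, function(j) {
    compare_weights(c(cv_female$ci_lower[[j]], cv_female$ci_upper[[j]]),
                    c(cv_male$ci_lower[[j]], cv_male$ci_upper[[j]]),
                    cv_female$mean_betas[[j]], cv_male$mean_betas[[j]])
  }, character(1))
  data.frame(
    coefficient = nm,
    mean_female = unname(cv_female$mean_betas[nm]),
    ci_lower_female = unname(cv_female$ci_lower[nm]),
    ci_upper_female = unname(cv_female$ci_upper[nm]),
    symbol = unname(symbol),
    mean_male = unname(cv_male$mean_betas[nm]),
    ci_lower_male = unname(cv_male$ci_lower[nm]),
    ci_upper_male = unname(cv_male$ci_upper[nm]),
    stringsAsFactors = FALSE
  )
}

#' Export a cross-validation result
#'
#' Writes one CSV row per repetition (7 betas + held-out AUC) and a JSON
#' summary (means, both interval types, failure counts, seed).
#'
#' @param cv A \code{cv_result}.
#' @param path_prefix Files are written as \code{<prefix>_reps.csv} and
#'   \code{<prefix>_summary.json}.
#' @return Invisibly, the two paths.
#' @export
write_cv_result <- function(cv, path_prefix) {
  stopifnot(inherits(cv, "cv_result"))
  reps <- as.data.frame(cv$beta_matrix)
  reps$test_auc <- cv$test_aucs_by_rep
  csv_path <- paste0(path_prefix, "_reps.csv")
  json_path <- paste0(path_prefix, "_summary.json")
  write.csv(reps, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    n_reps = cv$n_reps, n_failed = cv$n_failed, n_flagged = cv$n_flagged,
    seed = cv$seed, interval = cv$interval,
    mean_betas = as.list(cv$mean_betas),
    ci_percentile = list(lower = as.list(cv$ci_percentile[1, ]),
                         upper = as.list(cv$ci_percentile[2, ])),
    ci_mean = list(lower = as.list(cv$ci_mean[1, ]),
                   upper = as.list(cv$ci_mean[2, ])),
    mean_test_auc = mean(cv$test_aucs)
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
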