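# Discrimination and calibration: Mann-Whitney AUC, DeLong comparison of two
# correlated ROC curves via placement values, Hosmer-Lemeshow decile
# calibration, and plot-ready calibration tables.

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1",
                                      call. = FALSE)
  if (all(labels == 0) || all(labels == 1)) {
    stop("degenerate labels: need at least one positive and one negative",
         call. = FALSE)
  }
  as.integer(labels)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Fraction of (positive, negative) pairs in which the positive scores
#' higher, ties counting 1/2. Computed via the rank-sum identity, which is
#' exactly the pair count for untied data and the tie-adjusted count
#' otherwise.
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param labels Binary outcomes aligned with \code{scores}.
#' @return AUC in [0, 1].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels) || any(!is.finite(scores))) {
    stop("scores must be finite and aligned with labels", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties 1/2), and symmetrically for each negative.
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two risk scores evaluated on the same patients using
#' the placement-value (structural components) formulation: the variance of
#' the paired AUC difference is assembled from the empirical covariance of
#' the placement values, z = (AUC_a - AUC_b)/sqrt(var), and the p value is
#' the two-sided normal tail.
#'
#' @param scores_a,scores_b Two score vectors aligned to the same labels.
#' @param labels Binary outcomes; at least 2 positives and 2 negatives.
#' @return Object of class \code{roc_comparison} with fields \code{auc_a},
#'   \code{auc_b}, \code{variance_diff}, \code{z}, \code{p_value}.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("score vectors must be aligned with labels", call. = FALSE)
  }
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("need at least 2 positives and 2 negatives", call. = FALSE)
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  variance_diff <- max(S[1, 1] + S[2, 2] - 2 * S[1, 2], 0)
  diff <- pa$auc - pb$auc
  if (variance_diff <= 0) {
    if (abs(diff) < 1e-12) {
      z <- 0
      p_value <- 1
    } else {
      stop("zero variance of the AUC difference with unequal AUCs: ",
           "numerical degeneracy", call. = FALSE)
    }
  } else {
    z <- diff / sqrt(variance_diff)
    p_value <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 variance_diff = variance_diff, z = z, p_value = p_value),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong comparison: AUC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

# Deterministic risk-decile grouping: stable sort on (predicted, index),
# contiguous chunks with sizes differing by at most one (earlier groups take
# the remainder).
risk_groups <- function(predicted, n_groups) {
  n <- length(predicted)
  if (n < n_groups) stop("need at least n_groups observations", call. = FALSE)
  if (length(unique(predicted)) < n_groups) {
    stop("fewer distinct predicted values than groups; reduce n_groups",
         call. = FALSE)
  }
  ord <- order(predicted, seq_len(n))
  base <- n %/% n_groups
  sizes <- rep(base, n_groups) + as.integer(seq_len(n_groups) <= n %% n_groups)
  group <- integer(n)
  group[ord] <- rep(seq_len(n_groups), times = sizes)
  group
}

check_calibration_inputs <- function(predicted, observed, n_groups) {
  if (any(!is.finite(predicted)) || any(predicted <= 0) || any(predicted >= 1)) {
    stop("predicted probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!all(observed %in% c(0, 1))) stop("observed must be binary 0/1",
                                        call. = FALSE)
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ", call. = FALSE)
  }
  stopifnot(n_groups >= 2L)
}

group_table <- function(predicted, observed, n_groups) {
  group <- risk_groups(predicted, n_groups)
  tab <- data.frame(
    group = seq_len(n_groups),
    n = as.integer(tabulate(group, n_groups)),
    mean_predicted = as.numeric(tapply(predicted, group, mean)),
    observed_events = as.integer(tapply(observed, group, sum)),
    expected_events = as.numeric(tapply(predicted, group, sum))
  )
  tab$observed_rate <- tab$observed_events / tab$n
  tab
}

#' Hosmer-Lemeshow calibration test over risk deciles
#'
#' Divides the sample into \code{n_groups} quantile groups of predicted risk
#' and compares observed with expected events in each:
#' statistic = sum over groups of (O - E)^2 / (E (1 - pbar)), with pbar the
#' group mean predicted risk, referred to a chi-square distribution with
#' \code{n_groups - 2} degrees of freedom (the external-validation variant
#' \code{n_groups - 1} is available via \code{df_variant}).
#'
#' Groups with expected counts within 0.5 of 0 or of the group size use a
#' continuity floor of 0.5 in the denominator, with a warning, rather than
#' failing.
#'
#' @param predicted Predicted probabilities in (0, 1).
#' @param observed Binary outcomes.
#' @param n_groups Number of risk groups (default 10, i.e. deciles).
#' @param df_variant \code{"fit"} for g - 2 df (default) or
#'   \code{"validation"} for g - 1.
#' @return Object of class \code{calibration_table}: per-group table,
#'   \code{hl_statistic}, \code{df}, \code{p_value}.
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10L,
                            df_variant = c("fit", "validation")) {
  df_variant <- match.arg(df_variant)
  check_calibration_inputs(predicted, observed, n_groups)
  tab <- group_table(predicted, observed, n_groups)
  E <- tab$expected_events
  n_g <- tab$n
  pbar <- tab$mean_predicted
  degenerate <- E < 0.5 | (n_g - E) < 0.5
  if (any(degenerate)) {
    warning(sum(degenerate), " group(s) with near-degenerate expected ",
            "counts; continuity floor of 0.5 applied", call. = FALSE)
  }
  denom <- pmax(E, 0.5) * pmax(1 - pbar, 0.5 / n_g)
  terms <- (tab$observed_events - E)^2 / denom
  statistic <- sum(terms)
  df <- n_groups - ifelse(df_variant == "fit", 2L, 1L)
  structure(list(
    groups = tab,
    hl_statistic = statistic,
    df = as.integer(df),
    p_value = pchisq(statistic, df, lower.tail = FALSE)
  ), class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.4g\n",
              x$hl_statistic, x$df, x$p_value))
  print(round(x$groups[, c("group", "n", "mean_predicted",
                           "observed_events", "expected_events")], 4))
  invisible(x)
}

#' ROC curve points
#'
#' Sensitivity/specificity pairs at every distinct score threshold,
#' plot-ready and exportable as CSV.
#'
#' @inheritParams auc
#' @return Data frame with columns \code{threshold, tpr, fpr}, ordered from
#'   the most permissive to the strictest threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labels(labels)
  thresholds <- sort(unique(scores))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  data.frame(threshold = c(-Inf, thresholds, Inf), tpr = c(1, tpr, 0),
             fpr = c(1, fpr, 0))
}

#' Plot-ready calibration table
#'
#' Per-risk-group mean predicted probability versus observed event rate,
#' using the same decile convention as \code{\link{hosmer_lemeshow}}. Points
#' on the identity line indicate perfect calibration.
#'
#' @inheritParams hosmer_lemeshow
#' @return Data frame with columns \code{group, n, mean_predicted,
#'   observed_rate, observed_events, expected_events}, ordered by increasing
#'   predicted risk.
#' @export
calibration_curve <- function(predicted, observed, n_groups = 10L) {
  check_calibration_inputs(predicted, observed, n_groups)
  tab <- group_table(predicted, observed, n_groups)
  tab[, c("group", "n", "mean_predicted", "observed_rate",
          "observed_events", "expected_events")]
}
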