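# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

covariate_names <- c("peakvo2_pct", "vevco2_slope", "hb", "na", "lvef",
                     "mdrd")

# All-pairs concordance count (ties 1/2), the defining AUC formula:
# count of concordant pairs over total pairs.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  count <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  count / (length(pos) * length(neg))
}

# Two-parameter (intercept, slope) logistic log-likelihood grid search,
# refined in stages down to a grid step below 1e-4.
grid_fit_logistic <- function(x, y) {
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  center <- c(0, 0)
  width <- c(8, 8)
  for (stage in 1:5) {
    as <- seq(center[1] - width[1], center[1] + width[1], length.out = 41)
    bs <- seq(center[2] - width[2], center[2] + width[2], length.out = 41)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(loglik, grid$a, grid$b)
    best <- which.max(vals)
    center <- c(grid$a[best], grid$b[best])
    width <- width * 0.075  # next grid spans +/- 1.5 old steps
  }
  center
}

# Paired stratified bootstrap test of the AUC difference: normal reference
# with bootstrap standard error of the difference.
bootstrap_auc_diff_p <- function(scores_a, scores_b, labels, B = 20000) {
  ip <- which(labels == 1)
  i0 <- which(labels == 0)
  d0 <- pair_count_auc(scores_a, labels) - pair_count_auc(scores_b, labels)
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    j1 <- sample(ip, replace = TRUE)
    j0 <- sample(i0, replace = TRUE)
    idx <- c(j1, j0)
    yy <- c(rep(1L, length(j1)), rep(0L, length(j0)))
    diffs[b] <- pair_count_auc(scores_a[idx], yy) -
      pair_count_auc(scores_b[idx], yy)
  }
  2 * pnorm(-abs(d0) / sd(diffs))
}

# Small deterministic two-sex cohort without using the generator.
toy_cohort <- function(n_per_sex = 30, seed = 123) {
  set.seed(seed)
  n <- 2 * n_per_sex
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = rep(c("F", "M"), each = n_per_sex),
    lvef = runif(n, 20, 50), hb = runif(n, 10, 16),
    mdrd = runif(n, 40, 100), na = runif(n, 132, 146),
    vevco2_slope = runif(n, 25, 45), peakvo2_pct = runif(n, 30, 90),
    event = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE
  )
}

zero_patient <- function(sex = "F") {
  list(sex = sex, peakvo2_pct = 0, vevco2_slope = 0, hb = 0, na = 0,
       lvef = 0, mdrd = 0)
}

# Table of published cross-validated weights: per-sex means and 95%
# intervals, with the printed between-sex symbols, in the order
# (intercept, LVEF, Hb, MDRD, Na, VE/VCO2 slope, peakVO2 % predicted).
published_weight_table <- function() {
  data.frame(
    variable = c("intercept", "lvef", "hb", "mdrd", "na", "vevco2_slope",
                 "peakvo2_pct"),
    mean_f = c(4.111, -0.027, -0.172, -0.009, -0.017, 0.025, -0.034),
    lo_f = c(3.116, -0.03, -0.186, -0.01, -0.024, 0.022, -0.035),
    hi_f = c(5.107, -0.025, -0.158, -0.007, -0.01, 0.027, -0.032),
    mean_m = c(9.79, -0.036, -0.078, -0.011, -0.059, 0.028, -0.047),
    lo_m = c(9.465, -0.037, -0.084, -0.011, -0.061, 0.027, -0.047),
    hi_m = c(10.115, -0.035, -0.073, -0.01, -0.057, 0.029, -0.046),
    symbol = c("<", "<", ">", "=", "<", "=", "<"),
    stringsAsFactors = FALSE
  )
}
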