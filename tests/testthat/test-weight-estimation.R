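test_that("half splits partition the cohort with the ceil/floor convention", {
  co4 <- toy_cohort(2)  # 4 rows
  set.seed(1)
  sp <- half_split(co4)
  expect_length(sp$training, 2)
  expect_length(sp$testing, 2)
  expect_length(intersect(sp$training, sp$testing), 0)
  expect_setequal(c(sp$training, sp$testing), 1:4)

  co5 <- toy_cohort(3)[1:5, ]
  set.seed(1)
  sp5 <- half_split(co5)
  expect_length(sp5$training, 3)
  expect_length(sp5$testing, 2)

  set.seed(99)
  a <- half_split(co5)
  set.seed(99)
  b <- half_split(co5)
  expect_identical(a, b)

  expect_error(half_split(co5[1, , drop = FALSE]), "at least 2")
})

test_that("stratified splits keep the size contract and balance events", {
  co <- toy_cohort(50)
  set.seed(5)
  sp <- half_split(co, stratified = TRUE)
  expect_length(sp$training, 50)
  n_ev_train <- sum(co$event[sp$training])
  expect_lt(abs(n_ev_train - sum(co$event) / 2), 2)
})

test_that("fit_logistic matches closed-form solutions", {
  # intercept-only: the MLE is the logit of the event rate
  x0 <- matrix(numeric(0), nrow = 10, ncol = 0)
  f1 <- fit_logistic(x0, c(rep(1, 5), rep(0, 5)))
  expect_equal(unname(f1$coefficients[1]), 0, tolerance = 1e-8)
  f2 <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0),
                     c(rep(1, 20), rep(0, 80)))
  expect_equal(unname(f2$coefficients[1]), log(0.25), tolerance = 1e-8)
  # one binary covariate: slope is the log odds ratio of the 2x2 table
  x <- matrix(c(rep(0, 50), rep(1, 50)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 20), rep(0, 30))
  f3 <- fit_logistic(x, y)
  expect_equal(unname(f3$coefficients), c(log(10 / 40), log(8 / 3)),
               tolerance = 1e-6)
  # degenerate outcomes and rank deficiency error out
  expect_error(fit_logistic(x, rep(1, 100)), "degenerate")
  expect_error(fit_logistic(cbind(x, x2 = 2 * x[, 1]), y), "rank")
})

test_that("fit_logistic agrees with a likelihood grid-search oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    if (sum(y) < 3 || sum(y) > n - 3) next
    fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
    oracle <- grid_fit_logistic(x, y)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 2e-4)
  }
})

test_that("separation triggers the penalised fallback instead of failing", {
  x <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(x, y)
  expect_true(fit$flagged)
  expect_true(all(is.finite(fit$coefficients)))
  # the penalised slope is large but finite
  expect_gt(fit$coefficients[["x"]], 1)
})

test_that("cv_recalibrate is deterministic and averages its repetitions", {
  co <- generate_cohort(cohort_spec(n_female = 0, n_male = 600, seed = 13))
  cv1 <- suppressWarnings(cv_recalibrate(co, n_reps = 15, master_seed = 7))
  cv2 <- suppressWarnings(cv_recalibrate(co, n_reps = 15, master_seed = 7))
  expect_identical(cv1$beta_matrix, cv2$beta_matrix)
  expect_identical(cv1$test_aucs, cv2$test_aucs)
  expect_false(identical(
    cv1$beta_matrix,
    suppressWarnings(cv_recalibrate(co, n_reps = 15,
                                    master_seed = 8))$beta_matrix))
  # a single repetition is its own mean
  cv_one <- suppressWarnings(cv_recalibrate(co, n_reps = 1, master_seed = 7))
  expect_equal(cv_one$mean_betas, cv_one$beta_matrix[1, ], tolerance = 1e-15)
  expect_equal(unname(cv_one$ci_lower), unname(cv_one$beta_matrix[1, ]),
               tolerance = 1e-12)
  # interval invariants
  expect_true(all(cv1$ci_lower <= cv1$mean_betas + 1e-12))
  expect_true(all(cv1$mean_betas <= cv1$ci_upper + 1e-12))
  expect_true(all(cv1$test_aucs >= 0 & cv1$test_aucs <= 1))
  expect_length(cv1$test_aucs, 15 - cv1$n_failed)
})

test_that("cv_recalibrate rejects mixed-sex cohorts and degenerate ones", {
  co <- toy_cohort(30)
  expect_error(suppressWarnings(cv_recalibrate(co)), "single-sex")
  tiny <- toy_cohort(30)[1:8, ]
  tiny$sex <- "F"
  tiny$event <- c(1L, rep(0L, 7))
  expect_error(suppressWarnings(cv_recalibrate(tiny, n_reps = 40,
                                               master_seed = 2)),
               "25%")
})

test_that("mean betas are consistent for the generating coefficients", {
  n <- 50000
  spec <- cohort_spec(n_female = 0, n_male = n, seed = 17)
  co <- generate_cohort(spec)
  fit <- fit_logistic(co, co$event)
  truth <- spec$sexes$M$coefficients$coefficients
  # standard errors from the observed information at the fit
  X <- cbind(1, as.matrix(co[, covariate_names]))
  p_hat <- plogis(drop(X %*% fit$coefficients))
  se <- sqrt(diag(solve(crossprod(X, X * (p_hat * (1 - p_hat))))))
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})

test_that("permuting patient order moves splits but not the weights", {
  co <- generate_cohort(cohort_spec(n_female = 0, n_male = 3000, seed = 19))
  cv_a <- cv_recalibrate(co, n_reps = 40, master_seed = 23)
  set.seed(29)
  co_perm <- co[sample.int(nrow(co)), ]
  rownames(co_perm) <- NULL
  cv_b <- cv_recalibrate(co_perm, n_reps = 40, master_seed = 23)
  expect_false(identical(cv_a$beta_matrix, cv_b$beta_matrix))
  mc_se <- apply(cv_a$beta_matrix, 2, sd) / sqrt(40)
  expect_true(all(abs(cv_a$mean_betas - cv_b$mean_betas) < 5 * sqrt(2) * mc_se))
})

test_that("compare_weights classifies interval overlap and magnitude", {
  # published hemoglobin row: female weight larger in magnitude
  expect_identical(
    compare_weights(c(-0.186, -0.158), c(-0.084, -0.073), -0.172, -0.078),
    ">")
  # touching endpoints count as overlap
  expect_identical(
    compare_weights(c(-0.01, -0.007), c(-0.011, -0.01), -0.009, -0.011),
    "=")
  expect_identical(
    compare_weights(c(-0.03, -0.025), c(-0.037, -0.035), -0.027, -0.036),
    "<")
  # interval order is normalized; malformed inputs error
  expect_identical(
    compare_weights(c(-0.158, -0.186), c(-0.073, -0.084), -0.172, -0.078),
    ">")
  expect_error(compare_weights(c(0, 1), c(2, 3), 1.5, 2.5), "contain")
  expect_error(compare_weights(c(0, NA), c(2, 3), 0, 2.5), "finite")
})

test_that("cv results export per-repetition CSV plus a JSON summary", {
  co <- generate_cohort(cohort_spec(n_female = 0, n_male = 500, seed = 37))
  cv <- suppressWarnings(cv_recalibrate(co, n_reps = 8, master_seed = 3))
  prefix <- tempfile()
  paths <- write_cv_result(cv, prefix)
  reps <- read.csv(paste0(prefix, "_reps.csv"))
  expect_equal(nrow(reps), 8)
  expect_identical(names(reps),
                   c("intercept", covariate_names, "test_auc"))
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(summ$n_reps, 8)
  expect_equal(unlist(summ$mean_betas), cv$mean_betas, tolerance = 1e-12)
  unlink(paste0(prefix, c("_reps.csv", "_summary.json")))
})
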