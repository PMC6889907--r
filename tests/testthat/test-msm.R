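test_that("IRLS solves the analytic intercept-only problem and matches glm", {
  y <- c(rep(1, 25), rep(0, 75))
  fit <- fit_weighted_logistic(y, matrix(1, 100, 1, dimnames = list(NULL, "i")))
  expect_equal(unname(fit$coef), log(1 / 3), tolerance = 1e-9)
  # rescaling the weights leaves the estimate unchanged
  fit2 <- fit_weighted_logistic(y, matrix(1, 100), weights = rep(7, 100))
  expect_equal(unname(fit2$coef), log(1 / 3), tolerance = 1e-9)

  set.seed(61)
  n <- 800
  x <- stats::rnorm(n)
  w <- stats::runif(n, 0.5, 2)
  yy <- stats::rbinom(n, 1, stats::plogis(-1 + 0.7 * x))
  X <- cbind(1, x)
  mine <- fit_weighted_logistic(yy, X, w)
  ref <- suppressWarnings(stats::glm.fit(X, yy, weights = w,
                                         family = stats::binomial()))
  expect_equal(unname(mine$coef), unname(ref$coefficients), tolerance = 1e-8)
})

test_that("IRLS reports rank deficiency and separation", {
  y <- c(0, 0, 1, 1)
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(fit_weighted_logistic(y, X), "rank deficient")
  # perfect separation: either flagged on the returned fit or a hard failure
  Xs <- cbind(1, c(-2, -1, 1, 2))
  res <- tryCatch(fit_weighted_logistic(y, Xs, max_iter = 30),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "separation|converge")
  } else {
    expect_true(res$separation)
  }
})

test_that("weighted logistic recovers known coefficients at scale", {
  set.seed(62)
  n <- 50000
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.3)
  beta <- c(-2, 0.5, -0.8)
  y <- stats::rbinom(n, 1, stats::plogis(cbind(1, x1, x2) %*% beta))
  fit <- fit_weighted_logistic(y, cbind(1, x1, x2))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - beta) <= 3 * se))
})

test_that("predicted prevalence averages fitted probabilities correctly", {
  set.seed(63)
  n <- 2000
  q <- sample(1:5, n, TRUE)
  w <- stats::runif(n, 0.5, 2)
  y <- stats::rbinom(n, 1, stats::plogis(-2 + 0.2 * q))

  # zero-information model: balanced outcome, intercept only
  yb <- rep(c(0, 1), n / 2)
  f0 <- fit_weighted_logistic(yb, matrix(1, n, 1))
  expect_equal(predicted_prevalence(f0, q)$overall, 0.5, tolerance = 1e-9)
  expect_equal(predicted_prevalence(f0, q)$by_quintile, rep(0.5, 5),
               tolerance = 1e-9)

  # saturated quintile model reproduces observed weighted prevalences
  Xq <- stats::model.matrix(~ factor(q))
  fs <- fit_weighted_logistic(y, Xq, w)
  pp <- predicted_prevalence(fs, q, w)
  direct <- vapply(1:5, function(k) stats::weighted.mean(y[q == k], w[q == k]),
                   numeric(1))
  expect_equal(pp$by_quintile, direct, tolerance = 1e-7)
  expect_equal(pp$overall, stats::weighted.mean(y, w), tolerance = 1e-7)
})

test_that("inequality summary is null under the null and invariant to affine recoding", {
  set.seed(64)
  n <- 4000
  q <- sample(1:5, n, TRUE)
  y <- stats::rbinom(n, 1, 0.2)
  X <- cbind(intercept = 1, income_q = q)
  fit <- fit_weighted_logistic(y, X)
  s <- inequality_summary(fit)
  expect_lt(abs(log(s$rr)), 3 * s$se_log_rr)
  expect_lt(abs(s$rd), 3 * s$se_rd)

  # affine recoding of the quintile axis leaves RR/RD at the extremes alone
  y2 <- stats::rbinom(n, 1, stats::plogis(-2.2 + 0.3 * q))
  f1 <- fit_weighted_logistic(y2, cbind(1, q))
  f2 <- fit_weighted_logistic(y2, cbind(1, 2 * q - 3))
  p_at <- function(f, codes) vapply(codes, function(k)
    mean(stats::plogis(f$coef[1] + f$coef[2] * k)), numeric(1))
  expect_equal(p_at(f1, c(1, 5)), p_at(f2, c(-1, 7)), tolerance = 1e-8)
})

test_that("TDE sits between crude and CDE on the confounded default generator", {
  cfg <- small_config(50000)
  co <- generate_cohort(cfg, 42)
  crude <- estimate_crude(co)
  tde <- estimate_tde(co)
  cde <- estimate_cde(co)
  expect_lt(cde$rr, tde$rr)
  expect_lt(tde$rr, crude$rr)
  expect_lt(cde$rd, crude$rd)
  # fitted mediator coefficient is negative: activity is protective
  expect_lt(cde$fit$coef[["bc_mvpa"]], 0)
})

test_that("an inert mediator coefficient makes scenario predictions equal observed CDE", {
  cfg <- small_config(8000)
  co <- generate_cohort(cfg, 43)
  cde <- estimate_cde(co)
  fit0 <- cde$fit
  fit0$coef[["bc_mvpa"]] <- 0
  X30 <- fit0$X
  X30[, "bc_mvpa"] <- boxcox_transform(co$mvpa_min + 30, 0.34)
  expect_equal(predicted_prevalence(fit0, co$income_q, X = X30)$overall,
               predicted_prevalence(fit0, co$income_q)$overall,
               tolerance = 1e-12)
})

test_that("raising everyone's MVPA cannot raise predicted prevalence", {
  cfg <- small_config(20000)
  co <- generate_cohort(cfg, 44)
  ws <- build_weights(co, "cde")
  base <- estimate_cde(co, weight_set = ws)
  for (add in c(5, 15, 30)) {
    up <- estimate_cde(co, mediator_policy = rep(add, nrow(co)), weight_set = ws)
    expect_lte(up$overall_prevalence, base$overall_prevalence)
  }
})

test_that("bootstrap CIs are deterministic, degenerate for constants, and cover the null", {
  cfg <- small_config(1500)
  co <- generate_cohort(cfg, 45)
  stat <- function(d) c(prev = stats::weighted.mean(
    internalizing_case(d$internalizing_score), d$design_weight))
  b1 <- bootstrap_ci(stat, co, reps = 50, seed = 9)
  b2 <- bootstrap_ci(stat, co, reps = 50, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low[["prev"]] < b1$ci_high[["prev"]])

  bc0 <- bootstrap_ci(function(d) c(k = 1.5), co, reps = 20, seed = 1)
  expect_equal(bc0$ci_low[["k"]], bc0$ci_high[["k"]])

  flaky <- function(d) { if (d$child_id[1] %% 3 == 0) stop("boom"); c(s = 1) }
  bf <- bootstrap_ci(flaky, co, reps = 30, seed = 2)
  expect_equal(bf$reps_used + bf$failures, 30)
  expect_gt(bf$failures, 0)

  # null generator: the 95% rd interval covers zero in most repeated runs
  cfgn <- null_config(1500)
  cover <- 0L
  for (i in 1:15) {
    con <- generate_cohort(cfgn, 100 + i)
    statrd <- function(d) c(rd = estimate_crude(d)$rd)
    ci <- bootstrap_ci(statrd, con, reps = 60, seed = i)
    if (ci$ci_low[["rd"]] <= 0 && ci$ci_high[["rd"]] >= 0) cover <- cover + 1L
  }
  expect_gte(cover, 12L)
})
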