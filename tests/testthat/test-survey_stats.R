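test_that("weighted descriptives reduce to plain statistics under equal weights", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  d <- survey_design(rep(1, 8), 1:8, rep(1, 8))
  ms <- weighted_descriptives(x, d, "mean_sd")
  expect_equal(unname(ms["mean"]), mean(x))
  expect_equal(unname(ms["sd"]), sqrt(mean((x - mean(x))^2)))
  mq <- weighted_descriptives(x, d, "median_iqr")
  expect_equal(unname(mq["median"]), oracle_quantile(x, 0.5))
})

test_that("weighted mean follows hand arithmetic", {
  d <- survey_design(rep(1, 3), 1:3, c(1, 1, 2))
  ms <- weighted_descriptives(c(0, 0, 3), d, "mean_sd")
  expect_equal(unname(ms["mean"]), 1.5)
})

test_that("category percentages are weighted and sum to 100", {
  set.seed(2)
  x <- factor(sample(letters[1:4], 40, replace = TRUE),
              levels = letters[1:5])
  d <- survey_design(rep(1:2, 20), rep(1:4, 10), runif(40, 0.5, 3))
  tab <- weighted_descriptives(x, d, "category_pct")
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_equal(sum(tab$n), 40L)
  expect_equal(tab$n[tab$level == "e"], 0L)  # empty level kept with zero count
})

test_that("degenerate design recovers ordinary least squares", {
  set.seed(4)
  n <- 30
  x <- rnorm(n)
  y <- 2 + 0.7 * x + rnorm(n, 0, 0.5)
  X <- cbind(1, x)
  d <- survey_design(rep(1, n), seq_len(n), rep(1, n))
  fit <- survey_lm(y, X, d)
  ols <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$beta, as.numeric(ols), tolerance = 1e-12)
  expect_equal(fit$df, n - 1L)
})

test_that("linearization covariance matches the loop-based oracle exactly", {
  d <- fixed_svy_data()
  X <- cbind(`(Intercept)` = 1, x = d$x)
  des <- survey_design(d$stratum, d$psu, d$w)
  fit <- survey_lm(d$y, X, des)
  orc <- oracle_linearization(d$y, X, d$w, d$stratum, d$psu)
  expect_equal(fit$coefficients$beta, orc$beta, tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(orc$V), tolerance = 1e-10)
  expect_equal(fit$df, 4L - 2L)
  # CI half-width is the t quantile times the SE and contains the estimate
  co <- fit$coefficients
  expect_equal(co$ci_high - co$beta, qt(0.975, fit$df) * co$se)
  expect_true(all(co$ci_low < co$beta & co$beta < co$ci_high))
})

test_that("point estimates are invariant to row duplication at half weight", {
  d <- fixed_svy_data()
  X <- cbind(1, d$x)
  des <- survey_design(d$stratum, d$psu, d$w)
  fit1 <- survey_lm(d$y, X, des)
  d2 <- rbind(d, d); d2$w <- d2$w / 2
  des2 <- survey_design(d2$stratum, d2$psu, d2$w)
  fit2 <- survey_lm(d2$y, cbind(1, d2$x), des2)
  expect_equal(fit2$coefficients$beta, fit1$coefficients$beta,
               tolerance = 1e-12)
})

test_that("variance is invariant to relabeling strata and PSUs", {
  d <- fixed_svy_data()
  X <- cbind(1, d$x)
  fit1 <- survey_lm(d$y, X, survey_design(d$stratum, d$psu, d$w))
  relab <- survey_design(paste0("S", d$stratum * 7),
                         paste0("P", d$psu * 3 + 1), d$w)
  fit2 <- survey_lm(d$y, X, relab)
  expect_equal(unname(fit2$vcov), unname(fit1$vcov), tolerance = 1e-12)
})

test_that("with one PSU per observation the estimator matches the HC sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(8)
  n <- 40
  x <- rnorm(n)
  y <- 1 + 0.3 * x + rnorm(n)
  des <- survey_design(rep(1, n), seq_len(n), rep(1, n))
  fit <- survey_lm(y, cbind(`(Intercept)` = 1, x = x), des)
  lmfit <- lm(y ~ x)
  hc0 <- sandwich::vcovHC(lmfit, type = "HC0")
  # the stratified estimator applies the n/(n-1) cluster factor to HC0
  expect_equal(unname(fit$vcov), unname(hc0) * n / (n - 1),
               tolerance = 1e-10)
})

test_that("singular designs and lonely PSUs are explicit errors", {
  d <- fixed_svy_data()
  X <- cbind(1, d$x, 2 * d$x)
  des <- survey_design(d$stratum, d$psu, d$w)
  expect_error(survey_lm(d$y, X, des), "collinear")

  lone <- d; lone$psu[lone$stratum == 2] <- 1
  des_l <- survey_design(lone$stratum, lone$psu, lone$w)
  expect_error(survey_lm(d$y, cbind(1, d$x), des_l), "lonely PSU")
  fit <- survey_lm(d$y, cbind(1, d$x), des_l, lonely_psu = "adjust")
  expect_true(all(is.finite(fit$coefficients$se)))

  expect_error(survey_design(1:3, 1:3, c(1, -1, 1)), "positive")
})

test_that("trend test detects a planted monotone signal and not its permutation", {
  set.seed(14)
  n <- 400
  q <- factor(paste0("Q", sample(1:4, n, replace = TRUE)),
              levels = paste0("Q", 1:4), ordered = TRUE)
  y <- 0.05 * as.integer(q) + rnorm(n, 0, 0.05)
  des <- survey_design(rep(1:4, length.out = n), rep(1:8, length.out = n),
                       rep(1, n))
  fit <- trend_test(y, q, NULL, des)
  tr <- fit$coefficients[fit$coefficients$term == "trend", ]
  expect_gt(tr$beta, 0)
  expect_lt(tr$p_value, 0.05)

  qp <- sample(q)
  fitp <- trend_test(y, qp, NULL, des)
  trp <- fitp$coefficients[fitp$coefficients$term == "trend", ]
  expect_gt(trp$p_value, 0.05)

  # quartile-median coding is available and monotone-equivalent in sign
  fitm <- trend_test(y, q, NULL, des, coding = "median",
                     score = as.integer(q) * 10)
  trm <- fitm$coefficients[fitm$coefficients$term == "trend", ]
  expect_gt(trm$beta, 0)
})
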