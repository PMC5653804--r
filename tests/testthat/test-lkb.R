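test_that("LKB probability and its inverse reproduce the planning thresholds", {
  expect_equal(lkb_probability(15.07, 15.07, 0.62), 0.5)
  expect_equal(lkb_probability(8.77, 15.07, 0.62), 0.25, tolerance = 2e-3)
  expect_equal(lkb_probability(0, 15.07, 0.62), pnorm(-1 / 0.62))
  expect_equal(invert_lkb(0.5, 15.07, 0.62), 15.07)
  expect_equal(round(invert_lkb(0.25, 15.07, 0.62), 1), 8.8)
  for (p in seq(0.01, 0.99, by = 0.07))
    expect_equal(lkb_probability(invert_lkb(p, 15.07, 0.62), 15.07, 0.62),
                 p, tolerance = 1e-10)
  expect_error(invert_lkb(1.2, 15.07, 0.62), "\\(0, 1\\)")
})

test_that("LKB probability is monotone in factor and in TV50", {
  set.seed(2)
  for (i in 1:10) {
    tv <- runif(1, 5, 40); m <- runif(1, 0.1, 2)
    x <- sort(runif(50, 0, 60))
    p <- lkb_probability(x, tv, m)
    expect_true(all(diff(p) >= 0))
    core <- p > 1e-12 & p < 1 - 1e-12       # away from double saturation
    expect_true(all(diff(p[core]) > 0))
    tvs <- sort(runif(20, 5, 40))
    q <- lkb_probability(20, tvs, m)
    expect_true(all(diff(q) <= 0))
    expect_true(all(diff(q[q > 1e-12 & q < 1 - 1e-12]) < 0))
  }
})

test_that("maximum-likelihood fit beats a brute-force grid on a hand dataset", {
  x <- c(3, 8, 12, 16, 22, 30)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_lkb(x, y)
  # dense (TV50, m) grid oracle
  grid_ll <- -Inf
  for (tv in seq(1, 60, length.out = 200))
    for (m in seq(0.05, 5, length.out = 200)) {
      p <- pmin(pmax(pnorm((x - tv) / (m * tv)), 1e-12), 1 - 1e-12)
      ll <- sum(y * log(p) + (1 - y) * log(1 - p))
      grid_ll <- max(grid_ll, ll)
    }
  expect_gte(fit$loglik, grid_ll)
  # CI brackets the estimate, profile cutoff achieved to 1e-3
  expect_true(all(fit$ci[, "lower"] <= coef(fit)))
  expect_true(all(fit$ci[, "upper"] >= coef(fit)))
  interior <- abs(fit$profile_delta - qchisq(0.95, 1)) < 1e-3
  expect_true(all(interior | fit$ci %in% c(0.01, 10, 10 * max(x))))
})

test_that("degenerate designs are rejected", {
  expect_error(fit_lkb(rep(10, 20), rbinom(20, 1, 0.5)), "identifiable")
  expect_error(fit_lkb(1:10, rep(0, 10)), "at least one event")
  expect_error(fit_lkb(1:10, rep(1, 10)), "at least one event")
})

test_that("the fit object supports the standard modelling verbs", {
  set.seed(3)
  x <- runif(250, 2, 35)
  y <- rbinom(250, 1, lkb_probability(x, 15, 0.6))
  fit <- fit_lkb(y ~ v40, data = data.frame(v40 = x, y = y))
  expect_named(coef(fit), c("TV50", "m"))
  expect_equal(fit$factor_name, "v40")
  expect_equal(unname(predict(fit, coef(fit)[["TV50"]])), 0.5)
  expect_equal(predict(fit, newdata = data.frame(v40 = x[1:5])),
               fitted(fit)[1:5])
  expect_equal(dim(confint(fit)), c(2L, 2L))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  r <- residuals(fit)
  expect_equal(sign(r), sign(y - fitted(fit)))
  expect_equal(sum(residuals(fit, "response")), sum(y - fitted(fit)))
  set.seed(9)
  sims <- simulate(fit, nsim = 3)
  expect_equal(dim(sims), c(250L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(fit), "TV50")
  expect_output(print(summary(fit)), "AUC")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("AUC equals explicit pair enumeration and is rank-invariant", {
  expect_equal(auc(c(0.2, 0.8), c(0, 1)), 1)
  expect_equal(auc(rep(0.4, 10), rbinom(10, 1, 0.5) * 0 + c(rep(0, 5), rep(1, 5))),
               0.5)
  pred <- c(0.1, 0.4, 0.35, 0.8, 0.4)
  y <- c(0, 0, 1, 1, 1)
  # explicit concordant / discordant / tied count
  num <- 0
  for (i in which(y == 1)) for (j in which(y == 0))
    num <- num + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
  expect_equal(auc(pred, y), num / (3 * 2))
  expect_equal(auc(qlogis(pred), y), auc(pred, y))
  expect_error(auc(pred, rep(1, 5)), "both classes")
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(4)
  pred <- runif(100)
  y <- rbinom(100, 1, pred)
  expect_equal(auc(pred, y),
               as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE))))
})

test_that("Hosmer-Lemeshow matches a hand-computed 3-group example", {
  # groups engineered by distinct prediction levels
  pred <- rep(c(0.1, 0.5, 0.9), each = 4)
  y <- c(1, 0, 0, 0,  1, 1, 0, 0,  1, 1, 1, 1)
  hl <- hosmer_lemeshow(pred, y, groups = 3)
  # hand: per group n=4, E = 0.4, 2.0, 3.6; O = 1, 2, 4
  stat_hand <- (1 - 0.4)^2 / (0.4 * (1 - 0.4 / 4)) +
    (2 - 2)^2 / (2 * (1 - 2 / 4)) +
    (4 - 3.6)^2 / (3.6 * (1 - 3.6 / 4))
  expect_equal(hl$statistic, stat_hand, tolerance = 1e-10)
  expect_equal(hl$df, 1)
  expect_equal(hl$p_value, pchisq(stat_hand, 1, lower.tail = FALSE))
  # perfect calibration at group level -> statistic 0, p = 1
  pred2 <- rep(c(0.25, 0.75), each = 4)
  y2 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  hl2 <- hosmer_lemeshow(pred2, y2, groups = 2)
  expect_equal(hl2$statistic, 0)
  expect_equal(hl2$p_value, 1)
})

test_that("the Hosmer-Lemeshow statistic has its chi-square null distribution", {
  # With externally specified true probabilities the statistic is
  # approximately chi-square with `groups` df (the groups - 2 correction
  # reported by the function applies to within-sample fitted models).
  set.seed(11)
  stats <- replicate(400, {
    pred <- runif(150, 0.05, 0.95)
    y <- rbinom(150, 1, pred)
    hosmer_lemeshow(pred, y, groups = 10)$statistic
  })
  ps <- pchisq(stats, df = 10, lower.tail = FALSE)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("scaled Brier score matches hand computation", {
  y <- c(0, 1, 1, 0)
  expect_equal(scaled_brier(rep(0.5, 4), y), 0)
  expect_equal(scaled_brier(y, y), 1)
  pred <- c(0.2, 0.7, 0.9, 0.4)
  bs <- mean((pred - y)^2)
  expect_equal(scaled_brier(pred, y), 1 - bs / 0.25, tolerance = 1e-12)
  expect_error(scaled_brier(pred, rep(0, 4)), "both classes")
})

test_that("calibration slope recovers 1 for honest predictions and 0.5 for doubled logits", {
  set.seed(13)
  pred <- plogis(rnorm(5000, 0, 1.2))
  y <- rbinom(5000, 1, pred)
  cal <- calibration_slope(pred, y)
  expect_lt(abs(cal$slope - 1), 0.1)
  expect_lt(abs(cal$intercept), 0.1)
  over <- plogis(2 * qlogis(pred))
  cal2 <- calibration_slope(over, y)
  expect_lt(abs(cal2$slope - 0.5), 0.06)
  expect_error(calibration_slope(rep(0.3, 10), rbinom(10, 1, 0.3)),
               "constant")
})
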