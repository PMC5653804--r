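test_that("intercept-only propensity equals the observed arm fraction", {
  co <- small_cohort(seed = 2, n_per_arm = 50, organs = character(0))
  ps <- fit_propensity(co, covariates = character(0))
  expect_equal(unique(round(ps$p, 12)),
               round(mean(co$patients$modality == "VMAT"), 12))
})

test_that("independent covariates give null coefficients and AUC near 0.5", {
  co <- generate_cohort(synth_config(n_per_arm = 500, seed = 21,
                                     confounding = 0,
                                     organs = character(0)))
  ps <- fit_propensity(co)
  expect_true(all(abs(coef(ps$model)[-1] *
                        apply(co$patients[, ps$covariates], 2, sd)) < 0.15))
  a <- auc(ps$p, as.integer(co$patients$modality == "VMAT"))
  expect_lt(abs(a - 0.5), 0.05)
})

test_that("perfect separation is flagged with the offending covariate", {
  co <- small_cohort(seed = 3, n_per_arm = 20, organs = character(0))
  co$patients$leak <- as.integer(co$patients$modality == "VMAT")
  expect_error(fit_propensity(co, covariates = c("age", "leak")),
               "separation.*leak")
})

test_that("identical score multisets match every treated unit at distance 0", {
  p <- rep(c(0.2, 0.4, 0.6, 0.8), 2)
  treated <- rep(c(TRUE, FALSE), each = 4)
  m <- match_caliper(p, treated)
  expect_equal(nrow(m$pairs), 4)
  expect_equal(max(m$pairs$distance), 0)
  expect_length(m$unmatched, 0)
})

test_that("units beyond the caliper stay unmatched", {
  p <- c(0.95, 0.50, 0.51, 0.49)
  treated <- c(TRUE, TRUE, FALSE, FALSE)
  m <- match_caliper(p, treated, ids = c("t1", "t2", "c1", "c2"))
  expect_true("t1" %in% m$unmatched)
  expect_equal(m$pairs$treated_id, "t2")
})

test_that("greedy pairing follows descending-propensity order with ties to the smaller id", {
  # hand-worked example: logits chosen so the greedy order matters
  lg <- c(t1 = 1.0, t2 = 0.8, t3 = 0.0, t4 = -1.0,
          c1 = 0.9, c2 = 0.7, c3 = 0.05, c4 = -2.5)
  p <- plogis(lg)
  treated <- c(rep(TRUE, 4), rep(FALSE, 4))
  m <- match_caliper(p, treated, ids = names(lg), caliper_mult = 0.5)
  # caliper = 0.5 * sd(lg) = 0.5 * 1.1339 = 0.567
  # order t1 (1.0): nearest c1 (0.1); t2 (0.8): c2 (0.1); t3: c3 (0.05);
  # t4 (-1.0): remaining c4 at 1.5 > caliper -> unmatched
  expect_equal(m$pairs$treated_id, c("t1", "t2", "t3"))
  expect_equal(m$pairs$control_id, c("c1", "c2", "c3"))
  expect_equal(m$unmatched, "t4")
  expect_equal(m$caliper, 0.5 * sd(lg), tolerance = 1e-12)
  # equidistant controls resolve to the smaller id
  lg2 <- c(a = 0, x2 = -0.5, x1 = 0.5)
  m2 <- match_caliper(plogis(lg2), c(TRUE, FALSE, FALSE),
                      ids = names(lg2), caliper_mult = 3)
  expect_equal(m2$pairs$control_id, "x1")
})

test_that("matching contracts hold on random cohorts and ignore row order", {
  for (seed in c(5, 11)) {
    co <- small_cohort(seed = seed, n_per_arm = 50, organs = character(0))
    ps <- fit_propensity(co)
    treated <- co$patients$modality == "IMRT"
    m <- match_caliper(ps$p, treated, ids = co$patients$id)
    expect_false(anyDuplicated(m$pairs$control_id) > 0)
    expect_false(anyDuplicated(m$pairs$treated_id) > 0)
    expect_true(all(m$pairs$distance <= m$caliper + 1e-12))
    # permutation invariance given the documented processing order
    set.seed(99)
    perm <- sample(length(ps$p))
    m2 <- match_caliper(ps$p[perm], treated[perm],
                        ids = co$patients$id[perm])
    o1 <- m$pairs[order(m$pairs$treated_id), ]
    o2 <- m2$pairs[order(m2$pairs$treated_id), ]
    expect_equal(o1$control_id, o2$control_id)
    expect_equal(o1$distance, o2$distance, tolerance = 1e-12)
  }
})

test_that("matching improves covariate balance on confounded cohorts", {
  worse <- 0
  for (seed in c(31, 32, 33)) {
    co <- generate_cohort(synth_config(n_per_arm = 150, seed = seed,
                                       confounding = 1.5,
                                       organs = character(0)))
    ps <- fit_propensity(co)
    m <- match_caliper(ps$p, co$patients$modality == "IMRT",
                       ids = co$patients$id)
    bal <- balance_diagnostics(co, m)
    expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
  }
})

test_that("self-matching gives zero SMD and empty matches are flagged", {
  co <- small_cohort(seed = 6, n_per_arm = 30, organs = character(0))
  df <- co$patients
  # duplicate every patient into the opposite arm: perfect overlap
  dup <- df
  dup$id <- paste0("D", dup$id)
  dup$modality <- ifelse(df$modality == "VMAT", "IMRT", "VMAT")
  both <- rbind(df, dup)
  ps <- fit_propensity(both)
  # wide caliper: every treated unit finds its mirror-image control
  m <- match_caliper(ps$p, both$modality == "IMRT", ids = both$id,
                     caliper_mult = 100)
  expect_equal(nrow(m$pairs), sum(both$modality == "IMRT"))
  bal <- balance_diagnostics(both, m)
  expect_true(all(abs(bal$smd_after) < 1e-8))
  empty <- structure(list(pairs = data.frame(treated_id = character(0),
                                             control_id = character(0),
                                             distance = numeric(0)),
                          caliper = 0.1, unmatched = character(0)),
                     class = "match_result")
  expect_error(balance_diagnostics(both, empty), "no matched pairs")
})
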