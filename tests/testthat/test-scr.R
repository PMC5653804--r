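test_that("fraction dose follows the prescription arithmetic", {
  expect_equal(fraction_dose(51, 30), 1.7)
  expect_equal(fraction_dose(63, 30), 2.1)
  expect_equal(fraction_dose(0, 30), 0)
  expect_error(fraction_dose(50, 0), ">= 1")
})

test_that("RED limits and plateau closed form hold", {
  p <- test_params(alpha = 0.1, R = 0.5)
  expect_equal(red_full(0, 0, p), 0)
  # slope at the origin is exactly 1 for any parameters
  for (R in c(0.2, 0.5, 0.9)) {
    pr <- test_params(alpha = 0.08, R = R)
    expect_equal(red_full(1e-6, 0, pr) / 1e-6, 1, tolerance = 1e-4)
  }
  # R -> 1 plateau: alpha' = 0.1, D = 20 -> (1/0.1)(1 - e^-2)
  pr1 <- test_params(alpha = 0.1, R = 1 - 1e-9)
  expect_equal(red_full(20, 0, pr1), (1 / 0.1) * (1 - exp(-2)),
               tolerance = 1e-4)
  # R -> 0 bell form
  pr0 <- test_params(alpha = 0.1, R = 0)
  expect_equal(red_full(20, 0, pr0), 20 * exp(-2), tolerance = 1e-12)
  expect_error(red_full(-1, 0, p), "non-negative")
})

test_that("RED is continuous across the R branch switches", {
  for (D in c(1, 10, 40)) {
    lo <- red_full(D, 1.8, test_params(R = 1e-7))
    hi <- red_full(D, 1.8, test_params(R = 1e-7 + 1e-10))
    expect_lt(abs(lo - hi), 1e-5)
    lo <- red_full(D, 1.8, test_params(R = 1 - 1e-7 - 1e-10))
    hi <- red_full(D, 1.8, test_params(R = 1 - 1e-7))
    expect_lt(abs(lo - hi), 1e-5)
  }
})

test_that("fractionation correction rescales the cell-kill parameter", {
  p <- test_params(alpha = 0.06, R = 0.4, alpha_beta = 3)
  # d = 3 Gy/fraction doubles alpha'; equivalent to alpha = 0.12 at d = 0
  expect_equal(red_full(30, 3, p),
               red_full(30, 0, test_params(alpha = 0.12, R = 0.4)))
})

test_that("OED averages RED over the differential DVH", {
  p <- test_params(alpha = 0.05, R = 0.5)
  # uniform organ: OED = RED at that dose
  u <- uniform_dvh(20)
  expect_equal(oed(u, p, n_fractions = 10),
               red_full(20, 2, p), tolerance = 1e-6)
  # two-bin DVH: arithmetic mean of the two bin REDs
  d <- dvh(c(0, 10, 20, 30, 40), c(0, 50, 0, 50), mode = "differential")
  expect_equal(oed(d, p, n_fractions = 20),
               0.5 * red_full(15, 0.75, p) + 0.5 * red_full(35, 1.75, p),
               tolerance = 1e-12)
  # alpha' -> 0: OED -> mean dose
  tiny <- test_params(alpha = 1e-8, R = 0.5)
  for (seed in c(2, 4)) {
    rd <- random_dvh(seed)
    expect_equal(oed(rd, tiny, n_fractions = 30), mean_dose(rd),
                 tolerance = 1e-3 * mean_dose(rd))
  }
})

test_that("OED is monotone under dose dominance in the low-dose regime", {
  p <- test_params(alpha = 0.004, R = 0.5)  # alpha' * Dmax << 1
  base <- dvh(c(0, 5, 10, 15, 20), c(40, 30, 20, 10), mode = "differential")
  # shift volume from a lower to a higher bin
  shifted <- dvh(c(0, 5, 10, 15, 20), c(30, 30, 20, 20),
                 mode = "differential")
  expect_gt(oed(shifted, p, 30), oed(base, p, 30))
})

test_that("EAR age modifiers behave as specified", {
  p <- test_params(beta_ear = 8, gamma_e = -0.02, gamma_a = 2.5)
  expect_equal(ear(10, p, age_x = 30, age_a = 70), 8 * 10)
  expect_equal(ear(0, p, age_x = 45), 0)
  flat <- test_params(beta_ear = 8, gamma_e = 0, gamma_a = 0)
  expect_equal(ear(10, flat, age_x = 33, age_a = 55),
               ear(10, flat, age_x = 61, age_a = 70))
  # linear in OED and in beta
  expect_equal(ear(14, p, 40, 70), 2 * ear(7, p, 40, 70))
  p2 <- test_params(beta_ear = 16, gamma_e = -0.02, gamma_a = 2.5)
  expect_equal(ear(7, p2, 40, 70), 2 * ear(7, p, 40, 70))
  expect_error(ear(10, p, age_x = -5), "positive")
  expect_error(ear(10, p, age_x = 50, age_a = 40), ">=")
  # accumulated EAR sums yearly risks and respects latency
  acc <- accumulated_ear(10, p, age_x = 60)
  expect_equal(acc, sum(sapply(60:70, function(a) ear(10, p, 60, a))))
  expect_lt(accumulated_ear(10, p, 60, latency = 5), acc)
})

test_that("cohort SCR applies the age cutoff and compares arms", {
  co <- small_cohort(seed = 17, n_per_arm = 25)
  params <- read_organ_params(system.file("extdata",
                                          "organ_params_synthetic.csv",
                                          package = "rtrisk"))
  res <- cohort_scr(co, params, age_cutoff = 65)
  expect_s3_class(res, "scr_result")
  expect_equal(res$n_included, sum(co$patients$age <= 65))
  expect_setequal(unique(res$per_patient$organ), names(params))
  expect_true(all(res$per_patient$oed >= 0))
  expect_true(all(res$per_patient$ear >= 0))
  # age filter keeps exactly the young patients
  co2 <- co
  co2$patients$age <- rep(c(60, 66, 70), length.out = nrow(co2$patients))
  res2 <- suppressWarnings(cohort_scr(co2, params["lung_ipsi"],
                                      age_cutoff = 65))
  expect_equal(res2$n_included, sum(co2$patients$age == 60))
  # organs without parameters are skipped with a warning
  expect_warning(cohort_scr(co, params["liver"]), "skipped")
})

test_that("identical dose distributions across arms give p = 1", {
  co <- small_cohort(seed = 19, n_per_arm = 10, organs = "lung_ipsi")
  # force both arms to share the same DVH set
  imrt <- co$patients$id[co$patients$modality == "IMRT"]
  vmat <- co$patients$id[co$patients$modality == "VMAT"]
  k <- min(length(imrt), length(vmat))
  keep <- c(imrt[1:k], vmat[1:k])
  co <- subset_cohort(co, keep)
  co$patients$age <- 55      # same exposure age so EARs are comparable
  for (i in 1:k)
    co$dvhs[[vmat[i]]] <- co$dvhs[[imrt[i]]]
  params <- list(lung_ipsi = test_params(organ = "lung_ipsi"))
  res <- cohort_scr(co, params, age_cutoff = 100)
  expect_true(all(res$summary$p_oed > 0.99))
  expect_true(all(res$summary$p_ear > 0.99))
})

test_that("stochastically lower VMAT lung doses yield lower VMAT OED", {
  # generator default: VMAT ipsilateral-lung DVHs sit below IMRT's
  co <- generate_cohort(synth_config(n_per_arm = 60, seed = 23,
                                     organs = "lung_ipsi"))
  params <- list(lung_ipsi = test_params(alpha = 0.01, R = 0.5,
                                         organ = "lung_ipsi"))
  res <- cohort_scr(co, params, age_cutoff = 100)
  s <- res$summary
  expect_lt(s$oed_mean_VMAT, s$oed_mean_IMRT)
})
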