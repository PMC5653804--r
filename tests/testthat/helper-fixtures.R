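# random valid DVHs for property-style tests
random_dvh <- function(seed, nbins = 40, mode = c("differential",
                                                  "cumulative")) {
  mode <- match.arg(mode)
  set.seed(seed)
  edges <- c(0, sort(runif(nbins, 0.1, 70)))
  v <- rgamma(nbins, shape = runif(1, 0.3, 3))
  v <- 100 * v / sum(v)
  d <- dvh(edges, v, mode = "differential")
  if (mode == "cumulative") to_cumulative(d) else d
}

# analytic normalized-logistic cumulative DVH on a fine grid
logistic_dvh <- function(loc = 20, scale = 6, grid = seq(0, 80, by = 0.1)) {
  s <- function(x) 1 / (1 + exp((x - loc) / scale))
  v <- 100 * s(grid) / s(0)
  v[1] <- 100
  dvh(grid, v, mode = "cumulative")
}

# small synthetic cohort used across matching / selection / scr tests
small_cohort <- function(seed = 1, n_per_arm = 40, ...) {
  generate_cohort(synth_config(n_per_arm = n_per_arm, seed = seed, ...))
}

test_params <- function(alpha = 0.05, R = 0.5, beta_ear = 8,
                        gamma_e = -0.02, gamma_a = 2.5, alpha_beta = 3,
                        organ = "organ") {
  organ_risk_params(organ, alpha, R, beta_ear, gamma_e, gamma_a,
                    alpha_beta)
}
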