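#' Default DVH shape parameters for the synthetic cohort generator
#'
#' Each organ's cumulative DVH is modelled as a normalized logistic
#' survival curve `V(x) = 100 * S(x) / S(0)`, `S(x) = 1 / (1 + exp((x -
#' loc) / scale))`, with patient-level variation on `loc` and `scale`.
#' Modality-dependent locations/scales reproduce the qualitative planning
#' differences between the two techniques: the arc technique (VMAT) exposes
#' a smaller ipsilateral-lung volume to low and intermediate doses, while
#' spreading slightly more low dose to the contralateral lung and breast.
#'
#' @return a named list (one element per organ) of shape parameters.
#' @export
default_dvh_shapes <- function() {
  list(
    lung_ipsi     = list(loc = c(IMRT = 27,  VMAT = 25),
                         scale = c(IMRT = 8,   VMAT = 7),
                         loc_sd = 5,   scale_sd = 1, band_sigma = 0.6),
    lung_contra   = list(loc = c(IMRT = 2,   VMAT = 4),
                         scale = c(IMRT = 3,   VMAT = 4),
                         loc_sd = 1.5, scale_sd = 0.5, band_sigma = 0.4),
    breast_contra = list(loc = c(IMRT = 1,   VMAT = 3),
                         scale = c(IMRT = 2.5, VMAT = 3.5),
                         loc_sd = 1.5, scale_sd = 0.5, band_sigma = 0.4),
    spinal_cord   = list(loc = c(IMRT = 3,   VMAT = 3),
                         scale = c(IMRT = 4,   VMAT = 4),
                         loc_sd = 1.5, scale_sd = 0.5, band_sigma = 0.4),
    liver         = list(loc = c(IMRT = 2,   VMAT = 2),
                         scale = c(IMRT = 3,   VMAT = 3),
                         loc_sd = 1.5, scale_sd = 0.5, band_sigma = 0.4),
    stomach       = list(loc = c(IMRT = 1.5, VMAT = 1.5),
                         scale = c(IMRT = 2.5, VMAT = 2.5),
                         loc_sd = 1,   scale_sd = 0.5, band_sigma = 0.4)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of [generate_cohort()]: cohort size, covariate
#' marginals (defaults follow the unmatched baseline table of the study
#' population the generator emulates), the confounded treatment-assignment
#' model, per-organ DVH shapes, and the ground-truth dose-response used to
#' draw pneumonitis outcomes.
#'
#' @param n_per_arm target number of patients per treatment arm; modality
#'   is assigned per patient by a logistic model on the covariates, so
#'   realized arm sizes vary around this (total cohort size is
#'   `2 * n_per_arm`).
#' @param seed integer seed making the generated cohort reproducible.
#' @param confounding multiplier on the covariate coefficients of the
#'   treatment-assignment model; 0 gives a randomized-like cohort, 1 the
#'   default observational imbalance (younger, lower-stage patients more
#'   likely to receive VMAT).
#' @param covariates list of covariate marginals: `age_mean`, `age_sd`,
#'   `age_range`, `ajcc_probs` (stages 1-3), `t_probs` (T1-T4), `n_probs`
#'   (N0-N3), `p_scf`, `p_chemo`.
#' @param assignment coefficients of the logistic treatment-assignment
#'   model `P(VMAT)`; `intercept` plus terms in centred age, AJCC stage,
#'   SCF and chemotherapy.
#' @param dvh_shapes per-organ DVH shape parameters, see
#'   [default_dvh_shapes()].
#' @param lkb_truth ground-truth dose-response for pneumonitis outcomes:
#'   `factor` (a dosimetric name such as `"V40"` or `"MD"`, evaluated on
#'   the ipsilateral lung), `tv50` and `m`.  Defaults are the fitted values
#'   of the emulated study (TV50 = 15.07% of lung volume, m = 0.62).
#' @param grade_split probabilities of grades 1:3 given an event, echoing
#'   the matched cohort's 20:9:2 grade distribution.
#' @param dose_grid dose axis (Gy) on which cumulative DVHs are tabulated.
#' @param organs organs to generate DVHs for; restrict for speed when only
#'   the ipsilateral lung is needed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_per_arm = 45, seed = 1, confounding = 1,
                         covariates = list(
                           age_mean = 52, age_sd = 11, age_range = c(28, 75),
                           ajcc_probs = c(0.59, 0.17, 0.24),
                           t_probs = c(0.49, 0.44, 0.05, 0.02),
                           n_probs = c(0.57, 0.22, 0.10, 0.11),
                           p_scf = 0.41, p_chemo = 0.57),
                         assignment = list(intercept = 0.575, age = -0.03,
                                           ajcc = -0.45, scf = -0.5,
                                           chemo = -0.4),
                         dvh_shapes = default_dvh_shapes(),
                         lkb_truth = list(factor = "V40", tv50 = 15.07,
                                          m = 0.62),
                         grade_split = c(20, 9, 2) / 31,
                         dose_grid = seq(0, 70, by = 0.5),
                         organs = names(default_dvh_shapes())) {
  stopifnot(n_per_arm >= 1, length(seed) == 1L)
  probs <- c(covariates$ajcc_probs, covariates$t_probs, covariates$n_probs,
             covariates$p_scf, covariates$p_chemo, grade_split)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (lkb_truth$tv50 <= 0 || lkb_truth$m <= 0)
    stop("ground-truth TV50 and m must be positive")
  structure(list(n_per_arm = n_per_arm, seed = seed,
                 confounding = confounding, covariates = covariates,
                 assignment = assignment, dvh_shapes = dvh_shapes,
                 lkb_truth = lkb_truth, grade_split = grade_split,
                 dose_grid = dose_grid, organs = organs),
            class = "synth_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

shape_dvh <- function(grid, loc, scale, organ, band_sigma = 0,
                      band_width = 5) {
  s <- 1 / (1 + exp((grid - loc) / scale))
  if (band_sigma > 0) {
    # plan-to-plan shape irregularity: independent log-normal volume
    # perturbations per dose band, applied to the differential density
    mids <- (grid[-1L] + grid[-length(grid)]) / 2
    dens <- -diff(s)
    band <- findInterval(mids, seq(0, max(grid), by = band_width))
    eps <- stats::rnorm(max(band), 0, band_sigma)
    dens <- dens * exp(eps[band])
    v <- c(rev(cumsum(rev(dens))), 0)
    v <- 100 * v / v[1L]
  } else {
    v <- 100 * s / s[1L]
  }
  v[1L] <- 100
  dvh(grid, v, organ = organ, mode = "cumulative")
}

factor_value <- function(d, factor) {
  if (identical(factor, "MD")) return(mean_dose(d))
  if (grepl("^V[0-9.]+$", factor))
    return(v_at(d, as.numeric(sub("^V", "", factor))))
  stop("unknown dosimetric factor: ", factor)
}

#' Generate a synthetic radiotherapy cohort with known ground truth
#'
#' Draws baseline covariates from the configured marginals, assigns
#' treatment modality by a confounded logistic model (creating the
#' pre-matching imbalance typical of observational cohorts), builds
#' per-organ DVHs from parametric cumulative shapes, and draws the
#' radiation-pneumonitis grade so that `P(grade >= 1)` follows the
#' configured ground-truth Lyman-Kutcher-Burman dose-response on the chosen
#' ipsilateral-lung dosimetric factor.
#'
#' @param cfg a [synth_config()].
#' @param organs organs to generate (default from `cfg`).
#' @return an object of class `rt_cohort`: a list with `patients` (a
#'   data.frame of covariates, modality and `rp_grade`) and `dvhs` (a list,
#'   one named list of [dvh] objects per patient).
#' @export
generate_cohort <- function(cfg = synth_config(), organs = cfg$organs) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- 2L * as.integer(cfg$n_per_arm)
  cv <- cfg$covariates
  age <- round(rtrunc_norm(n, cv$age_mean, cv$age_sd,
                           cv$age_range[1], cv$age_range[2]))
  ajcc <- sample.int(3L, n, replace = TRUE, prob = cv$ajcc_probs)
  t_stage <- sample.int(4L, n, replace = TRUE, prob = cv$t_probs)
  n_stage <- sample.int(4L, n, replace = TRUE, prob = cv$n_probs) - 1L
  scf <- stats::rbinom(n, 1L, cv$p_scf)
  chemo <- stats::rbinom(n, 1L, cv$p_chemo)
  a <- cfg$assignment
  eta <- a$intercept + cfg$confounding *
    (a$age * (age - cv$age_mean) + a$ajcc * (ajcc - 2) +
       a$scf * scf + a$chemo * chemo)
  modality <- ifelse(stats::rbinom(n, 1L, stats::plogis(eta)) == 1L,
                     "VMAT", "IMRT")
  ids <- sprintf("P%04d", seq_len(n))

  organs <- intersect(organs, names(cfg$dvh_shapes))
  dvhs <- vector("list", n)
  names(dvhs) <- ids
  fx <- numeric(n)
  for (i in seq_len(n)) {
    od <- list()
    for (org in organs) {
      sh <- cfg$dvh_shapes[[org]]
      loc <- stats::rnorm(1, sh$loc[[modality[i]]], sh$loc_sd)
      scl <- max(0.5, stats::rnorm(1, sh$scale[[modality[i]]], sh$scale_sd))
      od[[org]] <- shape_dvh(cfg$dose_grid, loc, scl, org,
                             band_sigma = sh$band_sigma %||% 0)
    }
    dvhs[[i]] <- od
    if ("lung_ipsi" %in% organs)
      fx[i] <- factor_value(od$lung_ipsi, cfg$lkb_truth$factor)
  }

  if ("lung_ipsi" %in% organs) {
    p_event <- stats::pnorm((fx - cfg$lkb_truth$tv50) /
                              (cfg$lkb_truth$m * cfg$lkb_truth$tv50))
    event <- stats::rbinom(n, 1L, p_event)
    grade <- integer(n)
    ne <- sum(event)
    if (ne > 0)
      grade[event == 1L] <- sample(1:3, ne, replace = TRUE,
                                   prob = cfg$grade_split)
  } else {
    grade <- rep(NA_integer_, n)
  }

  patients <- data.frame(id = ids, age = age, ajcc = ajcc,
                         t_stage = t_stage, n_stage = n_stage,
                         scf = scf, chemo = chemo, modality = modality,
                         rp_grade = grade, stringsAsFactors = FALSE)
  structure(list(patients = patients, dvhs = dvhs, config = cfg),
            class = "rt_cohort")
}

#' @export
print.rt_cohort <- function(x, ...) {
  tab <- table(x$patients$modality)
  cat(sprintf("<rt_cohort> %d patients (%s)\n", nrow(x$patients),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by patient id
#' @param x an `rt_cohort`.
#' @param ids patient ids to keep.
#' @return the subsetted `rt_cohort`.
#' @export
subset_cohort <- function(x, ids) {
  stopifnot(inherits(x, "rt_cohort"))
  keep <- x$patients$id %in% ids
  structure(list(patients = x$patients[keep, , drop = FALSE],
                 dvhs = x$dvhs[x$patients$id[keep]],
                 config = x$config),
            class = "rt_cohort")
}

#' Dosimetric factor matrix for a cohort
#'
#' Computes the candidate-predictor matrix (MD plus V_x at each threshold)
#' from one organ's DVHs across a cohort, the input to LASSO selection.
#'
#' @param cohort an `rt_cohort`.
#' @param organ organ whose DVHs to summarize (default ipsilateral lung).
#' @param thresholds dose thresholds in Gy, see [dosimetric_vector()].
#' @return numeric matrix, one row per patient, rownames = patient ids.
#' @export
cohort_factors <- function(cohort, organ = "lung_ipsi",
                           thresholds = seq(5, 50, by = 5)) {
  stopifnot(inherits(cohort, "rt_cohort"))
  rows <- lapply(cohort$patients$id, function(id) {
    d <- cohort$dvhs[[id]][[organ]]
    if (is.null(d)) stop("patient ", id, " has no DVH for organ ", organ)
    dosimetric_vector(d, thresholds)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- cohort$patients$id
  m
}

#' Baseline characteristics table by treatment arm
#'
#' Summarizes a cohort in the layout of a clinical "Table 1": counts and
#' percentages per category for categorical covariates (with a two-sided
#' chi-square p-value), mean and range for age (with a two-sided rank-sum
#' p-value), and the pneumonitis grade distribution.
#'
#' @param cohort an `rt_cohort` or its `patients` data.frame.
#' @param group grouping column, default `"modality"`.
#' @return a data.frame with columns `variable`, `level`, one count column
#'   per arm, and `p` (repeated within a variable block).
#' @export
table_one <- function(cohort, group = "modality") {
  df <- if (inherits(cohort, "rt_cohort")) cohort$patients else cohort
  if (nrow(df) == 0L) stop("empty cohort")
  arms <- sort(unique(df[[group]]))
  if (length(arms) < 2L) stop("table_one needs at least two groups")
  g <- factor(df[[group]], levels = arms)
  out <- list()

  fmt_n <- function(k, n) sprintf("%d (%.0f)", k, 100 * k / n)
  if ("age" %in% names(df)) {
    # age: mean (range), rank-sum p
    ptab <- tapply(df$age, g, function(a)
      sprintf("%.0f [%d-%d]", mean(a), min(a), max(a)))
    p_age <- suppressWarnings(stats::wilcox.test(df$age ~ g)$p.value)
    out[[length(out) + 1L]] <- data.frame(variable = "age",
                                          level = "mean [range]",
                                          t(ptab), p = p_age,
                                          check.names = FALSE)
  }

  cat_vars <- intersect(c("scf", "ajcc", "t_stage", "n_stage", "chemo"),
                        names(df))
  for (v in cat_vars) {
    f <- factor(df[[v]])
    tab <- table(f, g)
    p <- if (nrow(tab) > 1L)
      suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
    block <- data.frame(variable = v, level = rownames(tab), p = p,
                        check.names = FALSE)
    for (a in arms) block[[a]] <- fmt_n(tab[, a], sum(tab[, a]))
    block <- block[, c("variable", "level", arms, "p")]
    out[[length(out) + 1L]] <- block
  }
  if ("rp_grade" %in% names(df) && !anyNA(df$rp_grade)) {
    tab <- table(factor(df$rp_grade, levels = 0:3), g)
    block <- data.frame(variable = "rp_grade", level = rownames(tab),
                        p = NA_real_, check.names = FALSE)
    for (a in arms) block[[a]] <- fmt_n(tab[, a], sum(tab[, a]))
    out[[length(out) + 1L]] <- block[, c("variable", "level", arms, "p")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n") <- table(g)
  res
}

#' Count radiation-pneumonitis events
#'
#' @param cohort an `rt_cohort` or a `patients`-style data.frame with
#'   `rp_grade` and `modality` columns.
#' @param min_grade minimum grade counting as an event (default 1, the
#'   grade-1+ endpoint).
#' @return a list with `total`, per-arm counts `by_arm`, and `fraction` of
#'   the cohort with an event.
#' @export
count_rp_events <- function(cohort, min_grade = 1) {
  df <- if (inherits(cohort, "rt_cohort")) cohort$patients else cohort
  if (anyNA(df$rp_grade)) stop("rp_grade missing for some patients")
  ev <- df$rp_grade >= min_grade
  list(total = sum(ev),
       by_arm = tapply(ev, df$modality, sum),
       fraction = mean(ev))
}

#' The packaged matched-cohort pneumonitis grade table
#'
#' Grade 0-3 counts per treatment arm for the 64-patient (32:32) matched
#' cohort that this package's models emulate, shipped as a plain-text
#' fixture.  `matched_rp_fixture()` expands the counts into a minimal
#' cohort (id, modality, rp_grade only) for event accounting.
#'
#' @return `matched_rp_counts()`: a data.frame with columns `modality`,
#'   `rp_grade`, `count`; `matched_rp_fixture()`: an `rt_cohort` with one
#'   row per patient and no DVHs.
#' @export
matched_rp_counts <- function() {
  path <- system.file("extdata", "table1_matched_rp_grades.csv",
                      package = "rtrisk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname matched_rp_counts
#' @export
matched_rp_fixture <- function() {
  tab <- matched_rp_counts()
  idx <- rep(seq_len(nrow(tab)), tab$count)
  patients <- data.frame(
    id = sprintf("M%03d", seq_along(idx)),
    modality = tab$modality[idx],
    rp_grade = tab$rp_grade[idx],
    stringsAsFactors = FALSE)
  structure(list(patients = patients, dvhs = list(), config = NULL),
            class = "rt_cohort")
}

#' Read and write cohorts as plain-text files
#'
#' A cohort directory holds `patients.csv` (one row per patient) and a
#' `dvh/` subdirectory with one DVH CSV per patient (the [read_dvh_file()]
#' dialect).
#'
#' @param cohort an `rt_cohort`.
#' @param dir directory to write to / read from.
#' @return `read_cohort()`: an `rt_cohort`; `write_cohort()`: `dir`,
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rt_cohort"))
  dir.create(file.path(dir, "dvh"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(cohort$dvhs))
    if (length(cohort$dvhs[[id]]))
      write_dvh_file(cohort$dvhs[[id]], file.path(dir, "dvh",
                                                  paste0(id, ".csv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  dvhs <- list()
  for (id in patients$id) {
    f <- file.path(dir, "dvh", paste0(id, ".csv"))
    dvhs[[id]] <- if (file.exists(f)) read_dvh_file(f) else list()
  }
  structure(list(patients = patients, dvhs = dvhs, config = NULL),
            class = "rt_cohort")
}
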