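#' Organ parameters for the Schneider carcinoma-induction model
#'
#' Bundles the mechanistic and epidemiological constants of Schneider's
#' full carcinoma model for one organ: the cell-kill parameter `alpha`
#' (1/Gy), the repopulation/repair parameter `R` (0 = no repopulation,
#' 1 = full), the risk slope `beta_ear` (excess cases per 10,000
#' person-years per Gy, defined for exposure at age 30 and attained age
#' 70), the age modifiers `gamma_e` (age at exposure) and `gamma_a`
#' (attained age), and the fractionation ratio `alpha_beta` (Gy,
#' default 3).
#'
#' Published parameter values belong in a configuration file (see
#' [read_organ_params()]); the packaged
#' `extdata/organ_params_synthetic.csv` is a synthetic template with
#' field-plausible magnitudes, not a reproduction of any published set.
#'
#' @param organ organ label.
#' @param alpha cell-kill parameter in 1/Gy (> 0).
#' @param R repopulation/repair parameter in `[0, 1]`.
#' @param beta_ear EAR slope at the reference ages.
#' @param gamma_e,gamma_a age-modifier exponents.
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return a list of class `organ_risk_params`.
#' @export
organ_risk_params <- function(organ, alpha, R, beta_ear, gamma_e, gamma_a,
                              alpha_beta = 3) {
  if (alpha <= 0) stop("alpha must be positive")
  if (R < 0 || R > 1) stop("R must lie in [0, 1]")
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  structure(list(organ = organ, alpha = alpha, R = R, beta_ear = beta_ear,
                 gamma_e = gamma_e, gamma_a = gamma_a,
                 alpha_beta = alpha_beta),
            class = "organ_risk_params")
}

#' Read organ risk parameters from a configuration file
#'
#' Accepts a CSV with columns `organ, alpha, R, beta_ear, gamma_e,
#' gamma_a, alpha_beta` or a YAML mapping organ -> parameter list.
#'
#' @param path path to the CSV or YAML file.
#' @return named list of [organ_risk_params()], keyed by organ.
#' @export
read_organ_params <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    out <- lapply(names(raw), function(org) {
      do.call(organ_risk_params, c(list(organ = org), raw[[org]]))
    })
    names(out) <- names(raw)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("organ", "alpha", "R", "beta_ear", "gamma_e", "gamma_a")
    if (!all(need %in% names(df)))
      stop("organ parameter file must have columns ",
           paste(need, collapse = ", "))
    if (!"alpha_beta" %in% names(df)) df$alpha_beta <- 3
    out <- lapply(seq_len(nrow(df)), function(i) {
      organ_risk_params(df$organ[i], df$alpha[i], df$R[i], df$beta_ear[i],
                        df$gamma_e[i], df$gamma_a[i], df$alpha_beta[i])
    })
    names(out) <- df$organ
  }
  out
}

#' Dose per fraction at a DVH bin
#'
#' Assumes every voxel follows the same fractionation pattern, so a bin at
#' total dose `D` delivered in `n_fractions` fractions received
#' `D / n_fractions` per fraction (e.g. 63 Gy in 30 fractions is 2.1
#' Gy/fraction; 51 Gy is 1.7).
#'
#' @param D total dose in Gy.
#' @param n_fractions number of fractions (>= 1).
#' @return dose per fraction in Gy.
#' @export
fraction_dose <- function(D, n_fractions) {
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  D / n_fractions
}

#' Risk-equivalent dose (Schneider full carcinoma model)
#'
#' The dose-response-weighted dose proportional to the carcinoma-induction
#' risk at total dose `D`.  With the fractionation-corrected cell-kill
#' parameter `a = alpha * (1 + d / alpha_beta)` (`d` = dose per fraction)
#' the full mechanistic model is
#' \deqn{RED = \frac{e^{-aD}}{aR}\left[1 - 2R + R^2 e^{aD}
#'       - (1 - R)^2 e^{-\frac{aR}{1-R} D}\right].}
#' Closed-form limits are used within 1e-7 of the `R` boundaries:
#' `RED = D e^{-aD}` at `R -> 0` (pure bell-shaped cell kill) and
#' `RED = (1 - e^{-aD}) / a` at `R -> 1` (plateau model).  `RED(D)/D -> 1`
#' as `D -> 0` for any parameters.
#'
#' @param D total dose(s) in Gy (>= 0).
#' @param d dose per fraction in Gy (same length as `D` or scalar);
#'   default 0 gives the uncorrected low-dose-rate form.
#' @param params an [organ_risk_params()].
#' @return RED in Gy, same length as `D`.
#' @export
red_full <- function(D, d = 0, params) {
  stopifnot(inherits(params, "organ_risk_params"))
  if (any(D < 0)) stop("dose must be non-negative")
  a <- params$alpha * (1 + d / params$alpha_beta)
  if (any(a <= 0)) stop("fractionation-corrected alpha must be positive")
  R <- params$R
  eps <- 1e-7
  if (R <= eps) {
    D * exp(-a * D)
  } else if (R >= 1 - eps) {
    (1 - exp(-a * D)) / a
  } else {
    exp(-a * D) / (a * R) *
      (1 - 2 * R + R^2 * exp(a * D) -
         (1 - R)^2 * exp(-(a * R / (1 - R)) * D))
  }
}

#' Organ equivalent dose
#'
#' Volume-weighted average of the risk-equivalent dose over the organ's
#' differential DVH: `OED = sum_i w_i RED(D_i, d_i)` with `w_i` the bin
#' volume fraction, `D_i` the bin midpoint dose and `d_i` its dose per
#' fraction.  Expressed in Gy; proportional to the cancer-induction risk
#' in the organ.
#'
#' @param dvh a [dvh] object (either mode).
#' @param params an [organ_risk_params()].
#' @param n_fractions number of treatment fractions (default 30).
#' @return OED in Gy.
#' @export
oed <- function(dvh, params, n_fractions = 30) {
  dd <- to_differential(dvh)
  if (sum(dd$volume) <= 0) stop("empty DVH")
  mids <- (dd$dose[-1L] + dd$dose[-length(dd$dose)]) / 2
  w <- dd$volume / sum(dd$volume)
  sum(w * red_full(mids, fraction_dose(mids, n_fractions), params))
}

#' Excess absolute risk of carcinoma induction
#'
#' `EAR = beta_ear * OED * exp(gamma_e (age_x - 30) +
#' gamma_a ln(age_a / 70))`, in excess cases per 10,000 person-years.
#' The age modifier equals 1 at the reference ages (exposure at 30,
#' attained age 70).
#'
#' @param oed_value organ equivalent dose in Gy.
#' @param params an [organ_risk_params()].
#' @param age_x age at exposure in years (> 0).
#' @param age_a attained age in years (>= `age_x`).
#' @return EAR per 10,000 person-years.
#' @export
ear <- function(oed_value, params, age_x, age_a = 70) {
  stopifnot(inherits(params, "organ_risk_params"))
  if (any(age_x <= 0) || any(age_a <= 0)) stop("ages must be positive")
  if (any(age_a < age_x)) stop("attained age must be >= age at exposure")
  mu <- exp(params$gamma_e * (age_x - 30) + params$gamma_a * log(age_a / 70))
  params$beta_ear * oed_value * mu
}

#' Accumulated excess absolute risk up to an attained age
#'
#' Sums the yearly EAR over attained ages from `age_x + latency` to
#' `until_age` (default 70), one of the two readings of an "accumulated
#' EAR at age 70"; the other (the point EAR at attained age 70) is
#' [ear()] itself.
#'
#' @inheritParams ear
#' @param until_age last attained age included.
#' @param latency risk-free latency in years after exposure (default 0).
#' @return accumulated excess cases per 10,000 persons.
#' @export
accumulated_ear <- function(oed_value, params, age_x, until_age = 70,
                            latency = 0) {
  ages <- seq(ceiling(age_x + latency), until_age)
  if (!length(ages)) return(0)
  sum(vapply(ages, function(a) ear(oed_value, params, age_x, a),
             numeric(1)))
}

#' Secondary-cancer risk analysis of a cohort
#'
#' Computes OED and EAR per patient and organ under the Schneider full
#' model, excluding patients older than `age_cutoff` at treatment (risk
#' projection to attained age `age_a` is not meaningful for patients
#' already near it), and compares arms per organ with a two-sided
#' rank-sum (default) or t test.
#'
#' @param cohort an `rt_cohort`.
#' @param params named list of [organ_risk_params()] keyed by organ (see
#'   [read_organ_params()]).
#' @param n_fractions number of treatment fractions.
#' @param age_a attained age for the EAR projection (default 70).
#' @param age_cutoff patients with `age > age_cutoff` are excluded
#'   (default 65).
#' @param test `"wilcox"` or `"t"` for the per-organ arm comparison.
#' @return an object of class `scr_result`: `per_patient` (data.frame
#'   with id, modality, age, organ, oed, ear), `summary` (per organ:
#'   per-arm mean and SD of OED and EAR, p-values), and settings.
#' @export
cohort_scr <- function(cohort, params, n_fractions = 30, age_a = 70,
                       age_cutoff = 65, test = c("wilcox", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(cohort, "rt_cohort"))
  df <- cohort$patients
  keep <- df$age <= age_cutoff
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no patients at or below the age cutoff")

  organs <- unique(unlist(lapply(cohort$dvhs[df$id], names)))
  no_par <- setdiff(organs, names(params))
  if (length(no_par)) {
    warning("no risk parameters for organ(s): ",
            paste(no_par, collapse = ", "), "; skipped")
    organs <- intersect(organs, names(params))
  }
  if (!length(organs)) stop("no organ has both DVHs and risk parameters")

  rows <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    for (org in organs) {
      d <- cohort$dvhs[[id]][[org]]
      if (is.null(d)) next
      o <- oed(d, params[[org]], n_fractions)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, modality = df$modality[i], age = df$age[i], organ = org,
        oed = o, ear = ear(o, params[[org]], age_x = df$age[i],
                           age_a = max(df$age[i], age_a)),
        stringsAsFactors = FALSE)
    }
  }
  per_patient <- do.call(rbind, rows)

  arms <- sort(unique(per_patient$modality))
  summ <- do.call(rbind, lapply(organs, function(org) {
    sub <- per_patient[per_patient$organ == org, ]
    row <- data.frame(organ = org)
    for (a in arms) {
      s <- sub[sub$modality == a, ]
      row[[paste0("oed_mean_", a)]] <- mean(s$oed)
      row[[paste0("oed_sd_", a)]] <- stats::sd(s$oed)
      row[[paste0("ear_mean_", a)]] <- mean(s$ear)
      row[[paste0("ear_sd_", a)]] <- stats::sd(s$ear)
    }
    if (length(arms) == 2L) {
      cmp <- function(v) {
        x1 <- sub[[v]][sub$modality == arms[1L]]
        x2 <- sub[[v]][sub$modality == arms[2L]]
        if (!length(x1) || !length(x2)) return(NA_real_)
        if (isTRUE(all.equal(c(x1, x2), rep(mean(c(x1, x2)),
                                            length(c(x1, x2)))))) return(1)
        p <- if (test == "wilcox")
          suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
        else stats::t.test(x1, x2)$p.value
        p
      }
      row$p_oed <- cmp("oed")
      row$p_ear <- cmp("ear")
    }
    row
  }))
  structure(list(per_patient = per_patient, summary = summ,
                 settings = list(n_fractions = n_fractions, age_a = age_a,
                                 age_cutoff = age_cutoff, test = test),
                 n_included = nrow(df)),
            class = "scr_result")
}

#' @export
print.scr_result <- function(x, ...) {
  cat(sprintf("<scr_result> %d patients (age <= %g), %d organs\n",
              x$n_included, x$settings$age_cutoff,
              length(unique(x$per_patient$organ))))
  print(x$summary, digits = 4)
  invisible(x)
}
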