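#' Fit a propensity-score model for treatment modality
#'
#' Logistic regression of `P(modality == VMAT)` on baseline covariates,
#' fit by iteratively reweighted least squares to a score (gradient) norm
#' below 1e-8.  Age enters continuously, AJCC stage as an ordinal 1-3
#' score, SCF irradiation and chemotherapy as binaries.
#'
#' @param cohort an `rt_cohort` or `patients` data.frame.
#' @param covariates covariate column names; default the four matching
#'   covariates (age, AJCC stage, SCF, chemotherapy).
#' @param treat_level modality level modelled as the "success", default
#'   `"VMAT"`.
#' @return an object of class `propensity_model` with elements `model`
#'   (the glm), `p` (propensity scores), `logit`, `ids`.
#' @export
fit_propensity <- function(cohort, covariates = c("age", "ajcc", "scf",
                                                  "chemo"),
                           treat_level = "VMAT") {
  df <- if (inherits(cohort, "rt_cohort")) cohort$patients else cohort
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariates not in cohort: ", paste(missing_cov, collapse = ", "))
  y <- as.integer(df$modality == treat_level)
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("need at least 2 patients per arm")
  fdat <- df[, covariates, drop = FALSE]
  fdat$.y <- y
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = fdat,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (length(covariates) && any(abs(cf[-1L]) > 15)) {
    worst <- names(which.max(abs(cf[-1L])))
    stop("perfect or quasi-perfect separation on covariate '", worst, "'")
  }
  p <- as.numeric(stats::fitted(fit))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  # verify the ML score equations are solved to tight tolerance
  X <- stats::model.matrix(fit)
  grad <- as.numeric(crossprod(X, y - p))
  if (sqrt(sum(grad^2)) > 1e-6)
    warning("propensity model score norm ", format(sqrt(sum(grad^2))),
            " exceeds tolerance; fit may be ill-conditioned")
  structure(list(model = fit, covariates = covariates,
                 treat_level = treat_level, p = p, logit = stats::qlogis(p),
                 ids = df$id),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> P(%s) ~ %s  (n = %d)\n", x$treat_level,
              paste(x$covariates, collapse = " + "), length(x$p)))
  print(round(stats::coef(x$model), 4))
  invisible(x)
}

#' Greedy 1:1 caliper matching on the propensity logit
#'
#' Pairs each treated patient with the nearest untreated control on the
#' absolute logit-propensity distance, without replacement.  The caliper
#' is `caliper_mult` times the standard deviation of the logit scores over
#' the whole cohort (default 0.2, the conventional recommendation).
#' Treated units are processed in descending propensity order; distance
#' ties are broken by the smaller control id.  Pairs exceeding the caliper
#' are not formed and the treated unit is reported as unmatched.
#'
#' @param p propensity scores for all patients (in (0,1)).
#' @param treated logical vector, `TRUE` for the arm being matched.
#' @param ids patient ids aligned with `p`; defaults to indices.
#' @param caliper_mult positive caliper multiplier on the pooled logit SD.
#' @return an object of class `match_result`: `pairs` (data.frame
#'   `treated_id`, `control_id`, `distance`), `caliper`, `unmatched`
#'   (treated ids left unmatched).
#' @export
match_caliper <- function(p, treated, ids = NULL, caliper_mult = 0.2) {
  stopifnot(length(p) == length(treated))
  if (caliper_mult <= 0) stop("caliper_mult must be positive")
  if (!any(treated) || all(treated)) stop("both arms must be non-empty")
  if (is.null(ids)) ids <- as.character(seq_along(p))
  lg <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  caliper <- caliper_mult * stats::sd(lg)
  t_idx <- which(treated)
  t_idx <- t_idx[order(-p[t_idx], ids[t_idx])]
  avail <- which(!treated)
  pairs <- list()
  unmatched <- character(0)
  for (i in t_idx) {
    if (!length(avail)) { unmatched <- c(unmatched, ids[i]); next }
    d <- abs(lg[avail] - lg[i])
    best <- avail[order(d, ids[avail])][1L]
    bd <- abs(lg[best] - lg[i])
    if (bd <= caliper) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        treated_id = ids[i], control_id = ids[best], distance = bd,
        stringsAsFactors = FALSE)
      avail <- setdiff(avail, best)
    } else {
      unmatched <- c(unmatched, ids[i])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = character(0), control_id = character(0),
               distance = numeric(0))
  res <- structure(list(pairs = pairs, caliper = caliper,
                        caliper_mult = caliper_mult, unmatched = unmatched),
                   class = "match_result")
  # without-replacement and caliper contracts, asserted on every result
  stopifnot(!anyDuplicated(pairs$control_id),
            !anyDuplicated(pairs$treated_id),
            all(pairs$distance <= caliper + 1e-12))
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, caliper %.4f (logit), %d unmatched\n",
              nrow(x$pairs), x$caliper, length(x$unmatched)))
  invisible(x)
}

smd_num <- function(x1, x0) {
  s <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x1) - mean(x0)) / s
}

#' Covariate balance diagnostics before and after matching
#'
#' Standardized mean differences (SMD) and two-sided test p-values (rank
#' sum for age, chi-square for categorical covariates) per covariate,
#' comparing treatment arms in the full cohort and in the matched subset.
#'
#' @param cohort an `rt_cohort` or `patients` data.frame.
#' @param match a [match_caliper()] result; its pairs define the matched
#'   subset.
#' @param covariates covariate names to diagnose.
#' @param treat_level modality treated as group 1.
#' @return data.frame with columns `covariate`, `smd_before`, `p_before`,
#'   `smd_after`, `p_after`.
#' @export
balance_diagnostics <- function(cohort, match,
                                covariates = c("age", "ajcc", "scf",
                                               "chemo"),
                                treat_level = "VMAT") {
  df <- if (inherits(cohort, "rt_cohort")) cohort$patients else cohort
  if (nrow(match$pairs) == 0L)
    stop("no matched pairs: balance diagnostics not computable")
  matched_ids <- c(match$pairs$treated_id, match$pairs$control_id)
  sub <- df[df$id %in% matched_ids, , drop = FALSE]
  one <- function(dat) {
    g1 <- dat$modality == treat_level
    vapply(covariates, function(v) {
      x <- as.numeric(dat[[v]])
      smd <- smd_num(x[g1], x[!g1])
      p <- if (v == "age") {
        suppressWarnings(stats::wilcox.test(x ~ g1)$p.value)
      } else {
        tab <- table(factor(dat[[v]]), g1)
        if (nrow(tab) > 1L)
          suppressWarnings(stats::chisq.test(tab)$p.value) else 1
      }
      c(smd = smd, p = p)
    }, numeric(2))
  }
  before <- one(df)
  after <- one(sub)
  data.frame(covariate = covariates,
             smd_before = before["smd", ], p_before = before["p", ],
             smd_after = after["smd", ], p_after = after["p", ],
             row.names = NULL)
}
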