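#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random event is
#' ranked above a random non-event, with half credit for ties.  Invariant
#' to any strictly increasing transform of the predictions.
#'
#' @param pred predicted risks or scores.
#' @param y binary 0/1 outcomes (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pred, y) {
  y <- as.numeric(y)
  stopifnot(length(pred) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute the AUC")
  r <- rank(pred)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into risk strata by quantiles of the predicted
#' probability (ties kept together) and compares observed with expected
#' event counts: `statistic = sum (O - E)^2 / (E (1 - E / n_g))`, referred
#' to a chi-square with `groups - 2` degrees of freedom (using the number
#' of groups actually formed when ties collapse strata).
#'
#' @param pred predicted probabilities.
#' @param y binary 0/1 outcomes.
#' @param groups target number of risk strata (default 10 deciles).
#' @return list with `statistic`, `df`, `p_value`, and the group table.
#' @export
hosmer_lemeshow <- function(pred, y, groups = 10) {
  y <- as.numeric(y)
  stopifnot(length(pred) == length(y), all(y %in% c(0, 1)))
  if (length(y) < 2 * groups)
    stop("need at least 2 observations per intended group")
  br <- unique(stats::quantile(pred, seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3) stop("predictions too tied to form risk groups")
  g <- cut(pred, br, include.lowest = TRUE)
  n_g <- as.numeric(table(g))
  O <- as.numeric(tapply(y, g, sum))
  E <- as.numeric(tapply(pred, g, sum))
  if (any(E <= 0) || any(E >= n_g))
    stop("a risk group has expected count 0 (or n); reduce 'groups'")
  stat <- sum((O - E)^2 / (E * (1 - E / n_g)))
  df <- length(n_g) - 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(group = levels(g), n = n_g, observed = O,
                          expected = E))
}

#' Scaled Brier score
#'
#' `1 - BS / BS_ref` where `BS = mean((pred - y)^2)` and `BS_ref =
#' pbar * (1 - pbar)` is the Brier score of the constant event-rate
#' prediction; 0 for a useless model, 1 for a perfect one.
#'
#' @inheritParams auc
#' @return scaled Brier score (<= 1).
#' @export
scaled_brier <- function(pred, y) {
  y <- as.numeric(y)
  stopifnot(length(pred) == length(y), all(y %in% c(0, 1)))
  pbar <- mean(y)
  if (pbar == 0 || pbar == 1)
    stop("both classes required: reference Brier score is 0")
  1 - mean((pred - y)^2) / (pbar * (1 - pbar))
}

#' Calibration slope and intercept
#'
#' Logistic recalibration: `y ~ logit(pred)` fit by maximum likelihood.
#' A slope of 1 indicates predictions on the correct scale; slopes below
#' 1 indicate overfitting (predictions too extreme).
#'
#' @inheritParams auc
#' @return list with `slope` and `intercept`.
#' @export
calibration_slope <- function(pred, y) {
  y <- as.numeric(y)
  stopifnot(length(pred) == length(y), all(y %in% c(0, 1)))
  if (any(pred <= 0 | pred >= 1))
    stop("pred must lie strictly in (0, 1)")
  if (stats::sd(pred) < 1e-12)
    stop("constant predictions: calibration slope undefined")
  lp <- stats::qlogis(pred)
  fit <- suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  cf <- stats::coef(fit)
  if (any(abs(cf) > 50)) stop("calibration model separated")
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]))
}

#' Performance report for a fitted LKB model
#'
#' Computes the standard model-performance panel on the fitting data:
#' discrimination (AUC), calibration (Hosmer-Lemeshow statistic and
#' p-value, calibration slope and intercept) and overall accuracy (scaled
#' Brier score).
#'
#' @param object an [fit_lkb()] result, or a list with `pred` and `y`.
#' @param groups Hosmer-Lemeshow group count.
#' @return an object of class `lkb_performance`.
#' @export
model_performance <- function(object, groups = 10) {
  if (inherits(object, "lkb_fit")) {
    pred <- fitted(object); y <- object$data$y
  } else {
    pred <- object$pred; y <- object$y
  }
  hl <- tryCatch(hosmer_lemeshow(pred, y, groups), error = function(e) NULL)
  cal <- tryCatch(calibration_slope(pred, y), error = function(e) NULL)
  structure(list(auc = auc(pred, y), hosmer_lemeshow = hl,
                 scaled_brier = scaled_brier(pred, y), calibration = cal),
            class = "lkb_performance")
}

#' @export
print.lkb_performance <- function(x, digits = 3, ...) {
  cat("Model performance\n")
  cat(sprintf("  AUC              %.3f\n", x$auc))
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("  Hosmer-Lemeshow  chi2 = %.3f (df %d), p = %.3f\n",
                x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
                x$hosmer_lemeshow$p_value))
  cat(sprintf("  scaled Brier     %.3f\n", x$scaled_brier))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration      slope %.3f, intercept %.3f\n",
                x$calibration$slope, x$calibration$intercept))
  invisible(x)
}
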