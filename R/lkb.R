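#' Lyman-Kutcher-Burman complication probability
#'
#' The LKB probit dose-response `NTCP = Phi((x - TV50) / (m * TV50))`,
#' with `x` a dosimetric factor (here typically the percent ipsilateral
#' lung volume receiving at least 40 Gy), `TV50` the factor value giving a
#' 50% complication probability and `m` the dimensionless slope
#' parameter.  With the volume parameter fixed at `n = 1` the model's
#' generalized-EUD reduction collapses and the selected factor is used
#' directly, so `TV50` carries the factor's units.
#'
#' @param x factor value(s).
#' @param tv50 factor value giving 50% complication probability (> 0).
#' @param m slope parameter (> 0); smaller is steeper.
#' @return complication probability in (0, 1), strictly increasing in `x`.
#' @examples
#' lkb_probability(15.07, tv50 = 15.07, m = 0.62)   # 0.5 by construction
#' invert_lkb(0.25, tv50 = 15.07, m = 0.62)         # ~8.8% planning threshold
#' @export
lkb_probability <- function(x, tv50, m) {
  stopifnot(tv50 > 0, m > 0)
  stats::pnorm((x - tv50) / (m * tv50))
}

#' @rdname lkb_probability
#' @param p complication probability in (0, 1).
#' @return `invert_lkb()`: the factor value at which the model predicts
#'   probability `p`, i.e. `TV50 * (1 + m * qnorm(p))`.
#' @export
invert_lkb <- function(p, tv50, m) {
  stopifnot(tv50 > 0, m > 0)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  tv50 * (1 + m * stats::qnorm(p))
}

lkb_negll <- function(tv50, m, x, y) {
  p <- stats::pnorm((x - tv50) / (m * tv50))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the LKB NTCP model by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of binary complication events
#' under the LKB probit dose-response over `TV50 in (0, 10 * max(x)]` and
#' `m in [0.01, 10]`, using bounded quasi-Newton (L-BFGS-B) from multiple
#' starting points (TV50 at several quantiles of `x` crossed with several
#' slopes, plus seeded jittered restarts).  Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` inside the log-likelihood.  95% confidence
#' intervals are profile-likelihood intervals (likelihood-ratio cutoff
#' `2 * dlnL = qchisq(level, 1)`, i.e. 3.84 at the default level), which
#' accommodate the asymmetry typical of the slope parameter.
#'
#' `fit_lkb()` is generic: the default method takes a numeric factor
#' vector and a binary event vector; the formula method takes
#' `events ~ factor` with a data.frame.
#'
#' @param x numeric vector of dosimetric factor values (or a formula).
#' @param events binary 0/1 event vector (e.g. grade-1+ pneumonitis).
#' @param factor_name label for the fitted factor, used in printing.
#' @param conf_level confidence level for the profile intervals.
#' @param n_starts number of additional seeded random restarts.
#' @param seed seed for the random restarts.
#' @param ... passed between methods.
#' @return an object of class `lkb_fit` with components `coefficients`
#'   (`TV50`, `m`), `loglik`, `ci` (profile intervals), `profile_delta`
#'   (achieved likelihood-ratio value at each interval endpoint), `n`,
#'   `n_events`, `data`, `converged`.
#' @examples
#' set.seed(1)
#' x <- runif(200, 2, 35)
#' y <- rbinom(200, 1, lkb_probability(x, 15, 0.6))
#' fit <- fit_lkb(x, y)
#' coef(fit); confint(fit)
#' @export
fit_lkb <- function(x, ...) UseMethod("fit_lkb")

#' @rdname fit_lkb
#' @export
fit_lkb.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L) stop("formula must be of the form events ~ factor")
  fit_lkb(mf[[2L]], as.numeric(mf[[1L]]),
          factor_name = names(mf)[2L], ...)
}

#' @rdname fit_lkb
#' @export
fit_lkb.default <- function(x, events, factor_name = "factor",
                            conf_level = 0.95, n_starts = 5, seed = 1,
                            ...) {
  x <- as.numeric(x)
  y <- as.numeric(events)
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(1 - y) == 0)
    stop("need at least one event and one non-event")
  if (diff(range(x)) < 1e-10)
    stop("all factor values identical: TV50 is not identifiable")

  upper_tv <- 10 * max(x)
  lower_tv <- max(1e-6, min(x[x > 0], upper_tv / 1e6) / 100)
  obj <- function(par) lkb_negll(par[1L], par[2L], x, y)

  qs <- stats::quantile(x, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE)
  qs <- pmin(pmax(qs, lower_tv * 2), upper_tv / 2)
  starts <- rbind(cbind(qs, 0.5), cbind(qs[c(2, 4)], c(0.2, 1.5)))
  set.seed(seed)
  extra <- cbind(stats::runif(n_starts, stats::quantile(x, 0.1) + 1e-6,
                              stats::quantile(x, 0.9) + 1e-3),
                 exp(stats::runif(n_starts, log(0.05), log(3))))
  starts <- rbind(starts, pmin(pmax(extra, lower_tv * 2), upper_tv / 2))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = c(lower_tv, 0.01), upper = c(upper_tv, 10),
                   control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("LKB fit failed to converge from any start")
  est <- best$par
  names(est) <- c("TV50", "m")
  loglik <- -best$value
  at_bound <- est[1L] >= upper_tv * (1 - 1e-6) || est[2L] >= 10 * (1 - 1e-6)
  if (at_bound)
    warning("LKB estimate at parameter bound; data may be separated or ",
            "uninformative for the slope")

  prof <- profile_ci_lkb(est, loglik, x, y, conf_level,
                         lower = c(lower_tv, 0.01),
                         upper = c(upper_tv, 10))

  structure(list(coefficients = est, loglik = loglik, ci = prof$ci,
                 profile_delta = prof$delta, conf_level = conf_level,
                 n = length(y), n_events = sum(y),
                 factor_name = factor_name,
                 data = list(x = x, y = y),
                 converged = best$convergence == 0 && !at_bound,
                 call = match.call()),
            class = "lkb_fit")
}

# profile-likelihood interval for one parameter of the LKB fit
profile_ci_lkb <- function(est, loglik, x, y, conf_level, lower, upper) {
  cut <- stats::qchisq(conf_level, df = 1)
  prof_ll <- function(i, val) {
    o <- if (i == 1L)
      stats::optimize(function(m) lkb_negll(val, m, x, y),
                      c(lower[2L], upper[2L]), tol = 1e-9)
    else
      stats::optimize(function(t) lkb_negll(t, val, x, y),
                      c(lower[1L], upper[1L]), tol = 1e-9)
    -o$objective
  }
  ci <- matrix(NA_real_, 2, 2,
               dimnames = list(names(est), c("lower", "upper")))
  delta <- ci
  for (i in 1:2) {
    f <- function(val) 2 * (loglik - prof_ll(i, val)) - cut
    for (side in 1:2) {
      dir <- if (side == 1L) -1 else 1
      bound <- if (side == 1L) lower[i] else upper[i]
      step <- max(abs(est[i]) * 0.1, 1e-3)
      a <- est[i]; b <- est[i] + dir * step
      found <- FALSE
      for (k in 1:60) {
        b <- max(min(b, upper[i]), lower[i])
        if (f(b) >= 0) { found <- TRUE; break }
        if (b == bound) break
        a <- b
        b <- b + dir * step * 2^k
      }
      if (found) {
        r <- stats::uniroot(f, sort(c(a, b)), tol = 1e-7)
        ci[i, side] <- r$root
        delta[i, side] <- 2 * (loglik - prof_ll(i, r$root))
      } else {
        ci[i, side] <- bound
        delta[i, side] <- 2 * (loglik - prof_ll(i, bound))
      }
    }
  }
  list(ci = ci, delta = delta)
}

#' @export
print.lkb_fit <- function(x, digits = 4, ...) {
  cat(sprintf("LKB NTCP model fit (n = 1 volume parameter), factor: %s\n",
              x$factor_name))
  cat(sprintf("  %d patients, %d events\n", x$n, x$n_events))
  cf <- stats::coef(x)
  for (i in seq_along(cf))
    cat(sprintf("  %-5s %8.4g  (%d%% CI %.4g-%.4g)\n", names(cf)[i], cf[i],
                round(100 * x$conf_level), x$ci[i, 1], x$ci[i, 2]))
  cat(sprintf("  log-likelihood %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.lkb_fit <- function(object, ...) object$coefficients

#' @export
logLik.lkb_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n, class = "logLik")
}

#' @export
confint.lkb_fit <- function(object, parm, level = 0.95, ...) {
  if (abs(level - object$conf_level) > 1e-12) {
    prof <- profile_ci_lkb(object$coefficients, object$loglik,
                           object$data$x, object$data$y, level,
                           lower = c(1e-6, 0.01),
                           upper = c(10 * max(object$data$x), 10))
    ci <- prof$ci
  } else ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.lkb_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    newdata[[object$factor_name]]
  } else as.numeric(newdata)
  cf <- object$coefficients
  t <- (x - cf[["TV50"]]) / (cf[["m"]] * cf[["TV50"]])
  if (type == "link") t else stats::pnorm(t)
}

#' @export
fitted.lkb_fit <- function(object, ...) predict(object)

#' @export
residuals.lkb_fit <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$data$y
  p <- pmin(pmax(fitted(object), 1e-12), 1 - 1e-12)
  switch(type,
         response = y - p,
         pearson = (y - p) / sqrt(p * (1 - p)),
         deviance = sign(y - p) *
           sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))))
}

#' @export
simulate.lkb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted(object)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.lkb_fit <- function(object, ...) {
  perf <- model_performance(object)
  structure(list(fit = object, performance = perf),
            class = "summary.lkb_fit")
}

#' @export
print.summary.lkb_fit <- function(x, ...) {
  print(x$fit)
  print(x$performance)
  invisible(x)
}

#' Dose-response curve of a fitted LKB model
#'
#' Plots the fitted NTCP curve over the observed factor range with the
#' profile-CI band at TV50, a rug of events (top) and non-events
#' (bottom), and binned observed complication proportions.
#'
#' @param x an `lkb_fit`.
#' @param bins number of quantile bins for observed proportions.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.lkb_fit <- function(x, bins = 6, ...) {
  xs <- x$data$x; y <- x$data$y
  grid <- seq(min(xs) * 0.8, max(xs) * 1.1, length.out = 200)
  cf <- stats::coef(x)
  graphics::plot(grid, lkb_probability(grid, cf[["TV50"]], cf[["m"]]),
                 type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = x$factor_name, ylab = "NTCP", ...)
  graphics::rug(xs[y == 1], side = 3)
  graphics::rug(xs[y == 0], side = 1)
  br <- unique(stats::quantile(xs, seq(0, 1, length.out = bins + 1)))
  if (length(br) > 2) {
    g <- cut(xs, br, include.lowest = TRUE)
    graphics::points(tapply(xs, g, mean), tapply(y, g, mean), pch = 19)
  }
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = cf[["TV50"]], lty = 3)
  invisible(x)
}
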