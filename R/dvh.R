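#' Dose-volume histogram objects
#'
#' A `dvh` object represents one organ's dose-volume curve in either
#' cumulative or differential form.  Doses are in Gy, volumes in percent of
#' the organ volume.
#'
#' In cumulative mode, `dose` and `volume` have equal length and
#' `volume[i]` is the percent of the organ receiving at least `dose[i]` Gy;
#' the curve starts at `V(0) = 100` and is non-increasing.  In differential
#' mode, `dose` holds the `m + 1` bin edges (starting at 0) and `volume`
#' the `m` per-bin percent volumes, which sum to 100.
#'
#' @param dose numeric vector of doses in Gy, strictly increasing, starting
#'   at 0.  For differential mode these are bin edges (one more element than
#'   `volume`).
#' @param volume numeric vector of percent volumes (see Details).
#' @param organ character label for the organ.
#' @param mode `"cumulative"` or `"differential"`.
#' @param total_volume_cc optional absolute organ volume in cc; carried as
#'   metadata, never used by downstream dosimetric computations (all of
#'   which work on relative volume).
#' @return an object of class `dvh`.
#' @examples
#' d <- dvh(c(0, 20, 40), c(60, 40), mode = "differential")
#' v_at(d, 20)
#' mean_dose(d)
#' @export
dvh <- function(dose, volume, organ = "organ",
                mode = c("cumulative", "differential"),
                total_volume_cc = NULL) {
  mode <- match.arg(mode)
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  x <- structure(
    list(organ = as.character(organ)[1L], mode = mode, dose = dose,
         volume = volume, total_volume_cc = total_volume_cc),
    class = "dvh")
  validate_dvh(x)
  x
}

validate_dvh <- function(x) {
  dose <- x$dose
  volume <- x$volume
  if (length(dose) < 1L || anyNA(dose) || anyNA(volume))
    stop("DVH must have at least one dose point and no missing values")
  if (any(diff(dose) <= 0))
    stop("DVH doses must be strictly increasing")
  if (dose[1L] != 0)
    stop("DVH dose axis must start at 0 Gy")
  if (any(volume < -1e-9))
    stop("DVH volumes must be non-negative")
  if (x$mode == "cumulative") {
    if (length(volume) != length(dose))
      stop("cumulative DVH needs one volume per dose point")
    if (abs(volume[1L] - 100) > 1e-6)
      stop("cumulative DVH must equal 100% at dose 0")
    if (any(diff(volume) > 1e-9))
      stop("cumulative DVH volumes must be non-increasing in dose")
  } else {
    if (length(volume) != length(dose) - 1L)
      stop("differential DVH needs one volume per bin (length(dose) - 1)")
    if (abs(sum(volume) - 100) > 1e-6)
      stop("differential DVH volumes must sum to 100%")
  }
  invisible(x)
}

#' @export
print.dvh <- function(x, ...) {
  nb <- if (x$mode == "cumulative") length(x$dose) else length(x$volume)
  cat(sprintf("<dvh> %s (%s), %d %s, dose range 0-%g Gy\n",
              x$organ, x$mode, nb,
              if (x$mode == "cumulative") "points" else "bins",
              max(x$dose)))
  invisible(x)
}

#' @rdname dvh
#' @param x object to test.
#' @export
is_dvh <- function(x) inherits(x, "dvh")

#' Convert a DVH between cumulative and differential form
#'
#' `to_cumulative()` returns the cumulative curve `V(x)` = percent volume
#' receiving at least `x` Gy on the same bin edges; `to_differential()` is
#' its inverse.  Both are idempotent, and a differential -> cumulative ->
#' differential round trip reproduces the input to floating-point accuracy.
#' A cumulative curve whose last value has not reached 0 has the residual
#' volume assigned to one trailing bin (of the last bin's width) when
#' converted to differential form; in practice cumulative curves terminate
#' at 0.
#'
#' @param d a [dvh] object.
#' @return a [dvh] in the requested mode.
#' @export
to_cumulative <- function(d) {
  stopifnot(is_dvh(d))
  if (d$mode == "cumulative") return(d)
  v <- c(rev(cumsum(rev(d$volume))), 0)
  # anchor exactly at 100 to absorb cumsum rounding (input sums to 100 +- 1e-6)
  v[1L] <- 100
  dvh(d$dose, v, organ = d$organ, mode = "cumulative",
      total_volume_cc = d$total_volume_cc)
}

#' @rdname to_cumulative
#' @export
to_differential <- function(d) {
  stopifnot(is_dvh(d))
  if (d$mode == "differential") return(d)
  edges <- d$dose
  v <- -diff(d$volume)
  residual <- d$volume[length(d$volume)]
  if (residual > 1e-9) {
    w <- if (length(edges) >= 2L) diff(edges)[length(edges) - 1L] else 1
    edges <- c(edges, edges[length(edges)] + w)
    v <- c(v, residual)
  }
  v <- pmax(v, 0)
  v <- v * (100 / sum(v))
  dvh(edges, v, organ = d$organ, mode = "differential",
      total_volume_cc = d$total_volume_cc)
}

#' Percent volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative dose-volume curve, so `v_at(d, 5)`
#' is the V5 metric (percent of the organ receiving at least 5 Gy).  Doses
#' beyond the last recorded point return 0.
#'
#' @param d a [dvh] object.
#' @param x dose(s) in Gy, non-negative.
#' @return percent volume(s) in `[0, 100]`.
#' @export
v_at <- function(d, x) {
  stopifnot(is_dvh(d))
  if (any(x < 0)) stop("dose threshold must be non-negative")
  cd <- to_cumulative(d)
  if (length(cd$dose) == 1L) return(ifelse(x <= cd$dose, 100, 0))
  stats::approx(cd$dose, cd$volume, xout = x, yright = 0,
                ties = "ordered")$y
}

#' Mean organ dose
#'
#' Volume-weighted mean of bin midpoint doses over the differential
#' representation, equal to the integral of the cumulative curve over dose
#' divided by 100.
#'
#' @param d a [dvh] object.
#' @return mean dose in Gy.
#' @export
mean_dose <- function(d) {
  dd <- to_differential(d)
  if (sum(dd$volume) <= 0) stop("empty DVH")
  mids <- (dd$dose[-1L] + dd$dose[-length(dd$dose)]) / 2
  sum(mids * dd$volume) / sum(dd$volume)
}

#' Dosimetric summary vector (MD and V_x metrics)
#'
#' Extracts the mean dose and the percent volumes receiving at least each
#' threshold dose.  For the ipsilateral lung these are the MD and the
#' IV5...IV50 candidate predictors of radiation pneumonitis.
#'
#' @param d a [dvh] object.
#' @param thresholds strictly increasing dose thresholds in Gy; default
#'   5, 10, ..., 50.
#' @return named numeric vector `c(MD = ..., V5 = ..., ...)`.
#' @export
dosimetric_vector <- function(d, thresholds = seq(5, 50, by = 5)) {
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  out <- c(MD = mean_dose(d))
  if (length(thresholds)) {
    v <- v_at(d, thresholds)
    names(v) <- paste0("V", format(thresholds, trim = TRUE, digits = 12))
    out <- c(out, v)
  }
  out
}

#' A DVH for an organ uniformly irradiated at one dose
#'
#' Convenience constructor placing the whole organ volume in one narrow
#' differential bin centred on `dose_gy` (half-width `width`).
#'
#' @param dose_gy the uniform dose in Gy.
#' @param width half-width of the bin in Gy.
#' @param organ organ label.
#' @return a differential [dvh].
#' @export
uniform_dvh <- function(dose_gy, width = 1e-6, organ = "organ") {
  stopifnot(dose_gy >= 0, width > 0)
  if (dose_gy <= width) {
    dvh(c(0, dose_gy + width), 100, organ = organ, mode = "differential")
  } else {
    dvh(c(0, dose_gy - width, dose_gy + width), c(0, 100),
        organ = organ, mode = "differential")
  }
}

#' Read and write DVH files
#'
#' The file dialect is a long-format CSV with header
#' `organ,mode,dose_Gy,volume` and one row per dose point, grouping rows by
#' organ.  Cumulative curves list `(dose, V(dose))` pairs.  Differential
#' curves list each bin's lower edge with its percent volume, followed by a
#' terminating row holding the final bin edge with volume 0, so that the
#' full edge vector round-trips exactly.
#'
#' @param path path to a CSV file (or connection for reading).
#' @return `read_dvh_file()`: a named list of [dvh] objects, one per organ.
#' @export
read_dvh_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "mode", "dose_Gy", "volume")
  if (!identical(names(df)[seq_along(need)], need))
    stop("malformed DVH header: expected columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("empty DVH file")
  rows <- seq_len(nrow(df))
  out <- list()
  for (org in unique(df$organ)) {
    idx <- which(df$organ == org)
    sub <- df[idx, ]
    mode <- unique(sub$mode)
    if (length(mode) != 1L || !mode %in% c("cumulative", "differential"))
      stop(sprintf("organ '%s': mode must be a single value, 'cumulative' or 'differential' (row %d)",
                   org, idx[1L]))
    if (anyNA(sub$dose_Gy) || anyNA(sub$volume))
      stop(sprintf("organ '%s': missing dose or volume (row %d)",
                   org, idx[which(is.na(sub$dose_Gy) | is.na(sub$volume))[1L]]))
    bad <- which(diff(sub$dose_Gy) <= 0)
    if (length(bad))
      stop(sprintf("organ '%s': dose not strictly increasing at row %d",
                   org, idx[bad[1L] + 1L]))
    neg <- which(sub$volume < 0)
    if (length(neg))
      stop(sprintf("organ '%s': negative volume at row %d", org, idx[neg[1L]]))
    if (mode == "cumulative") {
      inc <- which(diff(sub$volume) > 1e-9)
      if (length(inc))
        stop(sprintf("organ '%s': cumulative volume increases with dose at row %d",
                     org, idx[inc[1L] + 1L]))
      d <- dvh(sub$dose_Gy, sub$volume, organ = org, mode = "cumulative")
    } else {
      n <- nrow(sub)
      if (n < 2L || sub$volume[n] != 0)
        stop(sprintf("organ '%s': differential DVH must end with a zero-volume edge row (row %d)",
                     org, idx[n]))
      d <- dvh(sub$dose_Gy, sub$volume[-n], organ = org, mode = "differential")
    }
    out[[org]] <- d
  }
  out
}

#' @rdname read_dvh_file
#' @param dvhs a [dvh] or list of [dvh] objects.
#' @export
write_dvh_file <- function(dvhs, path) {
  if (is_dvh(dvhs)) dvhs <- list(dvhs)
  rows <- lapply(dvhs, function(d) {
    if (d$mode == "cumulative") {
      data.frame(organ = d$organ, mode = d$mode, dose_Gy = d$dose,
                 volume = d$volume)
    } else {
      data.frame(organ = d$organ, mode = d$mode, dose_Gy = d$dose,
                 volume = c(d$volume, 0))
    }
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
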