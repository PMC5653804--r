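#' Configuration for the end-to-end analysis pipeline
#'
#' @param mode `"synthesize"` (generate a cohort from `synth`) or
#'   `"cohort"` (load one with [read_cohort()] from `cohort_dir`).
#' @param synth a [synth_config()] used when synthesizing.
#' @param cohort_dir cohort directory used when `mode = "cohort"`.
#' @param covariates propensity/matching covariates.
#' @param treat_arm arm fully matched against the other (each of its
#'   patients seeks a control), default `"IMRT"` as the smaller arm.
#' @param caliper_mult caliper multiplier on the pooled logit SD.
#' @param thresholds candidate V_x thresholds in Gy (plus MD always).
#' @param ntcp_organ organ whose DVHs drive the NTCP analysis.
#' @param min_grade event endpoint: grade >= `min_grade`.
#' @param lasso list of [cv_select()] settings (`k`, `rule`, `loss`,
#'   `nlambda`).
#' @param scr list of SCR settings: `params_path` (organ parameter file,
#'   `NULL` to skip), `n_fractions`, `age_a`, `age_cutoff`, `test`.
#' @param seed global seed; each stage derives its own seed from it by a
#'   fixed offset so stages can be re-run in isolation.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthesize", "cohort"),
                            synth = synth_config(n_per_arm = 32),
                            cohort_dir = NULL,
                            covariates = c("age", "ajcc", "scf", "chemo"),
                            treat_arm = "IMRT", caliper_mult = 0.2,
                            thresholds = seq(5, 50, by = 5),
                            ntcp_organ = "lung_ipsi", min_grade = 1,
                            lasso = list(k = 10, rule = "1se",
                                         loss = "deviance", nlambda = 100),
                            scr = list(
                              params_path = system.file(
                                "extdata", "organ_params_synthetic.csv",
                                package = "rtrisk"),
                              n_fractions = 30, age_a = 70,
                              age_cutoff = 65, test = "wilcox"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (mode == "cohort" && (is.null(cohort_dir) || !dir.exists(cohort_dir)))
    stop("mode 'cohort' requires an existing cohort_dir")
  structure(list(mode = mode, synth = synth, cohort_dir = cohort_dir,
                 covariates = covariates, treat_arm = treat_arm,
                 caliper_mult = caliper_mult, thresholds = thresholds,
                 ntcp_organ = ntcp_organ, min_grade = min_grade,
                 lasso = lasso, scr = scr, seed = seed),
            class = "pipeline_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full matched-cohort toxicity and risk analysis
#'
#' Orchestrates the analysis end to end: load or synthesize a cohort,
#' estimate propensity scores and match the arms 1:1 within the caliper,
#' extract the dosimetric candidate factors from the ipsilateral-lung
#' DVHs, select the dominant factor by cross-validated LASSO, fit the LKB
#' NTCP model to the grade-1+ pneumonitis endpoint with validation
#' metrics, run the Schneider secondary-cancer-risk models per organ, and
#' compare arms.  Each stage writes a plain-text artifact to `out_dir`.
#' A failure of the SCR stage (e.g. missing organ parameters) is logged
#' and does not abort the NTCP arm, and vice versa.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, an object of class `rt_report` bundling all stage
#'   results and `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("rtrisk_")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # stage seeds fan out from the global seed by fixed offsets
  seed_synth <- cfg$seed + 101L
  seed_folds <- cfg$seed + 202L
  seed_fit <- cfg$seed + 303L
  note("pipeline seed %d (synth %d, folds %d, fit %d)", cfg$seed,
       seed_synth, seed_folds, seed_fit)

  cohort <- if (cfg$mode == "synthesize") {
    sc <- cfg$synth
    sc$seed <- seed_synth
    generate_cohort(sc)
  } else {
    read_cohort(cfg$cohort_dir)
  }
  note("cohort: %d patients (%s)", nrow(cohort$patients),
       paste(sprintf("%s %d", names(table(cohort$patients$modality)),
                     table(cohort$patients$modality)), collapse = ", "))

  ps <- fit_propensity(cohort, cfg$covariates)
  treated <- cohort$patients$modality == cfg$treat_arm
  match <- match_caliper(ps$p, treated, ids = cohort$patients$id,
                         caliper_mult = cfg$caliper_mult)
  note("matching: %d pairs within caliper %.4f, %d unmatched",
       nrow(match$pairs), match$caliper, length(match$unmatched))
  matched <- subset_cohort(cohort, c(match$pairs$treated_id,
                                     match$pairs$control_id))
  balance <- balance_diagnostics(cohort, match, cfg$covariates)
  t1 <- table_one(matched)
  utils::write.csv(t1, file.path(out_dir, "table_one.csv"),
                   row.names = FALSE)
  utils::write.csv(match$pairs, file.path(out_dir, "matches.csv"),
                   row.names = FALSE)
  utils::write.csv(balance, file.path(out_dir, "balance.csv"),
                   row.names = FALSE)

  ntcp <- tryCatch({
    X <- cohort_factors(matched, cfg$ntcp_organ, cfg$thresholds)
    y <- as.integer(matched$patients$rp_grade >= cfg$min_grade)
    sel <- cv_select(X, y, k = cfg$lasso$k, rule = cfg$lasso$rule,
                     loss = cfg$lasso$loss, seed = seed_folds,
                     nlambda = cfg$lasso$nlambda)
    note("selection: dominant factor %s at lambda %.4g", sel$factor,
         sel$lambda)
    fit <- fit_lkb(X[, sel$factor], y, factor_name = sel$factor,
                   seed = seed_fit)
    perf <- model_performance(fit)
    ev <- count_rp_events(matched, cfg$min_grade)
    write_json_report(list(
      factor = sel$factor, ranking = sel$ranking,
      lambda = sel$lambda, rule = cfg$lasso$rule),
      file.path(out_dir, "selection.json"))
    write_json_report(list(
      factor = fit$factor_name,
      estimates = as.list(stats::coef(fit)),
      ci = list(TV50 = as.numeric(fit$ci["TV50", ]),
                m = as.numeric(fit$ci["m", ])),
      loglik = fit$loglik, n = fit$n, events = fit$n_events,
      performance = list(
        auc = perf$auc,
        hosmer_lemeshow = perf$hosmer_lemeshow[c("statistic", "df",
                                                 "p_value")],
        scaled_brier = perf$scaled_brier,
        calibration = perf$calibration)),
      file.path(out_dir, "ntcp_fit.json"))
    grid <- seq(0, max(X[, sel$factor]) * 1.2, length.out = 200)
    utils::write.csv(
      data.frame(factor = grid,
                 ntcp = lkb_probability(grid, stats::coef(fit)[["TV50"]],
                                        stats::coef(fit)[["m"]])),
      file.path(out_dir, "dose_response.csv"), row.names = FALSE)
    list(selection = sel, fit = fit, performance = perf, events = ev,
         factors = X, y = y)
  }, error = function(e) {
    note("NTCP stage failed: %s", conditionMessage(e))
    NULL
  })

  scr <- if (!is.null(cfg$scr$params_path) &&
             nzchar(cfg$scr$params_path) &&
             file.exists(cfg$scr$params_path)) {
    tryCatch({
      params <- read_organ_params(cfg$scr$params_path)
      res <- withCallingHandlers(
        cohort_scr(matched, params, n_fractions = cfg$scr$n_fractions,
                   age_a = cfg$scr$age_a, age_cutoff = cfg$scr$age_cutoff,
                   test = cfg$scr$test),
        warning = function(w) {
          note("SCR warning: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      utils::write.csv(res$per_patient,
                       file.path(out_dir, "scr_per_patient.csv"),
                       row.names = FALSE)
      utils::write.csv(res$summary,
                       file.path(out_dir, "scr_summary.csv"),
                       row.names = FALSE)
      res
    }, error = function(e) {
      note("SCR stage failed: %s", conditionMessage(e))
      NULL
    })
  } else {
    note("SCR stage skipped: no organ parameter file configured")
    NULL
  }

  comparisons <- NULL
  if (!is.null(ntcp)) {
    arm <- matched$patients$modality
    counts <- table(arm, event = ntcp$y)
    p_counts <- suppressWarnings(
      stats::chisq.test(counts, correct = FALSE)$p.value)
    pred <- fitted(ntcp$fit)
    p_ntcp <- suppressWarnings(stats::wilcox.test(pred ~ arm)$p.value)
    comparisons <- data.frame(
      quantity = c("rp_events", "ntcp"),
      test = c("chi-square (no continuity correction)", "rank-sum"),
      p = c(p_counts, p_ntcp))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }

  writeLines(log_lines, log_path)
  invisible(structure(list(config = cfg, cohort = cohort, matched = matched,
                           propensity = ps, match = match,
                           balance = balance, table_one = t1, ntcp = ntcp,
                           scr = scr, comparisons = comparisons,
                           out_dir = out_dir),
                      class = "rt_report"))
}

#' @export
print.rt_report <- function(x, ...) {
  cat("<rt_report>\n")
  cat(sprintf("  matched pairs: %d\n", nrow(x$match$pairs)))
  if (!is.null(x$ntcp)) {
    cat(sprintf("  dominant factor: %s\n", x$ntcp$selection$factor))
    cf <- stats::coef(x$ntcp$fit)
    cat(sprintf("  LKB fit: TV50 = %.3f, m = %.3f\n", cf[["TV50"]],
                cf[["m"]]))
  }
  if (!is.null(x$scr))
    cat(sprintf("  SCR organs: %s\n",
                paste(unique(x$scr$per_patient$organ), collapse = ", ")))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

mean_dvh_curve <- function(cohort, organ, grid = seq(0, 70, by = 0.5)) {
  ids <- cohort$patients$id
  vs <- vapply(ids, function(id) {
    d <- cohort$dvhs[[id]][[organ]]
    if (is.null(d)) return(rep(NA_real_, length(grid)))
    v_at(d, grid)
  }, numeric(length(grid)))
  rowMeans(vs, na.rm = TRUE)
}

#' Figures for a pipeline report bundle
#'
#' Writes five PNG figures from a [run_pipeline()] bundle: mean
#' ipsilateral-lung DVHs by arm, the fitted NTCP dose-response curve, the
#' selected factor vs NTCP scatter by arm, per-organ OED/EAR bars, and
#' the NTCP vs EAR trend scatter.
#'
#' @param bundle an `rt_report`.
#' @param out_dir output directory (default the bundle's).
#' @return character vector of the files written.
#' @export
make_figures <- function(bundle, out_dir = bundle$out_dir) {
  stopifnot(inherits(bundle, "rt_report"))
  missing_parts <- c(
    if (is.null(bundle$matched)) "matched cohort",
    if (is.null(bundle$ntcp)) "ntcp results")
  if (length(missing_parts))
    stop("bundle is missing: ", paste(missing_parts, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  pngf <- function(name, fun, width = 700, height = 500) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    files <<- c(files, path)
  }
  matched <- bundle$matched
  arms <- sort(unique(matched$patients$modality))
  if (length(arms) < 2L)
    warning("single-arm bundle: group figures degrade to one series")
  organ <- bundle$config$ntcp_organ
  grid <- seq(0, 70, by = 0.5)

  pngf("fig_mean_dvh.png", function() {
    graphics::plot(NULL, xlim = range(grid), ylim = c(0, 100),
                   xlab = "Dose (Gy)", ylab = "Volume (%)",
                   main = paste("Mean cumulative DVH,", organ))
    for (i in seq_along(arms)) {
      sub <- subset_cohort(matched,
                           matched$patients$id[matched$patients$modality ==
                                                 arms[i]])
      graphics::lines(grid, mean_dvh_curve(sub, organ, grid), col = i,
                      lwd = 2, lty = i)
    }
    graphics::legend("topright", legend = arms, col = seq_along(arms),
                     lwd = 2, lty = seq_along(arms))
  })

  pngf("fig_ntcp_curve.png", function() plot(bundle$ntcp$fit,
                                             main = "LKB NTCP fit"))

  pngf("fig_factor_scatter.png", function() {
    sel <- bundle$ntcp$selection$factor
    xv <- bundle$ntcp$factors[, sel]
    pred <- fitted(bundle$ntcp$fit)
    cols <- match(matched$patients$modality, arms)
    graphics::plot(xv, pred, col = cols, pch = 19, xlab = sel,
                   ylab = "NTCP", main = "Selected factor vs NTCP by arm")
    graphics::legend("topleft", legend = arms, col = seq_along(arms),
                     pch = 19)
  })

  if (!is.null(bundle$scr)) {
    pngf("fig_oed_ear.png", function() {
      s <- bundle$scr$summary
      op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
      on.exit(graphics::par(op), add = TRUE)
      for (what in c("oed", "ear")) {
        m <- t(as.matrix(s[, paste0(what, "_mean_", arms), drop = FALSE]))
        colnames(m) <- s$organ
        graphics::barplot(m, beside = TRUE, las = 2,
                          col = seq_along(arms),
                          main = toupper(what),
                          ylab = if (what == "oed") "Gy" else
                            "excess cases / 10,000 PY")
        graphics::legend("topright", legend = arms,
                         fill = seq_along(arms))
      }
    })
    pngf("fig_ntcp_vs_ear.png", function() {
      lung <- bundle$scr$per_patient[
        bundle$scr$per_patient$organ == organ, ]
      pred <- fitted(bundle$ntcp$fit)
      names(pred) <- matched$patients$id
      common <- intersect(lung$id, names(pred))
      lung <- lung[match(common, lung$id), ]
      cols <- match(lung$modality, arms)
      graphics::plot(pred[common], lung$ear, col = cols, pch = 19,
                     xlab = "NTCP (grade 1+ RP)",
                     ylab = "EAR (excess cases / 10,000 PY)",
                     main = paste("NTCP vs EAR,", organ))
      graphics::legend("topleft", legend = arms, col = seq_along(arms),
                       pch = 19)
    })
  }
  files
}
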