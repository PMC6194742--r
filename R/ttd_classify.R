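# Reverse-causality screening: regress pair-level log fold-change on time
# to diagnosis (ttd) and classify each feature as potentially causal (C,
# difference constant in ttd), potentially reactive (R, difference shrinks
# toward zero with increasing ttd) or indeterminate (I, difference grows).

#' Pair-level log fold-changes
#'
#' `logFC = normalized log(case) - normalized log(control)` for every
#' matched pair and feature, with the pair's time to diagnosis attached.
#'
#' @param normmatrix features x samples matrix of normalized log
#'   intensities.
#' @param samples sample metadata; every pair must have exactly one case
#'   and one control among the matrix columns, with a ttd.
#' @param feature_ids features to compute (default all rows).
#' @return data.frame: feature_id, pair_id, ttd, logfc.
#' @export
pair_log_fold_change <- function(normmatrix, samples,
                                 feature_ids = rownames(normmatrix)) {
  smp <- study_frame(normmatrix, samples)
  cases <- smp[smp$caco == "case", ]
  ctrls <- smp[smp$caco == "control", ]
  if (anyDuplicated(cases$pair_id) || anyDuplicated(ctrls$pair_id))
    stop("a pair has more than one case or control")
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  if (anyNA(ctrls$sample_id)) stop("incomplete case-control pairs")
  if (anyNA(cases$ttd_years)) stop("missing time to diagnosis")
  m <- normmatrix[feature_ids, , drop = FALSE]
  d <- m[, cases$sample_id, drop = FALSE] - m[, ctrls$sample_id, drop = FALSE]
  data.frame(
    feature_id = rep(feature_ids, times = nrow(cases)),
    pair_id = rep(cases$pair_id, each = length(feature_ids)),
    ttd = rep(cases$ttd_years, each = length(feature_ids)),
    logfc = as.vector(d),
    stringsAsFactors = FALSE
  )
}

#' Regress log fold-change on time to diagnosis
#'
#' Unweighted OLS of pair-level logFC on ttd for each feature, with the
#' two-sided slope p-value and 95% pointwise confidence-band parameters.
#'
#' @param records data.frame from [pair_log_fold_change()].
#' @param alpha significance level for the slope test (default 0.05).
#' @param ttd_range observed ttd range used by the magnitude rule; default
#'   the range of `records$ttd`.
#' @return object of class `ttd_fit`: data.frame with feature_id,
#'   intercept, slope, slope_se, slope_p, sigma, n, class.
#' @export
ttd_regress <- function(records, alpha = 0.05, ttd_range = NULL) {
  stopifnot(all(c("feature_id", "ttd", "logfc") %in% names(records)))
  if (is.null(ttd_range)) ttd_range <- range(records$ttd)
  out <- do.call(rbind, lapply(split(records, records$feature_id), function(r) {
    n <- nrow(r)
    if (n < 3 || length(unique(r$ttd)) < 2) {
      return(data.frame(feature_id = r$feature_id[1], intercept = NA_real_,
                        slope = NA_real_, slope_se = NA_real_,
                        slope_p = NA_real_, sigma = NA_real_, n = n,
                        class = NA_character_, stringsAsFactors = FALSE))
    }
    fit <- lm(logfc ~ ttd, data = r)
    # a zero-residual line is a legitimate input (noise-free fixtures)
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    co <- sm$coefficients
    data.frame(
      feature_id = r$feature_id[1],
      intercept = co["(Intercept)", "Estimate"],
      slope = co["ttd", "Estimate"],
      slope_se = co["ttd", "Std. Error"],
      slope_p = co["ttd", "Pr(>|t|)"],
      sigma = sm$sigma, n = n,
      class = classify_feature(co["(Intercept)", "Estimate"],
                               co["ttd", "Estimate"],
                               co["ttd", "Pr(>|t|)"],
                               ttd_range[1], ttd_range[2], alpha),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  # preserve input feature order
  out <- out[match(unique(records$feature_id), out$feature_id), ]
  rownames(out) <- NULL
  class(out) <- c("ttd_fit", "data.frame")
  attr(out, "ttd_range") <- ttd_range
  attr(out, "alpha") <- alpha
  out
}

#' Classify one ttd regression fit
#'
#' C (potentially causal) when the slope is not significant
#' (`p > alpha`).  Otherwise the fitted absolute difference
#' `D(t) = |intercept + slope * t|` is compared at the ends of the observed
#' ttd range: R (potentially reactive) when `D(ttd_max) < D(ttd_min)` — the
#' case-control difference shrinks toward zero with increasing ttd — and
#' I (indeterminate) when it grows or is unchanged.
#'
#' @param intercept,slope,slope_p fit parameters.
#' @param ttd_min,ttd_max observed ttd range (years).
#' @param alpha significance level (default 0.05).
#' @return `"C"`, `"R"` or `"I"` (NA for an undefined fit).
#' @export
classify_feature <- function(intercept, slope, slope_p, ttd_min, ttd_max,
                             alpha = 0.05) {
  if (any(is.na(c(intercept, slope, slope_p)))) return(NA_character_)
  if (slope_p > alpha) return("C")
  d_min <- abs(intercept + slope * ttd_min)
  d_max <- abs(intercept + slope * ttd_max)
  if (d_max < d_min) "R" else "I"
}

#' Per-class tallies and per-feature summary
#'
#' @param fits a `ttd_fit` data.frame.
#' @return list with `table` (the fits) and `tally` (named counts over
#'   C/R/I).
#' @export
classification_report <- function(fits) {
  tally <- table(factor(fits$class, levels = c("C", "R", "I")))
  list(table = fits, tally = setNames(as.integer(tally), names(tally)))
}

#' Export scatter + fit-line + confidence-band plot data
#'
#' Emits, per feature, the pair-level points and the fitted line with a 95%
#' pointwise confidence band on a ttd grid, as plain tables suitable for
#' external plotting.
#'
#' @param records data.frame from [pair_log_fold_change()].
#' @param fits matching `ttd_fit`.
#' @param n_grid number of grid points for the band (default 50).
#' @param level confidence level (default 0.95).
#' @return list with `points` and `band` data.frames.
#' @export
ttd_plot_data <- function(records, fits, n_grid = 50, level = 0.95) {
  bands <- do.call(rbind, lapply(split(records, records$feature_id),
                                 function(r) {
    if (nrow(r) < 3 || length(unique(r$ttd)) < 2) return(NULL)
    fit <- lm(logfc ~ ttd, data = r)
    grid <- data.frame(ttd = seq(min(r$ttd), max(r$ttd),
                                 length.out = n_grid))
    pr <- predict(fit, newdata = grid, interval = "confidence",
                  level = level)
    data.frame(feature_id = r$feature_id[1], ttd = grid$ttd,
               fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"],
               stringsAsFactors = FALSE)
  }))
  rownames(bands) <- NULL
  list(points = records, band = bands)
}
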