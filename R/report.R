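# Cohort descriptive statistics, volcano-plot export, and the in-sample
# classification rate for a selected feature set.

#' Cohort descriptive table
#'
#' Per covariate: case/control medians with min/max for continuous
#' variables (two-sided Wilcoxon rank-sum p-value, unpaired) or level
#' counts for categorical variables (chi-square p-value).  Covariates with
#' a single distinct value get an `NA` p-value with a warning.
#'
#' @param samples sample metadata (study samples with `caco` are used).
#' @param covariates column names to summarize.
#' @return data.frame: covariate, statistic, cases, controls, p_value
#'   (p repeated across a covariate's rows).
#' @export
cohort_table <- function(samples,
                         covariates = c("age", "gender", "ttd_years")) {
  st <- samples[samples$role == "study" & !is.na(samples$caco), ]
  if (!nrow(st)) stop("no study samples with case-control labels")
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(st)) stop("covariate absent: ", cv)
    x <- st[[cv]]
    grp <- st$caco
    if (is.numeric(x)) {
      ok <- !is.na(x)
      if (length(unique(x[ok])) < 2) {
        warning("covariate constant, test skipped: ", cv)
        p <- NA_real_
      } else {
        p <- suppressWarnings(
          wilcox.test(x[ok & grp == "case"], x[ok & grp == "control"],
                      alternative = "two.sided")$p.value)
      }
      fmt <- function(g, f) f(x[ok & grp == g])
      for (stat in c("median", "min", "max")) {
        f <- get(stat)
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, statistic = stat,
          cases = as.character(signif(fmt("case", f), 6)),
          controls = as.character(signif(fmt("control", f), 6)),
          p_value = p, stringsAsFactors = FALSE)
      }
    } else {
      ok <- !is.na(x)
      tab <- table(x[ok], grp[ok])
      if (nrow(tab) < 2) {
        warning("covariate constant, test skipped: ", cv)
        p <- NA_real_
      } else {
        p <- suppressWarnings(chisq.test(tab)$p.value)
      }
      for (lev in rownames(tab)) {
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, statistic = lev,
          cases = as.character(tab[lev, "case"]),
          controls = as.character(tab[lev, "control"]),
          p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-plot export
#'
#' Per-feature case-control fold-change and `-log10` p-value from the
#' covariate-adjusted linear model, with selected features flagged and a
#' reference line value at p = 0.05.
#'
#' @param fit a `caco_fit`.
#' @param selection optional `selection_profile`; its `selected` flags are
#'   passed through unchanged.
#' @return data.frame: feature_id, fold_change, p_value, neg_log10_p,
#'   selected; attribute `"reference_line"` = `-log10(0.05)`.
#' @export
volcano_export <- function(fit, selection = NULL) {
  tab <- fit$table
  sel <- rep(FALSE, nrow(tab))
  if (!is.null(selection))
    sel <- tab$feature_id %in% selection$feature_id[selection$selected]
  out <- data.frame(
    feature_id = tab$feature_id,
    fold_change = tab$fold_change,
    p_value = tab$p_value,
    neg_log10_p = -log10(tab$p_value),
    selected = sel,
    stringsAsFactors = FALSE
  )
  attr(out, "reference_line") <- -log10(0.05)
  out
}

#' In-sample classification rate of a feature set
#'
#' Logistic regression of case-control status on the named features'
#' normalized log intensities, fitted and evaluated on the same data
#' ("learning set"); the rate is the fraction of samples whose fitted
#' probability falls on the correct side of 0.5.  Because selection and
#' evaluation reuse the data, the rate is optimistic, and the result is
#' flagged accordingly.  Perfect separation triggers a ridge-penalized
#' fallback fit (flagged).
#'
#' @param normmatrix features x samples matrix of normalized log
#'   intensities.
#' @param samples sample metadata.
#' @param feature_set non-empty character vector of feature ids.
#' @return list with `rate`, `n`, `separation` (logical), and
#'   `optimism_caveat` (always TRUE).
#' @export
in_sample_classification <- function(normmatrix, samples, feature_set) {
  if (!length(feature_set)) stop("empty feature set")
  missing <- setdiff(feature_set, rownames(normmatrix))
  if (length(missing)) stop("unknown features: ",
                            paste(missing, collapse = ", "))
  smp <- study_frame(normmatrix, samples)
  X <- t(normmatrix[feature_set, smp$sample_id, drop = FALSE])
  y <- as.numeric(smp$caco == "case")
  dat <- data.frame(y = y, X)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    # ridge fallback keeps the fit defined under separation
    rf <- glmnet::glmnet(cbind(X, 0), y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    phat <- as.numeric(predict(rf, cbind(X, 0), type = "response"))
  } else {
    phat <- fitted(fit)
  }
  rate <- mean((phat > 0.5) == (y == 1))
  list(rate = rate, n = length(y), separation = separation,
       optimism_caveat = TRUE)
}
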