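# Ensemble variable selection: covariate-adjusted per-feature linear model,
# bootstrap-LASSO stability selection, and random-forest permutation
# importance, intersected with an iterative morphology-exclusion loop.

# study-sample metadata aligned to the columns of a matrix
study_frame <- function(logmatrix, samples) {
  smp <- samples[match(colnames(logmatrix), samples$sample_id), ]
  if (anyNA(smp$sample_id)) stop("sample metadata missing for some columns")
  smp <- smp[smp$role == "study", ]
  if (!nrow(smp)) stop("no study samples among matrix columns")
  smp
}

# per-feature mean paired log fold-change (case - control), raw or normalized
paired_mean_logfc <- function(logmatrix, smp) {
  cases <- smp[smp$caco == "case", ]
  ctrls <- smp[smp$caco == "control", ]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  if (anyNA(ctrls$sample_id)) stop("incomplete case-control pairs")
  d <- logmatrix[, cases$sample_id, drop = FALSE] -
    logmatrix[, ctrls$sample_id, drop = FALSE]
  rowMeans(d)
}

#' Per-feature case-control linear model
#'
#' Fits, independently for each feature, the OLS model
#' `log Y = b0 + b1*caco + b2*gel + b3*batch + b4*age + b5*gender + e`
#' on raw (not batch/gel-adjusted) log intensities over study samples, and
#' ranks features by the two-sided nominal p-value of the case-control
#' coefficient `b1`.  Constant covariate columns other than `caco` are
#' dropped with a warning.
#'
#' @param logmatrix features x samples matrix of raw log intensities.
#' @param samples sample metadata (see [generate_cohort()] for columns).
#' @return object of class `caco_fit`: list with `table` (feature_id,
#'   estimate, se, statistic, p_value, p_rank, fold_change), `df`, and
#'   `terms_dropped`.  `fold_change` is the exponential of the mean paired
#'   log fold-change.
#' @export
fit_case_control_lm <- function(logmatrix, samples) {
  smp <- study_frame(logmatrix, samples)
  Y <- t(logmatrix[, smp$sample_id, drop = FALSE])   # n x p
  X <- cbind(intercept = 1,
             caco = as.numeric(smp$caco == "case"),
             gel = as.numeric(smp$gel == 1),
             batch = as.numeric(smp$batch == 2),
             age = as.numeric(smp$age),
             gender = as.numeric(smp$gender == "M"))
  if (length(unique(X[, "caco"])) < 2)
    stop("case-control status is constant")
  dropped <- colnames(X)[apply(X, 2, function(v) length(unique(v)) < 2)]
  dropped <- setdiff(dropped, "intercept")
  if (length(dropped)) {
    warning("constant covariate(s) dropped: ", paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design")
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("too few samples for the design")
  B <- qr.coef(qrX, Y)                               # k x p
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  c_caco <- xtxinv[which(colnames(X) == "caco"), which(colnames(X) == "caco")]
  se <- sqrt(sigma2 * c_caco)
  est <- B["caco", ]
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), df)
  fc <- exp(paired_mean_logfc(logmatrix[, smp$sample_id, drop = FALSE], smp))
  tab <- data.frame(
    feature_id = rownames(logmatrix),
    estimate = unname(est), se = unname(se), statistic = unname(tstat),
    p_value = unname(pval),
    p_rank = rank(unname(pval), ties.method = "min"),
    fold_change = unname(fc),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, df = df, terms_dropped = dropped),
            class = "caco_fit")
}

# design matrix for the penalized / forest models: normalized feature
# intensities plus age and gender as ordinary candidates.  Rows and columns
# are put in canonical (sorted-id) order so the stochastic criteria are
# invariant to the ordering of the input matrix.
selection_design <- function(normmatrix, samples) {
  smp <- study_frame(normmatrix, samples)
  smp <- smp[order(smp$sample_id), ]
  feats <- sort(rownames(normmatrix))
  X <- cbind(t(normmatrix[feats, smp$sample_id, drop = FALSE]),
             .age = as.numeric(smp$age),
             .gender = as.numeric(smp$gender == "M"))
  list(X = X, y = as.numeric(smp$caco == "case"), smp = smp,
       feature_ids = feats)
}

#' L1-penalized logistic (or linear) regression path
#'
#' Thin wrapper around [glmnet::glmnet()] exposing the penalized
#' subroutine used by [bootstrap_lasso()] so it can be checked against
#' closed-form oracles.
#'
#' @param x predictor matrix (observations x variables).
#' @param y response (binary 0/1 for `"binomial"`).
#' @param lambda descending penalty sequence.
#' @param family `"binomial"` or `"gaussian"`.
#' @param standardize passed to glmnet (default TRUE).
#' @return sparse coefficient matrix (variables x lambda), no intercept row.
#' @export
lasso_path <- function(x, y, lambda, family = c("binomial", "gaussian"),
                       standardize = TRUE) {
  family <- match.arg(family)
  if (any(diff(lambda) > 0)) stop("lambda must be descending")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  fit <- glmnet::glmnet(x, y, family = family, lambda = lambda,
                        standardize = standardize)
  beta <- fit$beta
  if (ncol(beta) < length(lambda)) {   # glmnet stopped early; pad with last
    pad <- Matrix::Matrix(0, nrow(beta), length(lambda) - ncol(beta),
                          sparse = TRUE)
    beta <- cbind(beta, pad)
  }
  beta
}

#' Default penalty grid
#'
#' 50 log-spaced values from the data-derived maximal penalty (the smallest
#' penalty shrinking every coefficient to zero on the full data) down to
#' 0.001 times that value.
#'
#' @param X,y design and response as built internally.
#' @param grid_size number of penalties (default 50).
#' @param lambda_min_ratio ratio of smallest to largest penalty.
#' @return descending numeric vector.
#' @keywords internal
penalty_grid <- function(X, y, grid_size = 50, lambda_min_ratio = 0.001) {
  f0 <- glmnet::glmnet(X, y, family = "binomial", nlambda = 5)
  lmax <- f0$lambda[1]
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = grid_size))
}

#' Bootstrap-LASSO stability selection
#'
#' For each of `B` bootstrap replicates — resampling matched pairs with
#' replacement, so each replicate keeps the 1:1 case-control structure —
#' fits an L1-penalized logistic regression of case-control status on the
#' normalized log intensities plus age and gender along a descending penalty
#' grid, and records, per candidate and penalty, the frequency of a nonzero
#' coefficient.  The summary frequency is the maximum over the middle 80%
#' of the grid (the extremes, where selection is vacuous or saturated, are
#' excluded); a feature is retained when its summary frequency reaches
#' `freq_cut`.
#'
#' @param normmatrix features x samples matrix of normalized log
#'   intensities.
#' @param samples sample metadata.
#' @param B number of bootstrap replicates (default 500).
#' @param grid optional descending penalty grid; default
#'   [penalty_grid()] with `grid_size` points.
#' @param grid_size size of the default grid (default 50).
#' @param freq_cut retention threshold on the summary frequency
#'   (default 0.10).
#' @param window central fraction of the grid over which the summary
#'   frequency is maximized (default 0.8).
#' @param seed RNG seed.
#' @return object of class `stability_profile`: list with `grid`,
#'   `freq` (candidates x penalties), `summary`, `retained` (features only),
#'   `feature_ids`, `covariates`, `B`, `freq_cut`.
#' @export
bootstrap_lasso <- function(normmatrix, samples, B = 500, grid = NULL,
                            grid_size = 50, freq_cut = 0.10, window = 0.8,
                            seed = 1) {
  if (B < 1) stop("B must be >= 1")
  des <- selection_design(normmatrix, samples)
  if (is.null(grid)) grid <- penalty_grid(des$X, des$y, grid_size)
  if (any(diff(grid) > 0) || any(grid <= 0))
    stop("penalty grid must be positive and descending")
  nlam <- length(grid)
  pairs <- sort(unique(des$smp$pair_id))
  idx_by_pair <- split(seq_len(nrow(des$X)), des$smp$pair_id)[pairs]
  counts <- matrix(0L, ncol(des$X), nlam,
                   dimnames = list(colnames(des$X), NULL))
  set.seed(seed)
  b <- 0
  while (b < B) {
    take <- sample(pairs, length(pairs), replace = TRUE)
    rows <- unlist(idx_by_pair[take], use.names = FALSE)
    yb <- des$y[rows]
    if (length(unique(yb)) < 2) next  # degenerate replicate: redraw
    beta <- lasso_path(des$X[rows, , drop = FALSE], yb, grid)
    counts <- counts + as.matrix(abs(beta) > 0)
    b <- b + 1
  }
  freq <- counts / B
  lo <- floor(nlam * (1 - window) / 2) + 1
  hi <- nlam - (lo - 1)
  summ <- apply(freq[, lo:hi, drop = FALSE], 1, max)
  is_feat <- rownames(freq) %in% des$feature_ids
  structure(list(grid = grid, freq = freq, summary = summ,
                 retained = summ[is_feat] >= freq_cut,
                 feature_ids = des$feature_ids,
                 covariates = summ[!is_feat],
                 window = c(lo, hi), B = B, freq_cut = freq_cut),
            class = "stability_profile")
}

#' Data-driven stability-frequency cutoff
#'
#' Sorts summary frequencies in decreasing order and places the cutoff at
#' the midpoint of the largest consecutive gap whose midpoint lies below
#' `ceiling`; falls back to the fixed default when no gap is at least
#' `min_gap` wide.
#'
#' @param profile a `stability_profile`.
#' @param ceiling highest admissible cutoff (default 0.5).
#' @param min_gap minimum gap width to accept (default 0.05).
#' @param fallback value returned when no qualifying gap exists
#'   (default 0.10).
#' @return a frequency cutoff in (0, 1].
#' @export
choose_freq_cut <- function(profile, ceiling = 0.5, min_gap = 0.05,
                            fallback = 0.10) {
  f <- sort(profile$summary[profile$feature_ids], decreasing = TRUE)
  if (length(f) < 2) return(fallback)
  gaps <- f[-length(f)] - f[-1]
  mids <- (f[-length(f)] + f[-1]) / 2
  ok <- mids <= ceiling
  if (!any(ok) || max(gaps[ok]) < min_gap) return(fallback)
  best <- which(ok)[which.max(gaps[ok])]
  unname(mids[best])
}

#' Random-forest permutation importance
#'
#' Grows a classification forest of case-control status on the same
#' candidate set as [bootstrap_lasso()] (normalized intensities plus age and
#' gender) and returns out-of-bag permutation importance (mean decrease in
#' OOB accuracy), the classical forest variable-importance measure.
#'
#' @param normmatrix features x samples matrix of normalized log
#'   intensities.
#' @param samples sample metadata.
#' @param n_trees number of trees (default 500).
#' @param mtry candidate variables per split; default `floor(sqrt(p))`.
#' @param min_node minimum node size to attempt a split (default 1).
#' @param max_depth depth cap (default 25).
#' @param seed RNG seed (forest RNG is internal and independent of R's).
#' @return object of class `rf_importance`: list with `table` (feature_id,
#'   importance, rank — features only), `covariates`, `oob_accuracy`.
#' @export
rf_importance <- function(normmatrix, samples, n_trees = 500, mtry = NULL,
                          min_node = 1, max_depth = 25, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  des <- selection_design(normmatrix, samples)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(des$X))))
  fit <- rf_forest_cpp(des$X, as.integer(des$y), as.integer(n_trees),
                       as.integer(mtry), as.integer(min_node),
                       as.integer(max_depth), as.integer(seed))
  imp <- setNames(fit$importance, colnames(des$X))
  feat <- imp[des$feature_ids]
  tab <- data.frame(feature_id = des$feature_ids,
                    importance = unname(feat),
                    rank = rank(-unname(feat), ties.method = "min"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 covariates = imp[setdiff(names(imp), des$feature_ids)],
                 oob_accuracy = fit$oob_accuracy),
            class = "rf_importance")
}

#' Intersect the three selection criteria
#'
#' A feature is selected when it is simultaneously (i) in the top
#' `top_frac` of features ranked by linear-model p-value, (ii) retained by
#' bootstrap-LASSO stability selection, and (iii) in the top `top_frac` by
#' random-forest importance — and not on the exclusion list.  Ranks use
#' `ties.method = "min"`, so all features tied at the boundary are admitted.
#' A Benjamini-Hochberg q-value column is emitted for reference only; it
#' plays no role in selection.
#'
#' @param fit a `caco_fit`.
#' @param profile a `stability_profile`.
#' @param importance an `rf_importance`.
#' @param top_frac rank fraction for the p-value and importance criteria
#'   (default 0.01); the rank cutoff is `ceiling(top_frac * p)`.
#' @param exclusions character vector of feature ids excluded by peak-
#'   morphology review.
#' @return object of class `selection_profile`: data.frame with columns
#'   feature_id, p_value, q_value, p_rank, fold_change, stability_freq,
#'   rf_importance, rf_rank, pass_lm, pass_lasso, pass_rf, excluded,
#'   selected.
#' @export
intersect_criteria <- function(fit, profile, importance, top_frac = 0.01,
                               exclusions = character()) {
  ids <- fit$table$feature_id
  if (!setequal(ids, profile$feature_ids) ||
      !setequal(ids, importance$table$feature_id))
    stop("criteria cover different feature sets")
  p <- length(ids)
  cutoff <- ceiling(top_frac * p)
  pv <- fit$table$p_value
  p_rank <- rank(pv, ties.method = "min")
  imp <- importance$table$importance[match(ids, importance$table$feature_id)]
  rf_rank <- rank(-imp, ties.method = "min")
  stab <- profile$summary[ids]
  pass_lm <- p_rank <= cutoff
  pass_rf <- rf_rank <= cutoff
  pass_lasso <- unname(stab >= profile$freq_cut)
  excluded <- ids %in% exclusions
  out <- data.frame(
    feature_id = ids,
    p_value = pv,
    q_value = p.adjust(pv, "BH"),
    p_rank = p_rank,
    fold_change = fit$table$fold_change,
    stability_freq = unname(stab),
    rf_importance = imp,
    rf_rank = rf_rank,
    pass_lm = pass_lm,
    pass_lasso = pass_lasso,
    pass_rf = pass_rf,
    excluded = excluded,
    selected = pass_lm & pass_lasso & pass_rf & !excluded,
    stringsAsFactors = FALSE
  )
  class(out) <- c("selection_profile", "data.frame")
  out
}

# restrict fit/profile/importance objects to a feature subset (keeps
# per-feature statistics; ranks are recomputed by intersect_criteria)
subset_criteria <- function(fit, profile, importance, ids) {
  fit$table <- fit$table[fit$table$feature_id %in% ids, , drop = FALSE]
  keep <- profile$feature_ids %in% ids
  profile$feature_ids <- profile$feature_ids[keep]
  profile$summary <- profile$summary[c(profile$feature_ids,
                                       names(profile$covariates))]
  profile$retained <- profile$retained[keep]
  importance$table <-
    importance$table[importance$table$feature_id %in% ids, , drop = FALSE]
  list(fit = fit, profile = profile, importance = importance)
}

#' Morphology-exclusion selection loop
#'
#' Stand-in for manual chromatographic peak review: removes flagged
#' features from the candidate set and reruns [intersect_criteria()]
#' (ranks recomputed on the remaining features) until the selected set
#' contains no flagged feature.  Terminates because the candidate set
#' shrinks monotonically.
#'
#' @param fit,profile,importance the three criterion objects.
#' @param morphology_flags character vector of flagged feature ids.
#' @param top_frac rank fraction (see [intersect_criteria()]).
#' @return a `selection_profile` for the final iteration, with attributes
#'   `"iterations"` and `"removed"`.
#' @export
selection_loop <- function(fit, profile, importance,
                           morphology_flags = character(),
                           top_frac = 0.01) {
  active <- fit$table$feature_id
  removed <- character(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    cur <- subset_criteria(fit, profile, importance, active)
    sel <- intersect_criteria(cur$fit, cur$profile, cur$importance,
                              top_frac = top_frac)
    bad <- intersect(sel$feature_id[sel$selected], morphology_flags)
    if (!length(bad) || !length(active)) break
    removed <- c(removed, bad)
    active <- setdiff(active, bad)
  }
  attr(sel, "iterations") <- iterations
  attr(sel, "removed") <- removed
  sel
}

#' Write a selection profile as TSV
#'
#' @param profile a `selection_profile`.
#' @param path output file.
#' @export
write_selection <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
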