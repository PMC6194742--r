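# Preprocessing: reagent-blank and QC-reproducibility feature filters,
# log transformation, per-feature batch/gel adjustment by OLS, and
# upper-quantile scaling.

#' Filter features against reagent blanks
#'
#' Retains features whose mean study intensity is at least `min_fold` times
#' the mean reagent-blank intensity.  The fold change is computed on the
#' natural (unlogged) scale over study samples only.  A blank mean of
#' exactly 0 is treated as an infinite fold change (pass).  The boundary is
#' inclusive: a fold change of exactly `min_fold` passes.
#'
#' @param table a [feature_table()] containing at least one blank sample.
#' @param min_fold minimum study/blank fold change (default 1.5).
#' @return list with `table` (retained features) and `report` (data.frame:
#'   feature_id, blank_fold, pass, reason).
#' @export
blank_filter <- function(table, min_fold = 1.5) {
  blank <- ft_role_matrix(table, "blank")
  if (ncol(blank) == 0) stop("no blank samples present")
  study <- ft_role_matrix(table, "study")
  m_study <- rowMeans(study)
  m_blank <- rowMeans(blank)
  fold <- ifelse(m_blank == 0, Inf, m_study / m_blank)
  pass <- fold >= min_fold
  report <- data.frame(
    feature_id = table$features$feature_id,
    blank_fold = fold,
    pass = pass,
    reason = ifelse(pass, "", sprintf("blank_fold<%g", min_fold)),
    stringsAsFactors = FALSE
  )
  list(table = ft_subset_features(table, report$feature_id[pass]),
       report = report)
}

#' Filter features on pooled-QC reproducibility
#'
#' Retains features whose coefficient of variation over QC injections
#' (sample sd / mean, natural intensity scale, n-1 denominator) is at most
#' `max_cv`.  The boundary is inclusive: a CV of exactly `max_cv` passes.
#' Features with a QC mean of 0 are flagged and dropped.
#'
#' @param table a [feature_table()] containing at least two QC samples.
#' @param max_cv maximum QC coefficient of variation (default 0.30).
#' @return list with `table` and `report` (feature_id, qc_cv, pass, reason).
#' @export
qc_cv_filter <- function(table, max_cv = 0.30) {
  qc <- ft_role_matrix(table, "qc")
  if (ncol(qc) < 2) stop("need at least 2 QC samples")
  m <- rowMeans(qc)
  s <- apply(qc, 1, sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  pass <- !is.na(cv) & cv <= max_cv
  report <- data.frame(
    feature_id = table$features$feature_id,
    qc_cv = cv,
    pass = pass,
    reason = ifelse(pass, "",
                    ifelse(is.na(cv), "qc_mean=0",
                           sprintf("qc_cv>%g", max_cv))),
    stringsAsFactors = FALSE
  )
  list(table = ft_subset_features(table, report$feature_id[pass]),
       report = report)
}

#' Natural-log transform of study intensities
#'
#' Zero intensities are replaced by a pseudo-intensity equal to half the
#' smallest positive value in the matrix before taking logs (configurable).
#'
#' @param table a [feature_table()].
#' @param roles sample roles to include (default study only).
#' @param pseudo pseudo-intensity for zeros; `NULL` (default) uses half the
#'   smallest positive intensity.
#' @return features x samples matrix of natural-log intensities.
#' @export
log_transform <- function(table, roles = "study", pseudo = NULL) {
  ids <- table$samples$sample_id[table$samples$role %in% roles]
  x <- table$intensities[, ids, drop = FALSE]
  if (any(x == 0)) {
    if (is.null(pseudo)) {
      pos <- x[x > 0]
      if (!length(pos)) stop("all intensities are zero")
      pseudo <- min(pos) / 2
    }
    x[x == 0] <- pseudo
  }
  log(x)
}

#' Remove batch and gel-status effects per feature
#'
#' Fits, independently for each feature, the ordinary-least-squares model
#' `log Y = b0 + b1 * gel + b2 * batch2 + e` over study samples (reference
#' levels gel = 0 and batch = 1) and returns normalized log intensities
#' `log Y - b1*gel - b2*batch2`.  A constant gel or batch column drops the
#' corresponding coefficient with a warning rather than failing.
#'
#' @param logmatrix features x samples matrix of log intensities (study
#'   samples).
#' @param samples sample metadata with `sample_id`, `gel`, `batch`.
#' @return object of class `normalization_fit`: list with `coefficients`
#'   (features x terms), `normalized` (matrix like `logmatrix`) and
#'   `terms_dropped`.
#' @export
batch_gel_adjust <- function(logmatrix, samples) {
  smp <- samples[match(colnames(logmatrix), samples$sample_id), ]
  if (anyNA(smp$sample_id)) stop("samples missing for some columns")
  X <- cbind(intercept = 1, gel = as.numeric(smp$gel == 1),
             batch = as.numeric(smp$batch == 2))
  dropped <- character(0)
  for (term in c("gel", "batch")) {
    if (length(unique(X[, term])) < 2) {
      dropped <- c(dropped, term)
    }
  }
  if (length(dropped)) {
    warning("constant column(s) dropped from adjustment: ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular batch/gel design")
  B <- t(qr.coef(qrX, t(logmatrix)))           # features x terms
  colnames(B) <- colnames(X)
  adj <- matrix(0, nrow(logmatrix), ncol(logmatrix))
  for (term in setdiff(colnames(X), "intercept"))
    adj <- adj + outer(B[, term], X[, term])
  normalized <- logmatrix - adj
  full <- matrix(0, nrow(logmatrix), 3,
                 dimnames = list(rownames(logmatrix),
                                 c("intercept", "gel", "batch")))
  full[, colnames(B)] <- B
  structure(list(coefficients = full, normalized = normalized,
                 terms_dropped = dropped),
            class = "normalization_fit")
}

#' Upper-quantile scaling of a log-intensity matrix
#'
#' Per sample, subtracts that sample's 75th percentile of log intensity
#' (linear-interpolation percentile) and adds the grand mean of those
#' percentiles, so that every sample's 75th percentile is identical
#' afterwards and within-sample rank order is preserved.
#'
#' @param logmatrix features x samples matrix of finite log intensities.
#' @param probs percentile to equalize (default 0.75).
#' @return scaled matrix with attribute `"offsets"` (per-sample shifts).
#' @export
upper_quantile_scale <- function(logmatrix, probs = 0.75) {
  if (nrow(logmatrix) < 1) stop("need at least one feature")
  stopifnot(all(is.finite(logmatrix)))
  q <- apply(logmatrix, 2, quantile, probs = probs, names = FALSE, type = 7)
  offsets <- mean(q) - q
  out <- sweep(logmatrix, 2, offsets, `+`)
  attr(out, "offsets") <- offsets
  out
}

#' Write a filter report as TSV
#'
#' @param reports one report or a list of reports from [blank_filter()] /
#'   [qc_cv_filter()]; multiple reports are merged on feature id.
#' @param path output file.
#' @return invisibly, the merged report.
#' @export
write_filter_report <- function(reports, path) {
  if (is.data.frame(reports)) reports <- list(reports)
  merged <- Reduce(function(a, b) merge(a, b, by = "feature_id",
                                        all = TRUE, suffixes = c("", ".y")),
                   reports)
  write.table(merged, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(merged)
}
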