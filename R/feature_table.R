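# Core container: an LC-MS feature intensity table keyed by feature id and
# sample id, with per-feature m/z and retention time and per-sample roles.

#' Construct a feature table
#'
#' @param feature_id character vector of unique feature ids.
#' @param mz per-feature m/z (Th, singly charged negative ions).
#' @param rt_sec per-feature retention time (seconds).
#' @param intensities features x samples matrix of non-negative intensities;
#'   column names are sample ids.
#' @param samples data.frame with at least `sample_id` and `role`
#'   (study/qc/blank), one row per intensity column.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(feature_id, mz, rt_sec, intensities, samples) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) stop("duplicate feature ids")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  stopifnot(length(feature_id) == nrow(intensities),
            length(mz) == length(feature_id),
            length(rt_sec) == length(feature_id))
  if (!setequal(colnames(intensities), samples$sample_id))
    stop("intensity columns and sample metadata do not match")
  intensities <- intensities[, samples$sample_id, drop = FALSE]
  if (length(intensities) && (any(!is.finite(intensities)) ||
                              any(intensities < 0)))
    stop("intensities must be finite and >= 0")
  rownames(intensities) <- feature_id
  structure(list(
    features = data.frame(feature_id = feature_id, mz = mz, rt_sec = rt_sec,
                          stringsAsFactors = FALSE),
    intensities = intensities,
    samples = samples
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$samples$role)
  cat(sprintf("feature_table: %d features x %d samples (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# subset a feature table by feature ids (keeps order of `ids`)
ft_subset_features <- function(ft, ids) {
  keep <- match(ids, ft$features$feature_id)
  if (anyNA(keep)) stop("unknown feature ids")
  feature_table(ft$features$feature_id[keep], ft$features$mz[keep],
                ft$features$rt_sec[keep],
                ft$intensities[keep, , drop = FALSE], ft$samples)
}

# intensity submatrix for one sample role
ft_role_matrix <- function(ft, role) {
  ids <- ft$samples$sample_id[ft$samples$role == role]
  ft$intensities[, ids, drop = FALSE]
}
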