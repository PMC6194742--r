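# Shared fixture builders.  Everything is generated in code; no data files.

# small default cohort used by several tests
small_cohort <- function(n_pairs = 20, p = 120, n_causal = 3, n_reactive = 3,
                         beta0 = 1.0, decay_span = 10, residual_sd = 0.5,
                         seed = 11, ...) {
  des <- cohort_design(n_pairs = n_pairs, p_features = p, n_qc = 6,
                       n_blank = 2, seed = seed, ...)
  eff <- standard_effects(p, n_causal = n_causal, n_reactive = n_reactive,
                          beta0 = beta0, decay_span = decay_span)
  generate_cohort(des, eff, noise_model(residual_sd = residual_sd))
}

# hand-built feature table: `study`, `qc`, `blank` are feature x sample
# matrices (any may have zero columns)
hand_table <- function(study, qc = NULL, blank = NULL,
                       pair_structure = TRUE) {
  p <- nrow(study)
  stopifnot(ncol(study) %% 2 == 0)
  n_pairs <- ncol(study) / 2
  caco <- rep(c("case", "control"), n_pairs)
  pair <- rep(sprintf("pair%02d", seq_len(n_pairs)), each = 2)
  ids <- paste0(pair, "_", caco)
  colnames(study) <- ids
  samples <- data.frame(
    sample_id = ids, role = "study", pair_id = pair, caco = caco,
    gel = 0L, batch = 1L, age = 50, gender = "M",
    ttd_years = rep(seq_len(n_pairs), each = 2),
    stringsAsFactors = FALSE)
  mats <- list(study)
  add_role <- function(m, role, prefix) {
    if (is.null(m) || ncol(m) == 0) return(NULL)
    colnames(m) <- sprintf("%s%02d", prefix, seq_len(ncol(m)))
    mats[[length(mats) + 1]] <<- m
    data.frame(sample_id = colnames(m), role = role,
               pair_id = NA_character_, caco = NA_character_, gel = 0L,
               batch = 1L, age = NA_real_, gender = NA_character_,
               ttd_years = NA_real_, stringsAsFactors = FALSE)
  }
  samples <- rbind(samples, add_role(qc, "qc", "QC"),
                   add_role(blank, "blank", "BL"))
  intens <- do.call(cbind, mats)
  feature_table(sprintf("f%03d", seq_len(p)), mz = 100 + seq_len(p),
                rt_sec = 60 + seq_len(p), intensities = intens,
                samples = samples)
}

# paired study samples with per-pair logFC injected directly (log scale)
paired_logmat <- function(logfc_matrix, ttd, base = 10, sd = 0) {
  p <- nrow(logfc_matrix)
  n <- ncol(logfc_matrix)
  study <- matrix(0, p, 2 * n)
  idx <- rep(seq_len(n), each = 2)
  s <- rep(c(0.5, -0.5), n)
  study <- base + logfc_matrix[, idx, drop = FALSE] * rep(s, each = p) +
    matrix(rnorm(p * 2 * n, 0, sd), p, 2 * n)
  caco <- rep(c("case", "control"), n)
  pair <- rep(sprintf("pair%02d", seq_len(n)), each = 2)
  ids <- paste0(pair, "_", caco)
  colnames(study) <- ids
  rownames(study) <- sprintf("f%03d", seq_len(p))
  samples <- data.frame(sample_id = ids, role = "study", pair_id = pair,
                        caco = caco, gel = 0L, batch = 1L, age = 50,
                        gender = "M", ttd_years = ttd[idx],
                        stringsAsFactors = FALSE)
  list(logmat = study, samples = samples)
}

# fabricated criterion objects for intersect_criteria unit tests:
# p-values, stability frequencies and importances given per feature id
fake_criteria <- function(p_value, stability, importance, freq_cut = 0.10) {
  ids <- names(p_value)
  fit <- structure(list(table = data.frame(
    feature_id = ids, estimate = 0, se = 1, statistic = 0,
    p_value = unname(p_value),
    p_rank = rank(unname(p_value), ties.method = "min"),
    fold_change = 1, stringsAsFactors = FALSE)), class = "caco_fit")
  prof <- structure(list(summary = stability, feature_ids = ids,
                         covariates = c(.age = 0, .gender = 0),
                         retained = stability >= freq_cut,
                         freq_cut = freq_cut),
                    class = "stability_profile")
  imp <- structure(list(table = data.frame(
    feature_id = ids, importance = unname(importance),
    rank = rank(-unname(importance), ties.method = "min"),
    stringsAsFactors = FALSE)), class = "rf_importance")
  list(fit = fit, profile = prof, importance = imp)
}
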