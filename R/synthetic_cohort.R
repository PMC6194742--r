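# Synthetic matched case-control cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: 66
# age/gender-matched case-control pairs measured by untargeted LC-MS in two
# batches, a gel-status artifact confined to batch 1, log-normal feature
# intensities, pooled-QC injections, reagent blanks, and planted
# case-control effects that are either constant in time-to-diagnosis
# (causal), decay linearly to zero (reactive), or grow (indeterminate).

#' Cohort design parameters
#'
#' @param n_pairs number of matched case-control pairs (default 66).
#' @param p_features number of LC-MS features.
#' @param batch_assignment fraction of pairs analyzed in batch 1; pairs are
#'   never split across batches (default 48/66, i.e. 96 of 132 samples).
#' @param gel_probability per-sample probability of gelled serum within
#'   batch 1; batch 2 is always gel-free (default 0.46, so roughly one third
#'   of all samples are gelled).
#' @param age_range uniform integer age range in years (default 35-65).
#' @param gender_balance fraction of male pairs (default 51/66).
#' @param ttd_range uniform time-to-diagnosis range in years
#'   (default 0.1-14.4).
#' @param n_qc number of pooled-QC injections, split across batches in
#'   proportion to batch size (default 13: one QC per ten study injections).
#' @param n_blank number of reagent blanks (default 3).
#' @param seed RNG seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_pairs = 66, p_features = 2000,
                          batch_assignment = 48 / 66, gel_probability = 0.46,
                          age_range = c(35, 65), gender_balance = 51 / 66,
                          ttd_range = c(0.1, 14.4), n_qc = 13, n_blank = 3,
                          seed = 1) {
  stopifnot(n_pairs >= 2, p_features >= 1,
            batch_assignment >= 0, batch_assignment <= 1,
            gel_probability >= 0, gel_probability <= 1,
            length(age_range) == 2, length(ttd_range) == 2,
            ttd_range[1] > 0, n_qc >= 0, n_blank >= 0)
  structure(list(n_pairs = n_pairs, p_features = p_features,
                 batch_assignment = batch_assignment,
                 gel_probability = gel_probability,
                 age_range = age_range, gender_balance = gender_balance,
                 ttd_range = ttd_range, n_qc = n_qc, n_blank = n_blank,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' A planted case-control effect
#'
#' `beta0` is the pair-level natural-log fold-change at time-to-diagnosis
#' zero.  The trajectory over ttd depends on the type: causal effects are
#' constant, reactive effects shrink piecewise-linearly to zero over
#' `decay_span` years, indeterminate effects grow by `growth_rate` per year
#' in absolute value, and null effects are identically zero.
#'
#' @param feature_index 1-based feature index the effect applies to.
#' @param effect_type one of "causal", "reactive", "indeterminate", "null".
#' @param beta0 log fold-change at ttd = 0 (natural-log units).
#' @param decay_span years over which a reactive effect reaches zero.
#' @param growth_rate per-year increase of |log fold-change| (indeterminate).
#' @return object of class `planted_effect`.
#' @export
planted_effect <- function(feature_index,
                           effect_type = c("causal", "reactive",
                                           "indeterminate", "null"),
                           beta0 = 0, decay_span = 10, growth_rate = 0) {
  effect_type <- match.arg(effect_type)
  stopifnot(is.finite(beta0), feature_index >= 1)
  if (effect_type == "null" && beta0 != 0)
    stop("null effects must have beta0 = 0")
  if (effect_type == "reactive" && decay_span <= 0)
    stop("reactive effects need decay_span > 0")
  if (effect_type == "indeterminate" && growth_rate < 0)
    stop("indeterminate effects need growth_rate >= 0")
  structure(list(feature_index = as.integer(feature_index),
                 effect_type = effect_type, beta0 = beta0,
                 decay_span = decay_span, growth_rate = growth_rate),
            class = "planted_effect")
}

#' Noise and artifact model
#'
#' Defaults describe a realistic, mostly filter-passing LC-MS run: baseline
#' natural-log intensities spanning e^8 to e^14 arbitrary units, residual
#' (biological + technical) log-sd 0.5, QC coefficients of variation of
#' 5-20% (under the 30% filter), blank signal at 0-30% of the study mean
#' (over the 1.5-fold filter), and per-feature batch/gel log offsets of
#' sd 0.3.
#'
#' @param base_log_mean_range range of per-feature baseline log intensities.
#' @param residual_sd per-subject log-scale residual standard deviation.
#' @param qc_cv_range range of per-feature QC coefficients of variation.
#' @param blank_fraction_range per-feature blank signal as a fraction of the
#'   mean study signal; must lie in [0, 1.5].
#' @param batch_shift_sd sd of the per-feature additive batch-2 log offset.
#' @param gel_shift_sd sd of the per-feature additive gel log offset.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(base_log_mean_range = c(8, 14), residual_sd = 0.5,
                        qc_cv_range = c(0.05, 0.20),
                        blank_fraction_range = c(0, 0.30),
                        batch_shift_sd = 0.3, gel_shift_sd = 0.3) {
  stopifnot(residual_sd >= 0, all(qc_cv_range >= 0),
            all(blank_fraction_range >= 0),
            all(blank_fraction_range <= 1.5),
            batch_shift_sd >= 0, gel_shift_sd >= 0)
  structure(list(base_log_mean_range = base_log_mean_range,
                 residual_sd = residual_sd, qc_cv_range = qc_cv_range,
                 blank_fraction_range = blank_fraction_range,
                 batch_shift_sd = batch_shift_sd, gel_shift_sd = gel_shift_sd),
            class = "noise_model")
}

# log fold-change trajectory of one planted effect at the given ttd values
effect_logfc <- function(effect, ttd) {
  switch(effect$effect_type,
    null = rep(0, length(ttd)),
    causal = rep(effect$beta0, length(ttd)),
    reactive = effect$beta0 * pmax(0, 1 - ttd / effect$decay_span),
    indeterminate = sign(effect$beta0) *
      (abs(effect$beta0) + effect$growth_rate * ttd)
  )
}

#' Convenience builder for a standard planted-effect set
#'
#' First `n_causal` features get constant effects of alternating sign
#' `(+beta0, -beta0, ...)`, the next `n_reactive` get reactive effects
#' starting at `beta0` and decaying over `decay_span` years, the next
#' `n_indeterminate` grow at `growth_rate`/year; all remaining features are
#' null.
#'
#' @param p_features total number of features.
#' @param n_causal,n_reactive,n_indeterminate planted counts.
#' @param beta0 magnitude of the log fold-change at ttd = 0.
#' @param decay_span years to zero for reactive effects.
#' @param growth_rate per-year growth for indeterminate effects.
#' @return list of [planted_effect()] objects covering all features.
#' @export
standard_effects <- function(p_features, n_causal = 5, n_reactive = 5,
                             n_indeterminate = 0, beta0 = 0.5,
                             decay_span = 10, growth_rate = 0.05) {
  stopifnot(n_causal + n_reactive + n_indeterminate <= p_features)
  sgn <- function(i) if (i %% 2 == 1) 1 else -1
  k <- 0
  eff <- list()
  for (i in seq_len(n_causal)) {
    k <- k + 1
    eff[[k]] <- planted_effect(k, "causal", beta0 = sgn(i) * beta0)
  }
  for (i in seq_len(n_reactive)) {
    k <- k + 1
    eff[[k]] <- planted_effect(k, "reactive", beta0 = sgn(i) * beta0,
                               decay_span = decay_span)
  }
  for (i in seq_len(n_indeterminate)) {
    k <- k + 1
    eff[[k]] <- planted_effect(k, "indeterminate", beta0 = sgn(i) * 0.1,
                               growth_rate = growth_rate)
  }
  for (j in seq(k + 1, length.out = p_features - k)) {
    eff[[j]] <- planted_effect(j, "null")
  }
  eff
}

#' Generate a synthetic cohort
#'
#' Study-sample log intensity of feature k in subject i is
#' `base_k + batchShift_k * [batch 2] + gelShift_k * [gel] +
#'  s/2 * logFC_k(ttd_i) + eps`, with `s = +1` for cases and `-1` for
#' controls, `logFC_k(ttd)` following the planted effect, and
#' `eps ~ N(0, residual_sd)`.  QC intensities are log-normal draws around
#' the per-batch pooled mean with the feature's QC CV; blank intensities are
#' `blank_fraction_k` times the mean study intensity (natural scale).
#' Controls inherit their case's ttd for bookkeeping.  Intensities are
#' generated on the natural-log scale and exponentiated, so they are always
#' positive.
#'
#' @param design a [cohort_design()].
#' @param effects list of [planted_effect()]; features not referenced are
#'   null.
#' @param noise a [noise_model()].
#' @return list with elements `features` (a [feature_table()]), `samples`
#'   (data.frame: sample_id, role, pair_id, caco, gel, batch, age, gender,
#'   ttd_years) and `truth` (data.frame: feature_id, effect_type, beta0,
#'   decay_span).
#' @export
generate_cohort <- function(design, effects = list(), noise = noise_model()) {
  stopifnot(inherits(design, "cohort_design"), inherits(noise, "noise_model"))
  p <- design$p_features
  for (e in effects) {
    if (!inherits(e, "planted_effect")) stop("effects must be planted_effect")
    if (e$feature_index > p) stop("effect references feature index > p_features")
  }
  set.seed(design$seed)
  n <- design$n_pairs

  # --- pair-level covariates (shared within pair) ---
  n_b1 <- round(design$batch_assignment * n)
  batch_pair <- rep(2L, n)
  batch_pair[sample.int(n, n_b1)] <- 1L
  age_pair <- sample(seq(design$age_range[1], design$age_range[2]), n,
                     replace = TRUE)
  male_pair <- rbinom(n, 1, design$gender_balance)
  ttd_pair <- runif(n, design$ttd_range[1], design$ttd_range[2])

  pair_id <- sprintf("pair%03d", seq_len(n))
  caco <- rep(c("case", "control"), n)
  idx_pair <- rep(seq_len(n), each = 2)
  sample_id <- paste0(pair_id[idx_pair], "_", caco)
  gel <- ifelse(batch_pair[idx_pair] == 1L,
                rbinom(2 * n, 1, design$gel_probability), 0L)

  samples <- data.frame(
    sample_id = sample_id, role = "study", pair_id = pair_id[idx_pair],
    caco = caco, gel = as.integer(gel), batch = batch_pair[idx_pair],
    age = age_pair[idx_pair],
    gender = ifelse(male_pair[idx_pair] == 1, "M", "F"),
    ttd_years = ttd_pair[idx_pair],
    stringsAsFactors = FALSE
  )

  # --- per-feature parameters ---
  feature_id <- sprintf("F%05d", seq_len(p))
  base <- runif(p, noise$base_log_mean_range[1], noise$base_log_mean_range[2])
  batch_shift <- rnorm(p, 0, noise$batch_shift_sd)
  gel_shift <- rnorm(p, 0, noise$gel_shift_sd)
  qc_cv <- runif(p, noise$qc_cv_range[1], noise$qc_cv_range[2])
  blank_frac <- runif(p, noise$blank_fraction_range[1],
                      noise$blank_fraction_range[2])

  # planted trajectories: p x n matrix of pair-level logFC
  logfc <- matrix(0, p, n)
  truth <- data.frame(feature_id = feature_id, effect_type = "null",
                      beta0 = 0, decay_span = NA_real_,
                      stringsAsFactors = FALSE)
  for (e in effects) {
    logfc[e$feature_index, ] <- effect_logfc(e, ttd_pair)
    truth$effect_type[e$feature_index] <- e$effect_type
    truth$beta0[e$feature_index] <- e$beta0
    truth$decay_span[e$feature_index] <-
      if (e$effect_type == "reactive") e$decay_span else NA_real_
  }

  # --- study intensities ---
  s <- ifelse(samples$caco == "case", 1, -1)          # length 2n
  logy <- matrix(base, p, 2 * n) +
    outer(batch_shift, as.numeric(samples$batch == 2L)) +
    outer(gel_shift, as.numeric(samples$gel == 1L)) +
    logfc[, idx_pair, drop = FALSE] * rep(s / 2, each = p) +
    matrix(rnorm(p * 2 * n, 0, noise$residual_sd), p, 2 * n)
  study <- exp(logy)
  colnames(study) <- samples$sample_id

  # --- QC injections: per-batch pooled mean, log-normal with target CV ---
  qc_mat <- NULL
  qc_samples <- NULL
  if (design$n_qc > 0) {
    n_qc1 <- round(design$n_qc * sum(samples$batch == 1L) / (2 * n))
    n_qc_b <- c(n_qc1, design$n_qc - n_qc1)
    qc_cols <- list()
    qc_ids <- character(0)
    qc_batch <- integer(0)
    for (b in 1:2) {
      nb <- n_qc_b[b]
      if (nb == 0) next
      in_b <- samples$batch == b
      if (!any(in_b)) next
      pooled <- rowMeans(study[, in_b, drop = FALSE])
      sdlog <- sqrt(log1p(qc_cv^2))
      meanlog <- log(pooled) - sdlog^2 / 2
      draws <- matrix(rlnorm(p * nb, meanlog = rep(meanlog, nb),
                             sdlog = rep(sdlog, nb)), p, nb)
      qc_cols <- c(qc_cols, list(draws))
      qc_ids <- c(qc_ids, sprintf("QC_b%d_%02d", b, seq_len(nb)))
      qc_batch <- c(qc_batch, rep(b, nb))
    }
    if (length(qc_cols)) {
      qc_mat <- do.call(cbind, qc_cols)
      colnames(qc_mat) <- qc_ids
      qc_samples <- data.frame(
        sample_id = qc_ids, role = "qc", pair_id = NA_character_,
        caco = NA_character_, gel = 0L, batch = qc_batch,
        age = NA_real_, gender = NA_character_, ttd_years = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }

  # --- reagent blanks: deterministic fraction of the mean study signal ---
  blank_mat <- NULL
  blank_samples <- NULL
  if (design$n_blank > 0) {
    mean_study <- rowMeans(study)
    blank_mat <- matrix(rep(blank_frac * mean_study, design$n_blank),
                        p, design$n_blank)
    colnames(blank_mat) <- sprintf("BLANK_%02d", seq_len(design$n_blank))
    blank_samples <- data.frame(
      sample_id = colnames(blank_mat), role = "blank",
      pair_id = NA_character_, caco = NA_character_, gel = 0L,
      batch = NA_integer_, age = NA_real_, gender = NA_character_,
      ttd_years = NA_real_, stringsAsFactors = FALSE
    )
  }

  intensities <- cbind(study, qc_mat, blank_mat)
  rownames(intensities) <- feature_id
  samples_all <- rbind(samples, qc_samples, blank_samples)
  rownames(samples_all) <- NULL

  ft <- feature_table(
    feature_id = feature_id,
    mz = round(runif(p, 100, 1000), 4),
    rt_sec = round(runif(p, 30, 1300), 1),
    intensities = intensities,
    samples = samples_all
  )
  list(features = ft, samples = samples_all, truth = truth)
}

#' Write a cohort fixture to TSV files
#'
#' Emits `features.tsv` (feature_id, mz, rt_sec, one column per sample),
#' `samples.tsv` and `truth.tsv` with full double precision, so that a
#' read/write round trip is exact to the last bit and repeated writes of the
#' same object are byte-identical.
#'
#' @param tables list as returned by [generate_cohort()] (the `truth`
#'   element is optional).
#' @param directory output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(tables, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ft <- tables$features
  num <- function(x) sprintf("%.17g", x)
  feat <- data.frame(feature_id = ft$features$feature_id,
                     mz = num(ft$features$mz),
                     rt_sec = num(ft$features$rt_sec),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(ft$intensities)))
    feat[[colnames(ft$intensities)[j]]] <- num(ft$intensities[, j])
  if (nrow(feat) == 0) {
    feat <- data.frame(feature_id = character(), mz = character(),
                       rt_sec = character(), check.names = FALSE)
    for (sid in tables$samples$sample_id) feat[[sid]] <- character()
  }
  paths <- file.path(directory, c("features.tsv", "samples.tsv", "truth.tsv"))
  write.table(feat, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  smp <- tables$samples
  smp$ttd_years <- ifelse(is.na(smp$ttd_years), NA, num(smp$ttd_years))
  write.table(smp, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tables$truth)) {
    tr <- tables$truth
    tr$beta0 <- num(tr$beta0)
    tr$decay_span <- ifelse(is.na(tr$decay_span), NA, num(tr$decay_span))
    write.table(tr, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[1:2]
  }
  invisible(paths)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param directory directory containing `features.tsv` and `samples.tsv`
#'   (and optionally `truth.tsv`).
#' @return list with `features`, `samples` and (if present) `truth`.
#' @export
read_fixture <- function(directory) {
  fpath <- file.path(directory, "features.tsv")
  spath <- file.path(directory, "samples.tsv")
  if (!file.exists(fpath) || !file.exists(spath))
    stop("fixture files not found in ", directory)
  feat <- read.delim(fpath, check.names = FALSE, colClasses = "character")
  samples <- read.delim(spath, check.names = FALSE,
                        stringsAsFactors = FALSE)
  samples$pair_id <- as.character(samples$pair_id)
  samples$caco <- as.character(samples$caco)
  samples$gender <- as.character(samples$gender)
  sample_cols <- setdiff(colnames(feat), c("feature_id", "mz", "rt_sec"))
  intens <- as.matrix(vapply(sample_cols,
                             function(cn) as.numeric(feat[[cn]]),
                             numeric(nrow(feat))))
  if (nrow(feat) == 0)
    intens <- matrix(numeric(0), 0, length(sample_cols),
                     dimnames = list(NULL, sample_cols))
  if (nrow(feat) == 1) intens <- matrix(intens, 1,
                                        dimnames = list(NULL, sample_cols))
  rownames(intens) <- feat$feature_id
  ft <- feature_table(feature_id = feat$feature_id,
                      mz = as.numeric(feat$mz),
                      rt_sec = as.numeric(feat$rt_sec),
                      intensities = intens, samples = samples)
  out <- list(features = ft, samples = samples)
  tpath <- file.path(directory, "truth.tsv")
  if (file.exists(tpath)) {
    tr <- read.delim(tpath, stringsAsFactors = FALSE)
    tr$feature_id <- as.character(tr$feature_id)
    out$truth <- tr
  }
  out
}
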