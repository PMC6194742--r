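# Generator contracts: noise-free constructions, Monte-Carlo agreement with
# the generating equation, reproducibility, fixture round trips.

test_that("zero-noise null cohort is constant within batch/gel strata", {
  des <- cohort_design(n_pairs = 4, p_features = 1, n_qc = 0, n_blank = 0,
                       seed = 3)
  coh <- generate_cohort(des, list(planted_effect(1, "null")),
                         noise_model(residual_sd = 0))
  smp <- coh$samples
  x <- coh$features$intensities[1, ]
  strata <- paste(smp$batch, smp$gel)
  for (st in unique(strata)) {
    v <- x[strata == st]
    expect_lt(diff(range(v)), 1e-9 * mean(v))
  }
})

test_that("noise-free causal effect gives exact paired logFC at all ttd", {
  des <- cohort_design(n_pairs = 6, p_features = 2, n_qc = 0, n_blank = 0,
                       seed = 5)
  coh <- generate_cohort(des, list(planted_effect(1, "causal", beta0 = 0.6)),
                         noise_model(residual_sd = 0, gel_shift_sd = 0))
  m <- log(coh$features$intensities)
  smp <- coh$samples
  cases <- smp$sample_id[smp$caco == "case"]
  ctrls <- smp$sample_id[smp$caco == "control"]
  expect_equal(unname(m[1, cases] - m[1, ctrls]), rep(0.6, 6),
               tolerance = 1e-12)
  expect_equal(unname(m[2, cases] - m[2, ctrls]), rep(0, 6),
               tolerance = 1e-12)
})

test_that("noise-free reactive/indeterminate trajectories are exact", {
  des <- cohort_design(n_pairs = 8, p_features = 2, n_qc = 0, n_blank = 0,
                       seed = 6)
  eff <- list(planted_effect(1, "reactive", beta0 = 0.9, decay_span = 10),
              planted_effect(2, "indeterminate", beta0 = 0.1,
                             growth_rate = 0.05))
  coh <- generate_cohort(des, eff,
                         noise_model(residual_sd = 0, gel_shift_sd = 0))
  m <- log(coh$features$intensities)
  smp <- coh$samples
  cases <- smp[smp$caco == "case", ]
  ctrls <- smp[smp$caco == "control", ]
  lfc1 <- m[1, cases$sample_id] - m[1, ctrls$sample_id]
  lfc2 <- m[2, cases$sample_id] - m[2, ctrls$sample_id]
  ttd <- cases$ttd_years
  expect_equal(unname(lfc1), 0.9 * pmax(0, 1 - ttd / 10), tolerance = 1e-12)
  expect_equal(unname(lfc2), 0.1 + 0.05 * ttd, tolerance = 1e-12)
  # trajectory monotonicity: reactive non-increasing, indeterminate
  # non-decreasing in |logFC|
  o <- order(ttd)
  expect_true(all(diff(abs(lfc1[o])) <= 1e-12))
  expect_true(all(diff(abs(lfc2[o])) >= -1e-12))
  # controls share their case's ttd
  expect_equal(cases$ttd_years, ctrls$ttd_years)
})

test_that("pair members share age, gender, batch and ttd", {
  coh <- small_cohort(n_pairs = 15, p = 12, seed = 21)
  st <- coh$samples[coh$samples$role == "study", ]
  for (col in c("age", "gender", "batch", "ttd_years")) {
    by_pair <- split(st[[col]], st$pair_id)
    expect_true(all(vapply(by_pair, function(v)
      length(unique(v)) == 1, logical(1))), label = col)
  }
  expect_true(all(st$gel[st$batch == 2] == 0))
})

test_that("Monte-Carlo pair-mean logFC of causal features matches beta0", {
  des <- cohort_design(n_pairs = 66, p_features = 2000, seed = 1)
  eff <- standard_effects(2000, n_causal = 5, n_reactive = 5, beta0 = 0.5,
                          decay_span = 10)
  coh <- generate_cohort(des, eff)
  m <- log(coh$features$intensities)
  smp <- coh$samples[coh$samples$role == "study", ]
  cases <- smp[smp$caco == "case", ]
  ctrls <- smp[smp$caco == "control", ]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  d <- m[1:5, cases$sample_id] - m[1:5, ctrls$sample_id]
  # pair logFC ~ N(+-0.5, 2 * residual_sd^2); SE of the mean over 66 pairs
  se <- sqrt(2 * 0.5^2 / 66)
  signs <- c(1, -1, 1, -1, 1)
  expect_true(all(abs(rowMeans(d) - signs * 0.5) < 3 * se))
})

test_that("generation is reproducible and QC/blank structure is sound", {
  a <- small_cohort(seed = 33)
  b <- small_cohort(seed = 33)
  expect_identical(a$features$intensities, b$features$intensities)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  roles <- table(a$samples$role)
  expect_equal(unname(roles["qc"]), 6)
  expect_equal(unname(roles["blank"]), 2)
})

test_that("blank fraction above 2/3 fails the downstream blank filter", {
  des <- cohort_design(n_pairs = 4, p_features = 3, n_qc = 0, n_blank = 2,
                       seed = 2)
  coh <- generate_cohort(des, list(),
                         noise_model(residual_sd = 0,
                                     blank_fraction_range = c(0.8, 0.8)))
  res <- blank_filter(coh$features, min_fold = 1.5)
  expect_true(all(!res$report$pass))
  expect_equal(res$report$blank_fold, rep(1 / 0.8, 3), tolerance = 1e-9)
})

test_that("fixtures round-trip exactly and deterministically", {
  coh <- small_cohort(n_pairs = 5, p = 8, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(coh, d1)
  back <- read_fixture(d1)
  expect_equal(back$features$intensities, coh$features$intensities,
               tolerance = 1e-12)
  expect_equal(back$features$features, coh$features$features)
  expect_equal(back$samples$ttd_years, coh$samples$ttd_years,
               tolerance = 1e-12)
  expect_equal(back$truth$effect_type, coh$truth$effect_type)
  # byte-identical across repeated writes
  write_fixture(coh, d2)
  for (f in c("features.tsv", "samples.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("empty feature set round-trips as header-only files", {
  samples <- data.frame(sample_id = c("a_case", "a_control"), role = "study",
                        pair_id = "a", caco = c("case", "control"), gel = 0L,
                        batch = 1L, age = 50, gender = "M", ttd_years = 1,
                        stringsAsFactors = FALSE)
  ft <- feature_table(character(0), numeric(0), numeric(0),
                      matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, samples$sample_id)),
                      samples)
  d <- withr::local_tempdir()
  write_fixture(list(features = ft, samples = samples), d)
  expect_equal(length(readLines(file.path(d, "features.tsv"))), 1L)
  back <- read_fixture(d)
  expect_equal(nrow(back$features$intensities), 0L)
  expect_equal(ncol(back$features$intensities), 2L)
})

test_that("design and effect validation rejects bad inputs", {
  expect_error(cohort_design(n_pairs = 1), "n_pairs")
  expect_error(planted_effect(1, "null", beta0 = 0.2), "beta0 = 0")
  expect_error(planted_effect(1, "reactive", beta0 = 1, decay_span = 0),
               "decay_span")
  des <- cohort_design(n_pairs = 2, p_features = 1, seed = 1)
  expect_error(generate_cohort(des, list(planted_effect(5, "causal",
                                                        beta0 = 1))),
               "feature index")
})
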