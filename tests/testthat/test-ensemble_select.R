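# Linear-model ranking, penalized-path oracle, stability selection,
# criterion intersection and the morphology-exclusion loop.

test_that("caco-only reduction reproduces the two-sample t-test", {
  set.seed(7)
  n <- 15
  lp <- paired_logmat(matrix(0, 3, n), ttd = seq_len(n), sd = 0)
  m <- lp$logmat
  for (k in 1:3) m[k, ] <- rnorm(2 * n, mean = 10, sd = 1)
  # constant gel/batch/age/gender -> dropped -> intercept + caco only
  expect_warning(fit <- fit_case_control_lm(m, lp$samples), "dropped")
  is_case <- lp$samples$caco == "case"
  for (k in 1:3) {
    oracle <- t.test(m[k, is_case], m[k, !is_case], var.equal = TRUE)
    expect_equal(fit$table$p_value[k], oracle$p.value, tolerance = 1e-10)
    expect_equal(fit$table$estimate[k],
                 mean(m[k, is_case]) - mean(m[k, !is_case]),
                 tolerance = 1e-10)
  }
})

test_that("full-covariate model matches lm() per feature", {
  coh <- small_cohort(n_pairs = 25, p = 10, seed = 17)
  m <- log_transform(coh$features)
  fit <- fit_case_control_lm(m, coh$samples)
  smp <- coh$samples[coh$samples$role == "study", ]
  smp <- smp[match(colnames(m), smp$sample_id), ]
  for (k in c(1, 5, 10)) {
    d <- data.frame(y = m[k, ], caco = as.numeric(smp$caco == "case"),
                    gel = smp$gel, batch = as.numeric(smp$batch == 2),
                    age = smp$age, gender = as.numeric(smp$gender == "M"))
    oracle <- summary(lm(y ~ caco + gel + batch + age + gender, d))
    expect_equal(fit$table$p_value[k],
                 oracle$coefficients["caco", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("symmetric pairs give a zero case-control coefficient", {
  lp <- paired_logmat(matrix(0, 2, 10), ttd = 1:10, sd = 0)
  m <- lp$logmat
  m[, ] <- m + rnorm(2)   # feature-level offsets; case == control per pair
  expect_warning(fit <- fit_case_control_lm(m, lp$samples))
  expect_equal(fit$table$estimate, c(0, 0), tolerance = 1e-12)
})

test_that("a strong planted feature ranks in the top 1% almost surely", {
  hits <- vapply(1:20, function(s) {
    des <- cohort_design(n_pairs = 66, p_features = 2000, seed = 1000 + s)
    coh <- generate_cohort(des,
                           list(planted_effect(1, "causal", beta0 = 1.0)),
                           noise_model(residual_sd = 0.3))
    fit <- fit_case_control_lm(log_transform(coh$features), coh$samples)
    fit$table$p_rank[1] <= ceiling(0.01 * 2000)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("lasso subroutine matches the soft-threshold closed form", {
  # orthonormal design (columns with x'x/n = 1, orthogonal), gaussian:
  # beta_j(lambda) = sign(z_j) * max(|z_j| - lambda, 0), z_j = x_j'y/n
  set.seed(3)
  n <- 400
  x1 <- rep(c(1, -1), n / 2)
  x2 <- rep(c(1, 1, -1, -1), n / 4)
  x <- cbind(x1, x2)
  stopifnot(abs(crossprod(x)[1, 2]) < 1e-12)
  y <- 0.9 * x1 + 0.2 * x2 + rnorm(n, 0, 0.5)
  y <- y - mean(y)
  z <- as.numeric(crossprod(x, y) / n)
  lambda <- sort(c(1.2, 0.6, 0.3, 0.1, 0.01), decreasing = TRUE)
  beta <- lasso_path(x, y, lambda, family = "gaussian",
                     standardize = FALSE)
  for (j in 1:2) for (l in seq_along(lambda)) {
    oracle <- sign(z[j]) * max(abs(z[j]) - lambda[l], 0)
    expect_equal(beta[j, l], oracle, tolerance = 1e-6)
  }
  expect_error(lasso_path(x, y, rev(lambda), family = "gaussian"),
               "descending")
})

test_that("stability selection: separator saturates, null model empties", {
  set.seed(21)
  n <- 20
  lp <- paired_logmat(matrix(c(3, 0, 0), 3, n), ttd = seq_len(n), sd = 0.2)
  prof <- bootstrap_lasso(lp$logmat, lp$samples, B = 40, seed = 5)
  expect_equal(unname(prof$summary["f001"]), 1.0, tolerance = 0.05)
  expect_true(prof$retained[prof$feature_ids == "f001"])
  # frequencies are probabilities and reproducible under a fixed seed
  expect_true(all(prof$freq >= 0 & prof$freq <= 1))
  prof2 <- bootstrap_lasso(lp$logmat, lp$samples, B = 40, seed = 5)
  expect_identical(prof$freq, prof2$freq)
  # a penalty at/above the data-wide maximum shrinks everything to zero
  big <- max(prof$grid) * 10
  prof0 <- bootstrap_lasso(lp$logmat, lp$samples, B = 10,
                           grid = c(big, big * 0.999), seed = 5)
  expect_true(all(prof0$freq == 0))
  expect_error(bootstrap_lasso(lp$logmat, lp$samples, B = 0), "B must")
})

test_that("data-driven frequency cutoff finds the gap or falls back", {
  mk <- function(f) structure(list(summary = setNames(f, names(f)),
                                   feature_ids = names(f)),
                              class = "stability_profile")
  f1 <- setNames(c(0.9, 0.85, 0.8, 0.02, 0.01),
                 sprintf("f%d", 1:5))
  cut1 <- choose_freq_cut(mk(f1))
  expect_gt(cut1, 0.02)
  expect_lte(cut1, 0.8)
  # all equal: no gap -> fallback
  f2 <- setNames(rep(0.4, 6), sprintf("f%d", 1:6))
  expect_equal(choose_freq_cut(mk(f2)), 0.10)
  # planted-signal profile: cutoff separates signal from null
  f3 <- setNames(c(rep(0.75, 5), runif(95, 0, 0.08)),
                 sprintf("f%d", 1:100))
  cut3 <- choose_freq_cut(mk(f3))
  expect_true(all(f3[1:5] >= cut3))
  expect_true(mean(f3[6:100] < cut3) >= 0.99)
})

test_that("random forest importance: separator wins, runs reproduce", {
  set.seed(10)
  n <- 20
  lfc <- matrix(0, 10, n)
  lfc[1, ] <- 3
  lp <- paired_logmat(lfc, ttd = seq_len(n), sd = 0.2)
  imp <- rf_importance(lp$logmat, lp$samples, n_trees = 100, seed = 4)
  expect_equal(imp$table$rank[imp$table$feature_id == "f001"], 1L)
  expect_gt(imp$oob_accuracy, 0.9)
  imp2 <- rf_importance(lp$logmat, lp$samples, n_trees = 100, seed = 4)
  expect_identical(imp$table, imp2$table)
  expect_error(rf_importance(lp$logmat, lp$samples, n_trees = 0),
               "n_trees")
})

test_that("pure-noise importances are calibrated to a permutation null", {
  # oracle: with case/control labels shuffled, importances follow the exact
  # null distribution; a pure-noise run should not produce more features
  # above that null's 99.9th percentile than chance allows.  (The naive
  # sign-flip mirror is not a valid null here: finite-sample chance
  # correlations give the true null a heavier positive tail.)
  set.seed(77)
  noise_run <- function(seed, shuffle) {
    lp <- paired_logmat(matrix(0, 150, 20), ttd = 1:20, sd = 1)
    if (shuffle) lp$samples$caco <- sample(lp$samples$caco)
    rf_importance(lp$logmat, lp$samples, n_trees = 150,
                  seed = seed)$table$importance
  }
  null_pool <- unlist(lapply(1:3, function(s) noise_run(100 + s, TRUE)))
  obs <- unlist(lapply(1:3, function(s) noise_run(s, FALSE)))
  thr <- quantile(null_pool, 0.999)
  # expected exceedances 0.001 * 450 = 0.45; allow Poisson-ish slack
  expect_lte(sum(obs > thr), 3)
  expect_lt(abs(mean(obs)), 0.002)
})

test_that("criterion intersection is a guarded set intersection", {
  ids <- c("a", "b", "c", "d")
  # top-50% rank cutoff (ceiling(0.5*4) = 2): lm picks {a,b}, rf {b,c};
  # stability retains {b,c,d}; intersection = {b}
  cr <- fake_criteria(
    p_value = setNames(c(0.001, 0.002, 0.5, 0.9), ids),
    stability = setNames(c(0.05, 0.9, 0.8, 0.2), ids),
    importance = setNames(c(0.001, 0.05, 0.06, -0.01), ids))
  sel <- intersect_criteria(cr$fit, cr$profile, cr$importance,
                            top_frac = 0.5)
  expect_equal(sel$feature_id[sel$selected], "b")
  # exclusion dominates
  sel2 <- intersect_criteria(cr$fit, cr$profile, cr$importance,
                             top_frac = 0.5, exclusions = "b")
  expect_equal(sum(sel2$selected), 0)
  expect_true(sel2$excluded[sel2$feature_id == "b"])
  # monotonicity: shrinking top_frac never adds a feature
  sel3 <- intersect_criteria(cr$fit, cr$profile, cr$importance,
                             top_frac = 0.25)
  expect_true(all(sel3$feature_id[sel3$selected] %in%
                    sel$feature_id[sel$selected]))
  # mismatched feature sets rejected
  cr2 <- fake_criteria(p_value = setNames(0.1, "zz"),
                       stability = setNames(1, "zz"),
                       importance = setNames(1, "zz"))
  expect_error(intersect_criteria(cr$fit, cr2$profile, cr2$importance),
               "different feature sets")
})

test_that("selection loop removes flagged features until stable", {
  ids <- sprintf("f%02d", 1:10)
  cr <- fake_criteria(
    p_value = setNames(seq(0.001, 0.01, length.out = 10), ids),
    stability = setNames(rep(0.9, 10), ids),
    importance = setNames(seq(1, 0.1, length.out = 10), ids))
  # top_frac 0.2 -> rank cutoff 2 -> selected {f01, f02}
  sel <- selection_loop(cr$fit, cr$profile, cr$importance, top_frac = 0.2)
  expect_equal(sel$feature_id[sel$selected], c("f01", "f02"))
  expect_equal(attr(sel, "iterations"), 1L)
  # flagging the top feature promotes the next candidate
  sel2 <- selection_loop(cr$fit, cr$profile, cr$importance,
                         morphology_flags = "f01", top_frac = 0.2)
  expect_equal(sel2$feature_id[sel2$selected], c("f02", "f03"))
  expect_equal(attr(sel2, "removed"), "f01")
  # flagging everything empties the selection and terminates
  sel3 <- selection_loop(cr$fit, cr$profile, cr$importance,
                         morphology_flags = ids, top_frac = 0.2)
  expect_equal(sum(sel3$selected), 0)
})

test_that("selected set is invariant to feature and sample ordering", {
  coh <- small_cohort(n_pairs = 20, p = 80, beta0 = 1.5, seed = 19)
  run <- function(tables) {
    raw <- log_transform(tables$features)
    norm <- upper_quantile_scale(
      batch_gel_adjust(raw, tables$samples)$normalized)
    fit <- fit_case_control_lm(raw, tables$samples)
    prof <- bootstrap_lasso(norm, tables$samples, B = 25, seed = 2)
    imp <- rf_importance(norm, tables$samples, n_trees = 60, seed = 3)
    sel <- intersect_criteria(fit, prof, imp, top_frac = 0.05)
    sort(sel$feature_id[sel$selected])
  }
  base <- run(coh)
  set.seed(1)
  perm_f <- sample(nrow(coh$features$intensities))
  perm_s <- sample(ncol(coh$features$intensities))
  ft <- coh$features
  shuf <- feature_table(ft$features$feature_id[perm_f],
                        ft$features$mz[perm_f], ft$features$rt_sec[perm_f],
                        ft$intensities[perm_f, perm_s],
                        ft$samples[order(match(ft$samples$sample_id,
                                               colnames(ft$intensities)[perm_s])), ])
  expect_gt(length(base), 0)
  expect_identical(run(list(features = shuf, samples = shuf$samples)), base)
})
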