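# End-to-end orchestration: filter -> normalize -> select -> classify-ttd
# -> report, with stage accounting and deterministic artifacts.

#' Pipeline configuration
#'
#' @param features_path,samples_path input TSV paths (the dialects of
#'   [write_fixture()]); alternatively pass in-memory `tables` to
#'   [run_pipeline()].
#' @param out_dir output directory.
#' @param min_fold blank-filter threshold (default 1.5).
#' @param max_cv QC CV threshold (default 0.30).
#' @param B bootstrap replicates for stability selection (default 500).
#' @param grid_size penalty-grid size (default 50).
#' @param freq_cut stability retention threshold (default 0.10).
#' @param top_frac rank fraction for p-value / importance criteria
#'   (default 0.01).
#' @param n_trees random-forest size (default 500).
#' @param alpha ttd slope significance level (default 0.05).
#' @param exclusions_file optional file of morphology-flagged feature ids,
#'   one per line.
#' @param seed RNG seed (mandatory for the stochastic stages).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(features_path = NULL, samples_path = NULL,
                            out_dir = "lipidens_out", min_fold = 1.5,
                            max_cv = 0.30, B = 500, grid_size = 50,
                            freq_cut = 0.10, top_frac = 0.01, n_trees = 500,
                            alpha = 0.05, exclusions_file = NULL, seed = 1) {
  stopifnot(min_fold >= 0, max_cv >= 0, B >= 1, grid_size >= 2,
            freq_cut > 0, freq_cut <= 1, top_frac > 0, top_frac <= 1,
            n_trees >= 1, alpha > 0, alpha < 1, !is.null(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes blank filter, QC CV filter, log transform, batch/gel
#' adjustment, upper-quantile scaling, ensemble selection, ttd
#' classification and reporting; writes TSV/JSON artifacts into
#' `config$out_dir` and logs stage counts to stderr.  All randomness is
#' controlled by `config$seed`, so repeated runs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param tables optional in-memory input (list with `features` and
#'   `samples`) overriding the configured paths.
#' @return invisibly, the report bundle (list of all stage artifacts).
#' @export
run_pipeline <- function(config, tables = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logmsg <- function(...) message("[lipidens] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(tables)) {
    if (is.null(config$features_path) || is.null(config$samples_path))
      stop("no input: set features_path/samples_path or pass tables")
    dirn <- dirname(config$features_path)
    tables <- stage("read", read_fixture(dirn))
  }
  ft <- tables$features
  samples <- tables$samples
  n_in <- nrow(ft$intensities)
  logmsg("input: %d features, %d samples (seed %d)", n_in,
         ncol(ft$intensities), config$seed)

  bf <- stage("blank_filter", blank_filter(ft, config$min_fold))
  qf <- stage("qc_cv_filter", qc_cv_filter(bf$table, config$max_cv))
  ft2 <- qf$table
  logmsg("filters: %d -> %d (blank) -> %d (qc)", n_in,
         nrow(bf$table$intensities), nrow(ft2$intensities))

  empty_sel <- nrow(ft2$intensities) == 0
  if (!empty_sel) {
    rawlog <- stage("log_transform", log_transform(ft2))
    norm_fit <- stage("batch_gel_adjust", batch_gel_adjust(rawlog, samples))
    norm <- stage("upper_quantile_scale",
                  upper_quantile_scale(norm_fit$normalized))
  } else {
    rawlog <- norm <- ft2$intensities
    norm_fit <- NULL
  }

  sel_out <- NULL
  if (!empty_sel) {
    fit <- stage("fit_case_control_lm", fit_case_control_lm(rawlog, samples))
    profile <- stage("bootstrap_lasso",
                     bootstrap_lasso(norm, samples, B = config$B,
                                     grid_size = config$grid_size,
                                     freq_cut = config$freq_cut,
                                     seed = child_seed(config$seed, 1)))
    imp <- stage("rf_importance",
                 rf_importance(norm, samples, n_trees = config$n_trees,
                               seed = child_seed(config$seed, 2)))
    flags <- character(0)
    if (!is.null(config$exclusions_file) &&
        file.exists(config$exclusions_file))
      flags <- readLines(config$exclusions_file, warn = FALSE)
    sel_out <- stage("selection",
                     selection_loop(fit, profile, imp, flags,
                                    top_frac = config$top_frac))
  }
  selected <- if (empty_sel) character(0) else
    sel_out$feature_id[sel_out$selected]
  logmsg("selected: %d feature(s)", length(selected))

  fits <- NULL
  rate <- NULL
  if (length(selected)) {
    rec <- stage("pair_log_fold_change",
                 pair_log_fold_change(norm, samples, selected))
    fits <- stage("ttd_regress", ttd_regress(rec, alpha = config$alpha))
    rate <- stage("in_sample_classification",
                  in_sample_classification(norm, samples, selected))
  }

  cohort <- stage("cohort_table", cohort_table(samples))
  volcano <- if (empty_sel) NULL else volcano_export(fit, sel_out)

  # --- artifacts ---
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  wt <- function(x, f) if (!is.null(x))
    write.table(format(x, digits = 6, trim = TRUE, scientific = FALSE),
                outp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_filter_report(list(bf$report, qf$report), outp("filter_report.tsv"))
  if (!empty_sel) {
    write.table(data.frame(feature_id = rownames(norm),
                           signif(norm, 7), check.names = FALSE),
                outp("normalized.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_selection(sel_out, outp("selection.tsv"))
  }
  wt(fits, "ttd_classes.tsv")
  wt(volcano, "volcano.tsv")
  wt(cohort, "cohort_table.tsv")

  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("lipidens")),
    parameters = config[setdiff(names(config),
                                c("features_path", "samples_path",
                                  "out_dir", "exclusions_file"))],
    stage_counts = list(
      input = n_in,
      after_blank_filter = nrow(bf$table$intensities),
      after_qc_filter = nrow(ft2$intensities),
      dropped_blank = sum(!bf$report$pass),
      dropped_qc = sum(!qf$report$pass)
    ),
    selected_features = selected,
    ttd_classes = if (!is.null(fits))
      setNames(as.list(fits$class), fits$feature_id) else list(),
    in_sample_rate = if (!is.null(rate)) rate$rate else NA,
    optimism_caveat = paste("in-sample rate: the same data performed",
                            "selection and evaluation; expect optimism")
  )
  jsonlite::write_json(report, outp("report.json"), auto_unbox = TRUE,
                       digits = 6, pretty = TRUE, null = "null")
  logmsg("report written to %s", config$out_dir)

  invisible(list(filter = list(blank = bf$report, qc = qf$report),
                 normalization = norm_fit, normalized = norm,
                 lm_fit = if (empty_sel) NULL else fit,
                 stability = if (empty_sel) NULL else profile,
                 importance = if (empty_sel) NULL else imp,
                 selection = sel_out, ttd = fits, rate = rate,
                 cohort = cohort, volcano = volcano, report = report))
}
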