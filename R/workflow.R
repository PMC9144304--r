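#' Built-in compound metadata for examples and benchmarks
#'
#' A synthetic flavonoid-like compound (modeled on a tricin MRM spectrum
#' entry) with reference intensity 40000 AUA, used wherever a default
#' compound scale is needed.
#'
#' @return A [compound_meta()].
#' @export
example_compound <- function() {
  compound_meta("tricin_synthetic", 40000,
                accession = "SYN-FIO-0001",
                extra = list(note = "synthetic stand-in spectrum scale"))
}

#' Run the simulation benchmark workflow end to end
#'
#' The package's reference experiment: simulate one compound over three
#' batches of 100, 200 and 300 injections with every 25th injection a
#' pooled QC and a type-4 effect (monotone drift plus batch shifts) at
#' severity 1.25; run the three outlier detectors on the drifted table;
#' correct it twice — with pseudoQC anchors trained on the largest batch,
#' and with the true QC anchors as comparator — and score both corrections
#' against the drift-free control by 10-fold cross-validated regression.
#'
#' @param seed Integer seed driving the simulation and fold assignment.
#' @param config A [drift_config()]; defaults to the scenario above.
#' @param grid A [param_grid()] for pseudoQC optimization.
#' @param out_dir Optional directory; when given, the corrected tables and
#'   a JSON report are written there.
#' @return A list of class `benchmark_report` with the simulation seed,
#'   outlier flag counts per method, optimized [pseudoqc_params()], and
#'   [cv_regression_metrics()] for both corrections.
#' @export
run_drift_benchmark <- function(seed = 1L, config = NULL, grid = param_grid(),
                                out_dir = NULL) {
  if (is.null(config)) config <- drift_config(seed = seed)
  meta <- example_compound()
  bundle <- simulate_data(meta, config)
  drifted <- bundle$type4

  n_pw <- nrow(pw_outlier(drifted)$flagged)
  n_iqr <- nrow(iqr_outlier(drifted)$flagged)
  n_grubbs <- nrow(grubbs_iterative(drifted)$flagged)

  train_batch <- batches(drifted)[which.max(config$batch_sizes)]
  res_pseudo <- pseudo_sdc(drifted, train_batch, grid)
  res_true <- qcrsc_correct(drifted, anchors = "trueqc",
                            compound = meta$compound_id)

  cv_pseudo <- cv_regression_metrics(res_pseudo$corrected, bundle$control,
                                     folds = 10L, seed = seed)
  cv_true <- cv_regression_metrics(res_true$corrected, bundle$control,
                                   folds = 10L, seed = seed)

  report <- structure(
    list(seed = seed, config = config, train_batch = train_batch,
         outlier_counts = c(pairwise = n_pw, iqr = n_iqr, grubbs = n_grubbs),
         params = res_pseudo$params,
         cv_pseudoqc = cv_pseudo, cv_trueqc = cv_true),
    class = "benchmark_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peak_table(res_pseudo$corrected,
                     file.path(out_dir, "corrected_pseudoqc.csv"))
    write_peak_table(res_true$corrected,
                     file.path(out_dir, "corrected_trueqc.csv"))
    write_peak_table(res_pseudo$augmented,
                     file.path(out_dir, "augmented_pseudoqc.csv"))
    jsonlite::write_json(
      list(seed = seed,
           batch_sizes = config$batch_sizes, qc_every = config$qc_every,
           slope_magnitude = config$slope_magnitude,
           batch_magnitude = config$batch_magnitude,
           outlier_counts = as.list(report$outlier_counts),
           params = report$params[c("quantile_increment", "test_breaks",
                                    "test_window", "test_index",
                                    "criterion_value")],
           cv_pseudoqc = list(r2 = cv_pseudo$r2, rmse = cv_pseudo$rmse),
           cv_trueqc = list(r2 = cv_true$r2, rmse = cv_true$rmse)),
      file.path(out_dir, "benchmark_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  cat(sprintf("  seed %d | batches %s | qc every %d | severity %.2f/%.2f\n",
              x$seed, paste(x$config$batch_sizes, collapse = "/"),
              x$config$qc_every, x$config$slope_magnitude,
              x$config$batch_magnitude))
  cat(sprintf("  outliers flagged: pairwise=%d, iqr=%d, grubbs=%d\n",
              x$outlier_counts["pairwise"], x$outlier_counts["iqr"],
              x$outlier_counts["grubbs"]))
  cat(sprintf("  pseudoQC correction: R2 = %.4f, RMSE = %.6g\n",
              x$cv_pseudoqc$r2, x$cv_pseudoqc$rmse))
  cat(sprintf("  trueQC  correction: R2 = %.4f, RMSE = %.6g\n",
              x$cv_trueqc$r2, x$cv_trueqc$rmse))
  invisible(x)
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text fixtures used by examples and tests:
#' * `toy.sdf` — a two-record synthetic SDF with spectral peak lists;
#' * `multibatch_partial_qc.csv` — a four-batch table shaped like a large
#'   targeted LC-MS campaign (batches of 165/198/663/1008 injections) in
#'   which only the largest batch carries pooled QC injections, with a
#'   type-4 effect applied;
#' * `driftfree.csv` — a drift-free single-compound table;
#' * `planted_outliers.csv` + `planted_outliers_truth.csv` — a one-batch
#'   replicate-triplet table with gross (10x) single-replicate outliers
#'   planted at known positions.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
generate_fixtures <- function(seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  sdf_path <- file.path(out_dir, "toy.sdf")
  write_sdf_metadata(list(
    example_compound(),
    compound_meta("apigenin_synthetic", 12000, accession = "SYN-FIO-0002")
  ), sdf_path)
  files <- c(files, sdf_path)

  cfg <- drift_config(batch_sizes = c(165L, 198L, 663L, 1008L),
                      qc_every = 25L, seed = seed)
  bundle <- simulate_data(example_compound(), cfg)
  tab <- bundle$type4
  keep <- !(tab$sample_class == "qc" & tab$batch_id != "B4")
  partial <- peak_table(as.data.frame(tab)[keep, , drop = FALSE])
  p1 <- file.path(out_dir, "multibatch_partial_qc.csv")
  write_peak_table(partial, p1)
  files <- c(files, p1)

  flat <- simulate_control(example_compound(),
                           drift_config(batch_sizes = c(100L, 100L),
                                        qc_every = 25L, seed = seed + 1L))
  p2 <- file.path(out_dir, "driftfree.csv")
  write_peak_table(flat, p2)
  files <- c(files, p2)

  set.seed(seed + 2L)
  base <- simulate_control(example_compound(),
                           drift_config(batch_sizes = c(78L, 78L, 78L),
                                        qc_every = 26L, seed = seed + 2L))
  ## one gross outlier per batch: each stays above its batch's pairwise
  ## threshold, so recall is exact by construction
  planted <- sort(vapply(batches(base), function(b) {
    sample(which(base$sample_class == "experimental" & base$batch_id == b), 1L)
  }, integer(1)))
  base$peak_area[planted] <- base$peak_area[planted] * 10
  p3 <- file.path(out_dir, "planted_outliers.csv")
  write_peak_table(base, p3)
  truth <- as.data.frame(base)[planted,
                               c("sample_id", "replicate_id", "batch_id",
                                 "compound_id")]
  p4 <- file.path(out_dir, "planted_outliers_truth.csv")
  utils::write.csv(truth, p4, row.names = FALSE)
  files <- c(files, p3, p4)
  invisible(files)
}
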