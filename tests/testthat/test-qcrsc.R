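test_that("flat anchors make the correction an exact identity", {
  tab <- drifted_table(n = 60, qc_every = 6, drift_fun = function(i) rep(1, length(i)))
  res <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1")
  expect_equal(res$corrected$peak_area, tab$peak_area, tolerance = 1e-9)
  trend <- do.call(rbind, res$per_batch_trend)
  expect_equal(trend$trend_factor, rep(1, nrow(trend)), tolerance = 1e-9)
})

test_that("record keys and row counts are preserved", {
  set.seed(31)
  b <- simulate_data(example_compound(),
                     drift_config(batch_sizes = c(75, 100), seed = 31))
  res <- qcrsc_correct(b$type4, anchors = "trueqc", compound = "tricin_synthetic")
  key <- function(t) paste(t$sample_id, t$replicate_id, t$batch_id,
                           t$injection_order)
  expect_identical(key(res$corrected), key(b$type4))
  expect_gt(min(do.call(rbind, res$per_batch_trend)$trend_factor), 0)
})

test_that("noiseless multiplicative drift is removed to within 1%", {
  base <- 1000
  drift <- function(i) 1.3^((i - 1) / 99)     # geometric ramp over the batch
  tab <- drifted_table(n = 100, qc_every = 10, base = base, drift_fun = drift)
  res <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1")
  qc_corr <- res$corrected$peak_area[res$corrected$sample_class == "qc"]
  expect_lt(diff(range(qc_corr)) / mean(qc_corr), 0.01)
  expect_equal(res$corrected$peak_area, rep(base, 100) * mean(res$corrected$peak_area) / base,
               tolerance = 0.01)
})

test_that("pseudoQC-anchored correction of noiseless drift recovers the control", {
  base <- 2000
  n <- 90
  drift <- function(i) 1.25^((i - 1) / (n - 1))
  tab <- drifted_table(n = n, qc_every = 9, base = base, drift_fun = drift)
  aug <- estimate_pseudoqc(tab, pseudoqc_params(0, 6, 5, 0), "cmp1")
  res <- qcrsc_correct(aug, anchors = "pseudoqc", compound = "cmp1")
  # corrected values are flat up to the median-alignment constant
  expect_lt(sd(res$corrected$peak_area) / mean(res$corrected$peak_area), 0.01)
  expect_false("pseudoqc" %in% res$corrected$sample_class)
  expect_true("pseudoqc" %in% res$augmented$sample_class)
})

test_that("median alignment equalizes anchor levels across batches", {
  set.seed(17)
  rows <- lapply(1:2, function(b) {
    as.data.frame(drifted_table(n = 60, qc_every = 6, base = c(1000, 4000)[b],
                                drift_fun = function(i) rep(1, length(i)),
                                batch = sprintf("B%d", b)))
  })
  tab <- peak_table(do.call(rbind, rows))
  res <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1")
  med <- tapply(res$corrected$peak_area[res$corrected$sample_class == "qc"],
                res$corrected$batch_id[res$corrected$sample_class == "qc"],
                median)
  expect_equal(unname(diff(range(med))), 0, tolerance = 1e-9)
  res_none <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1",
                            align = "none")
  med_none <- tapply(res_none$corrected$peak_area[res_none$corrected$sample_class == "qc"],
                     res_none$corrected$batch_id[res_none$corrected$sample_class == "qc"],
                     median)
  expect_gt(unname(diff(range(med_none))), 1000)
})

test_that("batches short on anchors fall back gracefully", {
  # 3 QCs -> linear fit; still removes a log-linear drift exactly
  tab <- drifted_table(n = 30, qc_every = 8, drift_fun = function(i) 1.2^(i / 30))
  expect_silent(res <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1"))
  qc_corr <- res$corrected$peak_area[res$corrected$sample_class == "qc"]
  expect_lt(diff(range(qc_corr)) / mean(qc_corr), 0.01)
  # 1 QC -> median alignment only, with warning
  tab1 <- drifted_table(n = 14, qc_every = 8)
  expect_warning(res1 <- qcrsc_correct(tab1, anchors = "trueqc", compound = "cmp1"),
                 "fewer than 2")
  expect_equal(nrow(res1$corrected), 14)
})

test_that("the full train/transfer/correct pipeline is deterministic", {
  b <- simulate_data(example_compound(),
                     drift_config(batch_sizes = c(100, 150), seed = 23))
  r1 <- suppressWarnings(pseudo_sdc(b$type4, "B2"))
  r2 <- suppressWarnings(pseudo_sdc(b$type4, "B2"))
  expect_identical(r1$corrected, r2$corrected)
  expect_identical(r1$params, r2$params)
  expect_equal(r1$anchors_used, "pseudoqc")
})

test_that("drift-free data passes through pseudo_sdc nearly unchanged", {
  cfg <- drift_config(batch_sizes = c(100, 150), slope_magnitude = 1,
                      batch_magnitude = 1, seed = 29)
  b <- simulate_data(example_compound(), cfg)
  res <- suppressWarnings(pseudo_sdc(b$control, "B2"))
  rel <- abs(res$corrected$peak_area / b$control$peak_area - 1)
  expect_lt(median(rel), cfg$technical_cv)
})

test_that("a batch layout with QCs only in the largest batch runs end to end", {
  cfg <- drift_config(batch_sizes = c(48, 66, 96), qc_every = 24, seed = 37)
  b <- simulate_data(example_compound(), cfg)
  tab <- as.data.frame(b$type4)
  tab <- tab[!(tab$sample_class == "qc" & tab$batch_id != "B3"), ]
  res <- suppressWarnings(pseudo_sdc(peak_table(tab), "B3"))
  expect_equal(sum(res$augmented$sample_class == "pseudoqc") %% 3, 0)
  expect_equal(nrow(res$corrected), nrow(tab))
})

test_that("location-scale baseline equalizes batches but keeps intra-batch drift", {
  set.seed(41)
  mk <- function(batch, base) {
    as.data.frame(drifted_table(n = 80, qc_every = 10, base = base,
                                drift_fun = function(i) 1.3^((i - 1) / 79),
                                noise_cv = 0.02, batch = batch))
  }
  tab <- peak_table(rbind(mk("B1", 1000), mk("B2", 4000)))
  corr <- location_scale_batch_correct(tab, "cmp1")
  lmean <- tapply(log(corr$peak_area), corr$batch_id, mean)
  expect_equal(unname(diff(lmean)), 0, tolerance = 1e-9)
  # intra-batch trend slope survives the location-scale baseline
  b1 <- corr[corr$batch_id == "B1", ]
  raw1 <- tab[tab$batch_id == "B1", ]
  slope_corr <- coef(lm(log(peak_area) ~ injection_order, data = b1))[2]
  slope_raw <- coef(lm(log(peak_area) ~ injection_order, data = raw1))[2]
  expect_gt(slope_raw, 0.001)
  expect_equal(unname(slope_corr / slope_raw), 1, tolerance = 0.1)
  # ...while the spline correction removes it
  rsc <- qcrsc_correct(tab, anchors = "trueqc", compound = "cmp1")
  b1_rsc <- rsc$corrected[rsc$corrected$batch_id == "B1", ]
  slope_rsc <- coef(lm(log(peak_area) ~ injection_order, data = b1_rsc))[2]
  expect_lt(abs(slope_rsc), 0.2 * slope_raw)
})

test_that("single-batch location-scale correction warns and returns identity", {
  tab <- vector_table(rnorm(20, 100, 5))
  expect_warning(out <- location_scale_batch_correct(tab, "cmp1"), "single")
  expect_equal(out$peak_area, tab$peak_area)
})
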