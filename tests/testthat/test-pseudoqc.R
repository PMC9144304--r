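test_that("constant signal yields constant pseudoQC anchors", {
  tab <- vector_table(rep(500, 60))
  p <- pseudoqc_params(0.1, 4, 5, 1)
  aug <- estimate_pseudoqc(tab, p, "cmp1")
  anchors <- aug[aug$sample_class == "pseudoqc", ]
  expect_equal(nrow(anchors), 4)
  expect_equal(anchors$peak_area, rep(500, 4))
})

test_that("anchor count equals test_breaks in every batch", {
  set.seed(10)
  tab <- random_triplet_table(n_samples = 30, n_batches = 3)
  p <- pseudoqc_params(0.05, 5, 3, 2)
  aug <- estimate_pseudoqc(tab, p, "cmp1")
  anchors <- aug[aug$sample_class == "pseudoqc", ]
  expect_equal(unname(table(anchors$batch_id)), rep(5L, 3), ignore_attr = TRUE)
})

test_that("on a noiseless linear trend anchors lie exactly on the line", {
  # rolling median of consecutive values on a line is the window's middle value
  n <- 60
  tab <- vector_table(100 + 5 * (1:n))
  for (ti in c(0, 2, 4)) {
    p <- pseudoqc_params(0, 3, 5, ti)
    aug <- estimate_pseudoqc(tab, p, "cmp1")
    anchors <- aug[aug$sample_class == "pseudoqc", ]
    expect_equal(anchors$peak_area, 100 + 5 * anchors$injection_order)
  }
})

test_that("quantile trimming discards exactly the outer band", {
  # segment of 20 values 1..20 with qi = 0.25: band [5.75, 15.25] keeps 6..15,
  # rolling median (w=3) over 6..15 starts at 7; with index 0 the anchor is 7
  # at the injection of retained value 2 (= injection 7)
  tab <- vector_table(as.numeric(1:20))
  p <- pseudoqc_params(0.25, 1, 3, 0)
  aug <- suppressWarnings(estimate_pseudoqc(tab, p, "cmp1"))
  a <- aug[aug$sample_class == "pseudoqc", ]
  expect_equal(a$peak_area, 7)
  expect_equal(a$injection_order, 7L)
})

test_that("infeasible segmentations raise informative errors", {
  tab <- vector_table(as.numeric(1:10))
  expect_error(suppressWarnings(
    estimate_pseudoqc(tab, pseudoqc_params(0, 4, 5, 0), "cmp1")), "segments")
  expect_error(suppressWarnings(
    estimate_pseudoqc(tab, pseudoqc_params(0.4, 2, 5, 0), "cmp1")),
    "quantile trimming")
  expect_error(suppressWarnings(
    estimate_pseudoqc(tab, pseudoqc_params(0, 2, 5, 2), "cmp1")), "test_index")
  expect_error(estimate_pseudoqc(tab, pseudoqc_params(0, 2, 3, 0), "nope"),
               "not present")
})

test_that("small training batches trigger the reliability warning", {
  tab <- vector_table(rnorm(15, 100, 1))
  expect_warning(estimate_pseudoqc(tab, pseudoqc_params(0, 2, 3, 0), "cmp1"),
                 "unreliable")
})

test_that("optimization matches the exhaustive grid oracle", {
  set.seed(55)
  small_grid <- param_grid(quantile_increment = c(0, 0.1, 0.2),
                           test_breaks = 2:3, test_window = c(3, 5))
  for (i in 1:20) {
    tab <- drifted_table(n = sample(c(40, 60), 1), qc_every = 8,
                         noise_cv = runif(1, 0.02, 0.25),
                         drift_fun = function(i) 1 + runif(1, -0.4, 0.6) * i / 60)
    got <- suppressWarnings(optimize_params(tab, "B1", small_grid, "cmp1"))
    want <- oracle_optimize(tab, "B1", small_grid, "cmp1")
    expect_equal(got$test_breaks, want$k)
    expect_equal(got$test_window, want$w)
    expect_equal(got$test_index, want$ti)
    expect_equal(got$quantile_increment, want$qi)
    expect_equal(got$criterion_value, want$mse, tolerance = 1e-12)
  }
})

test_that("criterion value is reproducible from the returned parameters", {
  set.seed(77)
  tab <- drifted_table(n = 80, qc_every = 10, noise_cv = 0.1)
  params <- suppressWarnings(optimize_params(tab, "B1", param_grid(), "cmp1"))
  aug <- suppressWarnings(estimate_pseudoqc(tab, params, "cmp1"))
  anch <- aug[aug$sample_class == "pseudoqc", ]
  qc <- tab[tab$sample_class == "qc", ]
  pred <- approx(anch$injection_order, anch$peak_area,
                 xout = qc$injection_order, rule = 2, ties = mean)$y
  expect_equal(params$criterion_value, mean((pred - qc$peak_area)^2),
               tolerance = 1e-9)
})

test_that("optimization is deterministic and honours tie-breaking", {
  tab <- vector_table(rep(c(100, 100, 100), 20))
  qc_rows <- data.frame(sample_id = sprintf("QC%d", 1:3), replicate_id = "1",
                        batch_id = "B1", sub_batch_id = NA,
                        injection_order = 61:63, compound_id = "cmp1",
                        sample_class = "qc", peak_area = 100,
                        sample_weight = NA)
  tab2 <- peak_table(rbind(as.data.frame(tab), qc_rows))
  g <- param_grid(quantile_increment = c(0, 0.1), test_breaks = 2:4,
                  test_window = c(3, 5))
  p1 <- optimize_params(tab2, "B1", g, "cmp1")
  p2 <- optimize_params(tab2, "B1", g, "cmp1")
  expect_identical(p1, p2)
  # constant data: every combination attains MSE 0; smallest combination wins
  expect_equal(p1$criterion_value, 0)
  expect_equal(p1$test_breaks, 2L)
  expect_equal(p1$test_window, 3L)
  expect_equal(p1$test_index, 0L)
  expect_equal(p1$quantile_increment, 0)
})

test_that("optimization requires true QCs in the training batch", {
  tab <- vector_table(rnorm(40, 100, 5))
  expect_error(optimize_params(tab, "B1", param_grid(), "cmp1"),
               "trueQC")
})

test_that("anchors track the true drift factors at default severity", {
  cors <- numeric(0)
  for (s in 1:20) {
    b <- simulate_data(example_compound(),
                       drift_config(batch_sizes = c(300, 300, 300),
                                    seed = 500 + s))
    p <- pseudoqc_params(0.15, 8, 15, 0)
    aug <- estimate_pseudoqc(b$type4, p, "tricin_synthetic")
    anch <- aug[aug$sample_class == "pseudoqc", ]
    truth_at <- numeric(nrow(anch))
    for (i in seq_len(nrow(anch))) {
      sel <- b$truth$batch_id == anch$batch_id[i] &
        b$truth$injection_order == anch$injection_order[i]
      truth_at[i] <- b$truth$type4[sel][1]
    }
    cors <- c(cors, cor(anch$peak_area, truth_at))
  }
  expect_gt(median(cors), 0.9)
  expect_gte(sum(cors > 0.85), 18)
})
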