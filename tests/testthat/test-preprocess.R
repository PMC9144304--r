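make_lod_table <- function(blank_areas, sub_batch = "SB1", compound = "cmp1",
                           exp_areas = NULL) {
  rows <- data.frame(
    sample_id = sprintf("BL%d", seq_along(blank_areas)), replicate_id = "1",
    batch_id = "B1", sub_batch_id = sub_batch,
    injection_order = seq_along(blank_areas), compound_id = compound,
    sample_class = "blank", peak_area = blank_areas, sample_weight = NA)
  if (!is.null(exp_areas)) {
    rows <- rbind(rows, data.frame(
      sample_id = sprintf("S%d", seq_along(exp_areas)), replicate_id = "1",
      batch_id = "B1", sub_batch_id = sub_batch,
      injection_order = length(blank_areas) + seq_along(exp_areas),
      compound_id = compound, sample_class = "experimental",
      peak_area = exp_areas, sample_weight = 50))
  }
  peak_table(rows)
}

test_that("LOD is three times the mean blank area per cell", {
  tab <- make_lod_table(c(10, 20, 30))
  lods <- compute_lod(tab)
  expect_equal(lods$lod, 60)
  expect_equal(lods$n_blank, 3L)
})

test_that("all-zero blanks give a zero LOD below which nothing falls", {
  tab <- make_lod_table(c(0, 0), exp_areas = c(0, 1, 5))
  lods <- compute_lod(tab)
  expect_equal(lods$lod, 0)
  res <- filter_lod(tab, lods)
  expect_length(res$removed_compounds, 0)
})

test_that("a table without blanks warns and removes nothing", {
  tab <- vector_table(1:10)
  expect_warning(lods <- compute_lod(tab), "no blank")
  expect_equal(nrow(lods), 0)
  res <- filter_lod(tab, lods)
  expect_length(res$removed_compounds, 0)
  expect_equal(nrow(res$table), 10)
})

test_that("removal needs strictly more than the threshold fraction below LOD", {
  # LOD = 30; 30 of 100 experimental records below -> removed,
  # exactly 25 of 100 below -> kept
  below30 <- make_lod_table(rep(10, 3), exp_areas = c(rep(1, 30), rep(100, 70)))
  res <- filter_lod(below30, compute_lod(below30))
  expect_equal(res$removed_compounds, "cmp1")
  below25 <- make_lod_table(rep(10, 3), exp_areas = c(rep(1, 25), rep(100, 75)))
  res2 <- filter_lod(below25, compute_lod(below25))
  expect_length(res2$removed_compounds, 0)
  expect_equal(nrow(res2$table), nrow(below25))
})

test_that("surviving compounds keep every record including sub-LOD ones", {
  tab <- make_lod_table(rep(10, 2), exp_areas = c(rep(1, 10), rep(100, 90)))
  res <- filter_lod(tab, compute_lod(tab))
  expect_equal(nrow(res$table), nrow(tab))
})

test_that("LOD computation and filtering match brute-force recomputation", {
  set.seed(99)
  for (i in 1:40) {
    n_cmp <- sample(2:4, 1)
    rows <- list()
    inj <- 0
    for (cmp in sprintf("c%d", seq_len(n_cmp))) {
      for (sb in c("SB1", "SB2")) {
        nb <- sample(0:3, 1)
        ne <- sample(4:10, 1)
        if (nb > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sprintf("BL_%s_%s_%d", cmp, sb, 1:nb),
            replicate_id = "1", batch_id = "B1", sub_batch_id = sb,
            injection_order = inj + seq_len(nb), compound_id = cmp,
            sample_class = "blank", peak_area = runif(nb, 0, 30),
            sample_weight = NA)
          inj <- inj + nb
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("S_%s_%s_%d", cmp, sb, 1:ne),
          replicate_id = "1", batch_id = "B1", sub_batch_id = sb,
          injection_order = inj + seq_len(ne), compound_id = cmp,
          sample_class = "experimental", peak_area = runif(ne, 0, 120),
          sample_weight = 50)
        inj <- inj + ne
      }
    }
    tab <- peak_table(do.call(rbind, rows))
    lods <- suppressWarnings(compute_lod(tab))
    want <- oracle_lod(tab)
    got <- setNames(lods$lod, paste(lods$compound_id, lods$sub_batch_id))
    expect_equal(got[sort(names(got))],
                 unlist(want)[sort(names(want))], tolerance = 1e-12,
                 ignore_attr = TRUE)
    res <- filter_lod(tab, lods)
    expect_setequal(res$removed_compounds, oracle_removed_compounds(tab, want))
  }
})

test_that("weight normalization divides areas and drops blanks and standards", {
  tab <- make_lod_table(c(5, 5), exp_areas = c(100, 200))
  ext <- data.frame(sample_id = "ES1", replicate_id = "1", batch_id = "B1",
                    sub_batch_id = "SB1", injection_order = 99,
                    compound_id = "cmp1", sample_class = "external_standard",
                    peak_area = 500, sample_weight = NA)
  tab <- peak_table(rbind(as.data.frame(tab), ext))
  norm <- weight_normalize(tab)
  expect_equal(norm$peak_area[norm$sample_class == "experimental"],
               c(100, 200) / 50)
  expect_false(any(norm$sample_class %in% c("blank", "external_standard")))
})

test_that("unit weights leave areas unchanged", {
  tab <- make_lod_table(c(5, 5), exp_areas = c(100, 200))
  tab$sample_weight[tab$sample_class == "experimental"] <- 1
  norm <- weight_normalize(tab)
  expect_equal(norm$peak_area[norm$sample_class == "experimental"],
               c(100, 200))
})

test_that("missing weights are an error and double normalization is blocked", {
  tab <- make_lod_table(c(5, 5), exp_areas = c(100, 200))
  norm <- weight_normalize(tab)
  expect_error(weight_normalize(norm), "already")
  tab$sample_weight[4] <- NA
  expect_error(weight_normalize(tab), "sample_weight")
})
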