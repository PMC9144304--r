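# Independent brute-force reference implementations and fixture builders.
# These deliberately re-derive each statistic from first principles so they
# share no code path with the package functions they check.

# ---- fixture builders -------------------------------------------------------

# A table of replicate triplets in one or more batches with lognormal noise.
random_triplet_table <- function(n_samples = 20, n_batches = 1, cv = 0.2,
                                 base = 1000, compound = "cmp1") {
  rows <- list()
  for (b in seq_len(n_batches)) {
    inj <- 0L
    for (s in seq_len(n_samples)) {
      level <- base * exp(rnorm(1, 0, cv))
      for (r in 1:3) {
        inj <- inj + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("B%d_S%02d", b, s), replicate_id = as.character(r),
          batch_id = sprintf("B%d", b), injection_order = inj,
          compound_id = compound, sample_class = "experimental",
          peak_area = level * exp(rnorm(1, 0, cv / 4)),
          stringsAsFactors = FALSE)
      }
    }
  }
  peak_table(do.call(rbind, rows))
}

# Single-batch, single-replicate table from a plain numeric vector.
vector_table <- function(x, batch = "B1", compound = "cmp1",
                         class = "experimental") {
  peak_table(data.frame(
    sample_id = sprintf("S%03d", seq_along(x)), replicate_id = "1",
    batch_id = batch, injection_order = seq_along(x), compound_id = compound,
    sample_class = class, peak_area = x, stringsAsFactors = FALSE))
}

# Table with a known smooth multiplicative drift and true QCs on the curve.
drifted_table <- function(n = 100, qc_every = 10, base = 1000,
                          drift_fun = function(i) 1 + 0.5 * (i - 1) / (n - 1),
                          noise_cv = 0, batch = "B1", compound = "cmp1") {
  inj <- seq_len(n)
  is_qc <- inj %% qc_every == 0
  cls <- ifelse(is_qc, "qc", "experimental")
  area <- base * drift_fun(inj) * exp(rnorm(n, 0, noise_cv))
  peak_table(data.frame(
    sample_id = sprintf("%s_%s%03d", batch, ifelse(is_qc, "QC", "S"), inj),
    replicate_id = "1", batch_id = batch, injection_order = inj,
    compound_id = compound, sample_class = cls, peak_area = area,
    stringsAsFactors = FALSE))
}

# ---- outlier oracles --------------------------------------------------------

# Enumerates every within-sample pair, takes the empirical quantile of the
# pooled differences per (compound, batch), and applies the
# farther-from-median rule.  Returns flagged keys as "sample/replicate".
oracle_pw_flags <- function(table, q = 0.95) {
  x <- table[table$sample_class == "experimental" & !is.na(table$peak_area), ]
  flags <- character(0)
  for (cmp in unique(x$compound_id)) for (b in unique(x$batch_id)) {
    g <- x[x$compound_id == cmp & x$batch_id == b, ]
    if (!nrow(g)) next
    pairs <- data.frame()
    for (s in unique(g$sample_id)) {
      gs <- g[g$sample_id == s, ]
      if (nrow(gs) < 2) next
      cmb <- utils::combn(nrow(gs), 2)
      pairs <- rbind(pairs, data.frame(
        sample = s, i = cmb[1, ], j = cmb[2, ],
        d = abs(gs$peak_area[cmb[1, ]] - gs$peak_area[cmb[2, ]])))
    }
    if (!nrow(pairs)) next
    thr <- as.numeric(stats::quantile(pairs$d, q, type = 7))
    gmed <- stats::median(g$peak_area)
    for (r in which(pairs$d > thr)) {
      s <- pairs$sample[r]
      gs <- g[g$sample_id == s, ]
      center <- if (nrow(gs) >= 3) stats::median(gs$peak_area) else gmed
      di <- abs(gs$peak_area[pairs$i[r]] - center)
      dj <- abs(gs$peak_area[pairs$j[r]] - center)
      pick <- if (di > dj) pairs$i[r] else if (dj > di) pairs$j[r] else
        c(pairs$i[r], pairs$j[r])
      flags <- c(flags, paste(s, gs$replicate_id[pick], sep = "/"))
    }
  }
  sort(unique(flags))
}

oracle_iqr_flags <- function(table, k = 1.5) {
  x <- table[table$sample_class == "experimental" & !is.na(table$peak_area), ]
  flags <- character(0)
  for (cmp in unique(x$compound_id)) for (b in unique(x$batch_id)) {
    g <- x[x$compound_id == cmp & x$batch_id == b, ]
    if (nrow(g) < 4) next
    q1 <- as.numeric(stats::quantile(g$peak_area, 0.25, type = 7))
    q3 <- as.numeric(stats::quantile(g$peak_area, 0.75, type = 7))
    out <- g$peak_area < q1 - k * (q3 - q1) | g$peak_area > q3 + k * (q3 - q1)
    flags <- c(flags, paste(g$sample_id[out], g$replicate_id[out], sep = "/"))
  }
  sort(unique(flags))
}

oracle_grubbs_flags <- function(table, alpha = 0.05) {
  x <- table[table$sample_class == "experimental" & !is.na(table$peak_area), ]
  crit <- function(n) {
    t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
    (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
  }
  flags <- character(0)
  for (cmp in unique(x$compound_id)) for (b in unique(x$batch_id)) {
    g <- x[x$compound_id == cmp & x$batch_id == b, ]
    if (nrow(g) < 3) next
    active <- seq_len(nrow(g))
    repeat {
      v <- g$peak_area[active]
      if (length(v) < 3 || stats::sd(v) == 0) break
      i <- which.max(abs(v - mean(v)))
      G <- abs(v[i] - mean(v)) / stats::sd(v)
      if (G <= crit(length(v))) break
      flags <- c(flags, paste(g$sample_id[active[i]],
                              g$replicate_id[active[i]], sep = "/"))
      active <- active[-i]
    }
  }
  sort(unique(flags))
}

report_keys <- function(report) {
  f <- report$flagged
  sort(unique(paste(f$sample_id, f$replicate_id, sep = "/")))
}

# ---- LOD oracles ------------------------------------------------------------

oracle_lod <- function(table) {
  blk <- table[table$sample_class == "blank" & !is.na(table$peak_area), ]
  out <- list()
  for (cmp in unique(blk$compound_id)) for (sb in unique(blk$sub_batch_id)) {
    v <- blk$peak_area[blk$compound_id == cmp & blk$sub_batch_id %in% sb]
    if (length(v)) out[[paste(cmp, sb)]] <- 3 * mean(v)
  }
  out
}

oracle_removed_compounds <- function(table, lods, frac = 0.25) {
  removed <- character(0)
  for (cmp in unique(table$compound_id)) {
    below <- total <- 0
    for (i in which(table$compound_id == cmp &
                    table$sample_class == "experimental" &
                    !is.na(table$peak_area))) {
      key <- paste(cmp, table$sub_batch_id[i])
      if (is.null(lods[[key]])) next
      total <- total + 1
      if (table$peak_area[i] < lods[[key]]) below <- below + 1
    }
    if (total > 0 && below / total > frac) removed <- c(removed, cmp)
  }
  removed
}

# ---- pseudoQC grid oracle ---------------------------------------------------

# Re-runs the documented anchor construction per combination via
# estimate_pseudoqc() and re-derives the training MSE independently, then
# scans the full grid in tie-break order.
oracle_optimize <- function(table, train_batch, grid, compound) {
  tab <- table[table$compound_id == compound, ]
  train <- tab[tab$batch_id == train_batch, ]
  qc <- train[train$sample_class == "qc" & !is.na(train$peak_area), ]
  best <- NULL
  for (k in grid$test_breaks) for (w in grid$test_window) {
    tis <- if (is.null(grid$test_index)) 0:(w - 1) else
      grid$test_index[grid$test_index < w]
    for (ti in tis) for (qi in grid$quantile_increment) {
      p <- pseudoqc_params(qi, k, w, ti)
      aug <- tryCatch(
        suppressWarnings(estimate_pseudoqc(peak_table(as.data.frame(tab)), p, compound)),
        error = function(e) NULL)
      if (is.null(aug)) next
      anch <- aug[aug$sample_class == "pseudoqc" & aug$batch_id == train_batch, ]
      pred <- stats::approx(anch$injection_order, anch$peak_area,
                            xout = qc$injection_order, rule = 2, ties = mean)$y
      mse <- mean((pred - qc$peak_area)^2)
      if (is.null(best) || mse < best$mse) {
        best <- list(qi = qi, k = k, w = w, ti = ti, mse = mse)
      }
    }
  }
  best
}
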