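#' Outlier detection reports
#'
#' All three detectors ([pw_outlier()], [iqr_outlier()],
#' [grubbs_iterative()]) return an `outlier_report`: a list with
#' `flagged` (a `data.frame` of flagged observations with their score),
#' `thresholds` (one row per compound x group with the cutoff used),
#' and the method parameters.  Reports are advisory: no observation is
#' removed — omitting flagged rows is an explicit downstream choice.
#'
#' @name outlier_report
NULL

new_outlier_report <- function(flagged, thresholds, method, ...) {
  structure(list(flagged = flagged, thresholds = thresholds,
                 method = method, ...),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> method=%s, %d observation(s) flagged\n",
              x$method, nrow(x$flagged)))
  invisible(x)
}

empty_flags <- function() {
  data.frame(sample_id = character(), replicate_id = character(),
             batch_id = character(), compound_id = character(),
             peak_area = numeric(), score = numeric(),
             threshold = numeric(), stringsAsFactors = FALSE)
}

## experimental records with non-missing areas, split by compound then group
split_experimental <- function(table, group_by) {
  stopifnot(group_by %in% names(table))
  x <- table[table$sample_class == "experimental" & !is.na(table$peak_area), ,
             drop = FALSE]
  split(x, list(x$compound_id, x[[group_by]]), drop = TRUE, sep = "\r")
}

#' Replicate-pairwise outlier detection
#'
#' For each compound and group (default: batch), computes all pairwise
#' absolute differences between replicate measurements of the same sample
#' (`|rep1-rep2|`, `|rep1-rep3|`, `|rep2-rep3|` for triplets) and pools
#' them into one distribution per group.  Differences exceeding the
#' empirical `quantile` of that distribution mark their pair as suspect;
#' within a suspect pair the replicate lying farther from the sample's
#' replicate median is flagged (both replicates on an exact tie).  For
#' two-replicate samples, the member farther from the group-level median
#' is flagged.  QC and blank records are never flagged.
#'
#' Unlike distribution-wide methods (IQR fences, Grubbs), this detector
#' works at the level of the experimental unit, so replicate-consistent
#' extreme samples — potential biological anomalies — are not flagged.
#'
#' @param table A [peak_table()].
#' @param quantile Upper-tail quantile threshold on pooled pairwise
#'   differences (default 0.95; linear-interpolation empirical quantile).
#' @param group_by Grouping column for pooling (default `"batch_id"`).
#' @return An [outlier_report] whose flagged-score column is the largest
#'   pairwise difference involving the flagged replicate.
#' @export
pw_outlier <- function(table, quantile = 0.95, group_by = "batch_id") {
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  groups <- split_experimental(table, group_by)
  flags <- list()
  thr <- list()
  any_replicates <- FALSE
  for (gname in names(groups)) {
    g <- groups[[gname]]
    by_sample <- split(g, g$sample_id)
    by_sample <- Filter(function(s) nrow(s) >= 2L, by_sample)
    if (!length(by_sample)) next
    any_replicates <- TRUE

    pair_rows <- lapply(by_sample, function(s) {
      idx <- utils::combn(nrow(s), 2L)
      data.frame(sample_id = s$sample_id[1],
                 i = idx[1, ], j = idx[2, ],
                 diff = abs(s$peak_area[idx[1, ]] - s$peak_area[idx[2, ]]),
                 stringsAsFactors = FALSE)
    })
    diffs <- unlist(lapply(pair_rows, `[[`, "diff"), use.names = FALSE)
    cutoff <- stats::quantile(diffs, quantile, names = FALSE, type = 7)
    thr[[gname]] <- data.frame(
      compound_id = g$compound_id[1], group = g[[group_by]][1],
      threshold = cutoff, n_pairs = length(diffs), stringsAsFactors = FALSE)

    group_median <- stats::median(g$peak_area)
    for (s_id in names(pair_rows)) {
      s <- by_sample[[s_id]]
      pr <- pair_rows[[s_id]]
      exceed <- pr[pr$diff > cutoff, , drop = FALSE]
      if (!nrow(exceed)) next
      center <- if (nrow(s) >= 3L) stats::median(s$peak_area) else group_median
      for (r in seq_len(nrow(exceed))) {
        ii <- exceed$i[r]; jj <- exceed$j[r]
        di <- abs(s$peak_area[ii] - center)
        dj <- abs(s$peak_area[jj] - center)
        pick <- if (di > dj) ii else if (dj > di) jj else c(ii, jj)
        for (p in pick) {
          flags[[length(flags) + 1L]] <- data.frame(
            sample_id = s$sample_id[p], replicate_id = s$replicate_id[p],
            batch_id = s$batch_id[p], compound_id = s$compound_id[p],
            peak_area = s$peak_area[p], score = exceed$diff[r],
            threshold = cutoff, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!any_replicates) {
    warning("no sample has two or more replicate measurements; empty report",
            call. = FALSE)
  }
  flagged <- if (length(flags)) do.call(rbind, flags) else empty_flags()
  if (nrow(flagged)) {
    key <- paste(flagged$sample_id, flagged$replicate_id, flagged$batch_id,
                 flagged$compound_id, sep = "\r")
    ord <- order(key, -flagged$score)
    flagged <- flagged[ord, , drop = FALSE]
    flagged <- flagged[!duplicated(key[ord]), , drop = FALSE]
    rownames(flagged) <- NULL
  }
  thresholds <- if (length(thr)) do.call(rbind, thr) else
    data.frame(compound_id = character(), group = character(),
               threshold = numeric(), n_pairs = integer())
  rownames(thresholds) <- NULL
  new_outlier_report(flagged, thresholds, "pairwise",
                     quantile = quantile, group_by = group_by)
}

#' Tukey fence (k x IQR) outlier detection
#'
#' Per compound and group, flags experimental observations outside
#' `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles from the
#' linear-interpolation empirical quantile.
#'
#' @param table A [peak_table()].
#' @param k Fence multiplier (default 1.5).
#' @param group_by Grouping column (default `"batch_id"`).
#' @return An [outlier_report]; score is the distance beyond the nearer
#'   fence, threshold the exceeded fence.
#' @export
iqr_outlier <- function(table, k = 1.5, group_by = "batch_id") {
  groups <- split_experimental(table, group_by)
  flags <- list(); thr <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (nrow(g) < 4L) {
      warning("group ", gsub("\r", "/", gname),
              " has fewer than 4 observations; skipped", call. = FALSE)
      next
    }
    q <- stats::quantile(g$peak_area, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    thr[[gname]] <- data.frame(
      compound_id = g$compound_id[1], group = g[[group_by]][1],
      lower = lo, upper = hi, stringsAsFactors = FALSE)
    out <- g$peak_area < lo | g$peak_area > hi
    if (any(out)) {
      o <- g[out, , drop = FALSE]
      flags[[gname]] <- data.frame(
        sample_id = o$sample_id, replicate_id = o$replicate_id,
        batch_id = o$batch_id, compound_id = o$compound_id,
        peak_area = o$peak_area,
        score = pmax(lo - o$peak_area, o$peak_area - hi),
        threshold = ifelse(o$peak_area > hi, hi, lo),
        stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(flags)) do.call(rbind, flags) else empty_flags()
  rownames(flagged) <- NULL
  thresholds <- if (length(thr)) do.call(rbind, thr) else
    data.frame(compound_id = character(), group = character(),
               lower = numeric(), upper = numeric())
  rownames(thresholds) <- NULL
  new_outlier_report(flagged, thresholds, "iqr", k = k, group_by = group_by)
}

## Two-sided Grubbs critical value at significance alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier detection
#'
#' Per compound and group, repeatedly applies the two-sided Grubbs test:
#' the statistic `G = max |x_i - mean(x)| / sd(x)` is compared with the
#' t-distribution-based critical value at level `alpha`; if it exceeds,
#' the extreme observation is flagged and removed, and the test repeats on
#' the remainder until no rejection or fewer than 3 observations remain.
#' Groups with zero standard deviation are not tested.
#'
#' @param table A [peak_table()].
#' @param alpha Type-I error rate (default 0.05).
#' @param group_by Grouping column (default `"batch_id"`).
#' @return An [outlier_report]; score is the Grubbs statistic, threshold
#'   the critical value at the step the observation was removed.
#' @export
grubbs_iterative <- function(table, alpha = 0.05, group_by = "batch_id") {
  groups <- split_experimental(table, group_by)
  flags <- list(); thr <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (nrow(g) < 3L) {
      warning("group ", gsub("\r", "/", gname),
              " has fewer than 3 observations; skipped", call. = FALSE)
      next
    }
    keep <- rep(TRUE, nrow(g))
    last_crit <- NA_real_
    repeat {
      x <- g$peak_area[keep]
      n <- length(x)
      if (n < 3L) break
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) break
      dev <- abs(x - mean(x))
      i_rel <- which.max(dev)
      G <- dev[i_rel] / s
      crit <- grubbs_critical(n, alpha)
      last_crit <- crit
      if (G <= crit) break
      i_abs <- which(keep)[i_rel]
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = g$sample_id[i_abs], replicate_id = g$replicate_id[i_abs],
        batch_id = g$batch_id[i_abs], compound_id = g$compound_id[i_abs],
        peak_area = g$peak_area[i_abs], score = G, threshold = crit,
        stringsAsFactors = FALSE)
      keep[i_abs] <- FALSE
    }
    thr[[gname]] <- data.frame(
      compound_id = g$compound_id[1], group = g[[group_by]][1],
      critical_value = last_crit, stringsAsFactors = FALSE)
  }
  flagged <- if (length(flags)) do.call(rbind, flags) else empty_flags()
  rownames(flagged) <- NULL
  thresholds <- if (length(thr)) do.call(rbind, thr) else
    data.frame(compound_id = character(), group = character(),
               critical_value = numeric())
  rownames(thresholds) <- NULL
  new_outlier_report(flagged, thresholds, "grubbs",
                     alpha = alpha, group_by = group_by)
}
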