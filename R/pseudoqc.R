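#' PseudoQC estimation parameters
#'
#' The four parameters controlling how pseudoQC anchor points are computed
#' from experimental-sample variability:
#' * `quantile_increment` — half-width of the quantile band trimmed off
#'   each end within a segment; observations outside
#'   `[quantile_increment, 1 - quantile_increment]` of the segment's
#'   empirical distribution are discarded before trend estimation;
#' * `test_breaks` — number of contiguous, (near-)equally sized
#'   injection-order segments each batch is divided into; one pseudoQC
#'   anchor is produced per segment;
#' * `test_window` — length (in retained observations) of the centered
#'   rolling median evaluated within each segment;
#' * `test_index` — 0-based positional offset selecting which rolling
#'   median entry becomes the segment's anchor.
#'
#' @param quantile_increment Real in `[0, 0.5)`.
#' @param test_breaks Positive integer.
#' @param test_window Positive odd integer.
#' @param test_index Non-negative integer `< test_window` selecting the
#'   anchor position within the rolling-median sequence.
#' @param criterion_value Training mean squared error attained by these
#'   parameters (filled in by [optimize_params()]).
#' @return An object of class `pseudoqc_params`.
#' @export
pseudoqc_params <- function(quantile_increment, test_breaks, test_window,
                            test_index, criterion_value = NA_real_) {
  if (quantile_increment < 0 || quantile_increment >= 0.5) {
    stop("quantile_increment must lie in [0, 0.5)", call. = FALSE)
  }
  test_breaks <- as.integer(test_breaks)
  test_window <- as.integer(test_window)
  test_index <- as.integer(test_index)
  if (test_breaks < 1L) stop("test_breaks must be positive", call. = FALSE)
  if (test_window < 1L || test_window %% 2L == 0L) {
    stop("test_window must be a positive odd integer", call. = FALSE)
  }
  if (test_index < 0L) stop("test_index must be non-negative", call. = FALSE)
  structure(list(quantile_increment = quantile_increment,
                 test_breaks = test_breaks, test_window = test_window,
                 test_index = test_index, criterion_value = criterion_value),
            class = "pseudoqc_params")
}

#' @export
print.pseudoqc_params <- function(x, ...) {
  cat(sprintf(paste0("<pseudoqc_params> quantile_increment=%.3g, test_breaks=%d, ",
                     "test_window=%d, test_index=%d (training MSE %.6g)\n"),
              x$quantile_increment, x$test_breaks, x$test_window,
              x$test_index, x$criterion_value))
  invisible(x)
}

#' Candidate grid for pseudoQC parameter optimization
#'
#' @param quantile_increment Candidate trim half-widths.
#' @param test_breaks Candidate segment counts.
#' @param test_window Candidate rolling-median windows (odd).
#' @param test_index Candidate anchor offsets, or `NULL` (default) for all
#'   offsets `0 ... window - 1` per window.
#' @param criterion Optimization criterion; only `"mse"` is implemented.
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(quantile_increment = c(0, 0.05, 0.1, 0.15, 0.2, 0.25),
                       test_breaks = 2:8,
                       test_window = c(3L, 5L, 7L, 9L, 11L),
                       test_index = NULL,
                       criterion = "mse") {
  criterion <- match.arg(criterion)
  if (!length(quantile_increment) || !length(test_breaks) || !length(test_window)) {
    stop("all candidate lists must be non-empty", call. = FALSE)
  }
  structure(list(quantile_increment = sort(unique(as.numeric(quantile_increment))),
                 test_breaks = sort(unique(as.integer(test_breaks))),
                 test_window = sort(unique(as.integer(test_window))),
                 test_index = if (is.null(test_index)) NULL else
                   sort(unique(as.integer(test_index))),
                 criterion = criterion),
            class = "param_grid")
}

## Contiguous segment sizes: remainder spread over leading segments.
segment_sizes <- function(m, k) {
  base <- m %/% k
  sizes <- rep(base, k)
  extra <- m %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

## PseudoQC anchors for one batch of one compound.  `x` is a data.frame of
## experimental records ordered by injection_order.  Returns a data.frame of
## anchors (injection_order, peak_area) or stops with a feasibility error.
batch_pseudoqc_anchors <- function(x, params, batch_id) {
  m <- nrow(x)
  k <- params$test_breaks
  w <- params$test_window
  if (m < k * w) {
    stop("batch ", batch_id, ": ", m, " experimental observations cannot fill ",
         k, " segments of window ", w, call. = FALSE)
  }
  sizes <- segment_sizes(m, k)
  bounds <- c(0L, cumsum(sizes))
  anchors <- vector("list", k)
  for (s in seq_len(k)) {
    seg <- x[(bounds[s] + 1L):bounds[s + 1L], , drop = FALSE]
    qi <- params$quantile_increment
    if (qi > 0) {
      band <- stats::quantile(seg$peak_area, c(qi, 1 - qi), names = FALSE, type = 7)
      keep <- seg$peak_area >= band[1] & seg$peak_area <= band[2]
      seg <- seg[keep, , drop = FALSE]
    }
    if (nrow(seg) < w) {
      stop("batch ", batch_id, ", segment ", s, ": only ", nrow(seg),
           " observations retained after quantile trimming; window is ", w,
           call. = FALSE)
    }
    rm_seq <- zoo::rollmedian(seg$peak_area, w, align = "center")
    idx <- params$test_index + 1L
    if (idx > length(rm_seq)) {
      stop("batch ", batch_id, ", segment ", s, ": test_index ",
           params$test_index, " exceeds rolling-median length ",
           length(rm_seq), call. = FALSE)
    }
    center <- params$test_index + (w + 1L) %/% 2L
    anchors[[s]] <- data.frame(
      injection_order = seg$injection_order[center],
      peak_area = rm_seq[idx], segment = s, stringsAsFactors = FALSE)
  }
  do.call(rbind, anchors)
}

#' Estimate pseudoQC anchor points in every batch
#'
#' For each batch, the experimental observations of `compound` are ordered
#' by injection, split into `test_breaks` contiguous segments, trimmed to
#' the central quantile band, and summarized by a centered rolling median;
#' the rolling-median entry at offset `test_index` becomes the segment's
#' pseudoQC anchor, positioned at the injection order of its window center.
#' QC and blank records never enter the estimation.  One `pseudoqc` record
#' per segment is appended to the table.
#'
#' @param table A [peak_table()].
#' @param params A [pseudoqc_params()].
#' @param compound Compound id to process.
#' @return The input table augmented with `sample_class == "pseudoqc"` rows
#'   (`test_breaks` per batch).
#' @export
estimate_pseudoqc <- function(table, params, compound) {
  stopifnot(inherits(params, "pseudoqc_params"))
  if (!compound %in% table$compound_id) {
    stop("compound '", compound, "' not present in table", call. = FALSE)
  }
  tab <- table[table$compound_id == compound, , drop = FALSE]
  exp_tab <- tab[tab$sample_class == "experimental" & !is.na(tab$peak_area), ,
                 drop = FALSE]
  rows <- list()
  for (b in batches(tab)) {
    x <- exp_tab[exp_tab$batch_id == b, , drop = FALSE]
    x <- x[order(x$injection_order), , drop = FALSE]
    if (nrow(x) < 24L) {
      warning("batch ", b, " has only ", nrow(x), " experimental observations; ",
              "pseudoQC estimates from small batches are unreliable",
              call. = FALSE)
    }
    anch <- batch_pseudoqc_anchors(x, params, b)
    rows[[b]] <- data.frame(
      sample_id = sprintf("pseudoQC_%s_%02d", b, anch$segment),
      replicate_id = "1", batch_id = b, sub_batch_id = NA_character_,
      injection_order = anch$injection_order, compound_id = compound,
      sample_class = "pseudoqc", peak_area = anch$peak_area,
      sample_weight = NA_real_, stringsAsFactors = FALSE)
  }
  out <- rbind(as.data.frame(table)[table$compound_id == compound, ],
               do.call(rbind, rows))
  other <- as.data.frame(table)[table$compound_id != compound, , drop = FALSE]
  if (nrow(other)) out <- rbind(other, out)
  peak_table(out)
}

## Interpolate anchor values (value vs injection order) to target positions:
## linear inside the anchor range, constant beyond the first/last anchor.
interp_anchors <- function(anchor_x, anchor_y, xout) {
  if (length(anchor_x) == 1L) return(rep(anchor_y, length(xout)))
  stats::approx(anchor_x, anchor_y, xout = xout, rule = 2, ties = mean)$y
}

## Minimum retained segment size over all batches for a given
## (test_breaks, quantile_increment): determines which (window, index)
## combinations are transferable to every batch.
min_retained_segment <- function(batch_areas, k, qi) {
  min(vapply(batch_areas, function(x) {
    sizes <- segment_sizes(length(x), k)
    bounds <- c(0L, cumsum(sizes))
    min(vapply(seq_len(k), function(s) {
      seg <- x[(bounds[s] + 1L):bounds[s + 1L]]
      if (qi > 0) {
        band <- stats::quantile(seg, c(qi, 1 - qi), names = FALSE, type = 7)
        sum(seg >= band[1] & seg <= band[2])
      } else {
        length(seg)
      }
    }, integer(1)))
  }, integer(1)))
}

#' Grid-optimize pseudoQC parameters on a training batch
#'
#' Runs [estimate_pseudoqc()] on the training batch for every combination
#' in the grid, linearly interpolates the resulting anchors to the
#' injection positions of the batch's true QC samples, and scores the
#' combination by the mean squared error (MSE) against the observed QC
#' areas.  The minimal-MSE combination is returned, with exact ties broken
#' toward smaller `test_breaks`, then smaller `test_window`, smaller
#' `test_index`, and smaller `quantile_increment`.
#'
#' Because the optimized parameters are transferred to the remaining
#' batches, only combinations feasible in *every* batch of `table` are
#' considered: a combination is skipped when, in any batch, a segment
#' retains fewer observations than the window after quantile trimming or
#' the offset runs past the rolling-median sequence.  To optimize without
#' the transfer constraint, pass only the training batch's rows.
#'
#' @param table A [peak_table()] containing QC records in `train_batch`.
#' @param train_batch Batch id to train on (normally the batch where true
#'   QCs are most represented).
#' @param grid A [param_grid()].
#' @param compound Compound id.
#' @return A [pseudoqc_params()] with `criterion_value` set to the
#'   training MSE.
#' @export
optimize_params <- function(table, train_batch, grid = param_grid(), compound) {
  stopifnot(inherits(grid, "param_grid"))
  tab <- table[table$compound_id == compound, , drop = FALSE]
  if (!nrow(tab)) stop("compound '", compound, "' not present", call. = FALSE)
  train <- tab[tab$batch_id == train_batch, , drop = FALSE]
  if (!nrow(train)) stop("training batch '", train_batch, "' not present",
                         call. = FALSE)
  qc <- train[train$sample_class == "qc" & !is.na(train$peak_area), , drop = FALSE]
  if (nrow(qc) < 2L) {
    stop("training batch must contain at least 2 trueQC records for '",
         compound, "'", call. = FALSE)
  }
  x <- train[train$sample_class == "experimental" & !is.na(train$peak_area), ,
             drop = FALSE]
  x <- x[order(x$injection_order), , drop = FALSE]
  if (nrow(x) < 24L) {
    warning("training batch has only ", nrow(x), " experimental observations; ",
            "optimized parameters may not transfer well", call. = FALSE)
  }

  exp_all <- tab[tab$sample_class == "experimental" & !is.na(tab$peak_area), ,
                 drop = FALSE]
  exp_all <- exp_all[order(exp_all$batch_id, exp_all$injection_order), ,
                     drop = FALSE]
  batch_areas <- split(exp_all$peak_area, exp_all$batch_id)

  combos <- grid_search_mse(x, qc, grid, batch_areas)
  if (!nrow(combos)) {
    stop("no feasible parameter combination for training batch '",
         train_batch, "'", call. = FALSE)
  }
  ## tie-break order: breaks, then window, then index, then increment
  combos <- combos[order(combos$test_breaks, combos$test_window,
                         combos$test_index, combos$quantile_increment), ,
                   drop = FALSE]
  best <- combos[which.min(combos$mse), , drop = FALSE]  # first min wins ties
  pseudoqc_params(best$quantile_increment, best$test_breaks,
                  best$test_window, best$test_index,
                  criterion_value = best$mse)
}

## MSE of every transfer-feasible grid combination on the training batch.
## Trimmed segments and rolling medians are shared across test_index values;
## the anchors produced are identical to batch_pseudoqc_anchors().
grid_search_mse <- function(x, qc, grid, batch_areas) {
  rows <- list()
  m <- nrow(x)
  for (k in grid$test_breaks) {
    if (m < k * min(grid$test_window)) next
    s_min <- vapply(grid$quantile_increment, function(qi) {
      min_retained_segment(batch_areas, k, qi)
    }, numeric(1))
    sizes <- segment_sizes(m, k)
    bounds <- c(0L, cumsum(sizes))
    for (qi_i in seq_along(grid$quantile_increment)) {
      qi <- grid$quantile_increment[qi_i]
      segs <- lapply(seq_len(k), function(s) {
        seg <- x[(bounds[s] + 1L):bounds[s + 1L], , drop = FALSE]
        if (qi > 0) {
          band <- stats::quantile(seg$peak_area, c(qi, 1 - qi),
                                  names = FALSE, type = 7)
          seg <- seg[seg$peak_area >= band[1] & seg$peak_area <= band[2], ,
                     drop = FALSE]
        }
        seg
      })
      for (w in grid$test_window) {
        if (w > s_min[qi_i]) next
        rms <- lapply(segs, function(seg) {
          if (nrow(seg) < w) NULL else
            zoo::rollmedian(seg$peak_area, w, align = "center")
        })
        if (any(vapply(rms, is.null, logical(1)))) next
        idx_all <- if (is.null(grid$test_index)) 0:(w - 1L) else
          grid$test_index[grid$test_index < w]
        idx_all <- idx_all[idx_all <= s_min[qi_i] - w]
        for (ti in idx_all) {
          if (any(vapply(rms, length, integer(1)) < ti + 1L)) next
          center <- ti + (w + 1L) %/% 2L
          if (any(vapply(segs, nrow, integer(1)) < center)) next
          anchor_x <- vapply(seq_len(k), function(s) {
            segs[[s]]$injection_order[center]
          }, numeric(1))
          anchor_y <- vapply(rms, `[[`, numeric(1), ti + 1L)
          pred <- interp_anchors(anchor_x, anchor_y, qc$injection_order)
          rows[[length(rows) + 1L]] <- data.frame(
            quantile_increment = qi, test_breaks = k, test_window = w,
            test_index = ti, mse = mean((pred - qc$peak_area)^2))
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(quantile_increment = numeric(), test_breaks = integer(),
               test_window = integer(), test_index = integer(),
               mse = numeric())
}
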