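#' Correction results
#'
#' [qcrsc_correct()] and [pseudo_sdc()] return a `correction_result`:
#' * `corrected` — the input records (pseudoQC anchor rows excluded) with
#'   drift- and batch-corrected peak areas;
#' * `augmented` — the uncorrected input plus any pseudoQC anchor rows, so
#'   the anchors can be exported to other correction tools;
#' * `anchors_used` — `"trueqc"` or `"pseudoqc"`;
#' * `per_batch_trend` — one `data.frame` per batch sampling the fitted
#'   multiplicative trend over injection order;
#' * `params` — the [pseudoqc_params()] used, when applicable.
#'
#' @name correction_result
NULL

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> anchors=%s, %d corrected record(s), %d batch(es)\n",
              x$anchors_used, nrow(x$corrected), length(x$per_batch_trend)))
  invisible(x)
}

## Leave-one-out cross-validated smoothing parameter for smooth.spline on
## (x, y).  Fixed spar grid; ties go to the heaviest smoothing.  Falls back
## to the heaviest spar when refits are infeasible (n - 1 < 4).
select_spar <- function(x, y, spar_grid = seq(0.1, 1.5, by = 0.1)) {
  n <- length(x)
  if (n - 1L < 4L) return(max(spar_grid))
  best_spar <- max(spar_grid)
  best_sse <- Inf
  for (spar in rev(spar_grid)) {     # heavy smoothing first => wins ties
    sse <- 0
    ok <- TRUE
    for (i in seq_len(n)) {
      fit <- tryCatch(
        stats::smooth.spline(x[-i], y[-i], spar = spar, cv = NA),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- stats::predict(fit, x[i])$y
      sse <- sse + (y[i] - pred)^2
    }
    if (ok && sse < best_sse) {
      best_sse <- sse
      best_spar <- spar
    }
  }
  best_spar
}

## Fit the log-trend for one batch from anchor points.  Returns a function
## s(injection) giving the fitted log area, or NULL when < 2 anchors.
fit_log_trend <- function(inj, log_area) {
  n <- length(inj)
  if (n >= 4L) {
    spar <- select_spar(inj, log_area)
    fit <- stats::smooth.spline(inj, log_area, spar = spar, cv = NA)
    function(x) stats::predict(fit, x)$y
  } else if (n >= 2L) {
    cf <- stats::coef(stats::lm(log_area ~ inj))
    function(x) cf[1] + cf[2] * x
  } else {
    NULL
  }
}

#' QC-robust smoothing-spline drift and batch correction
#'
#' Per batch, a cubic smoothing spline is fitted to the log peak areas of
#' the anchor samples (true QCs or pseudoQC estimates) against injection
#' order, with the smoothing parameter chosen by leave-one-out
#' cross-validation over a fixed grid (ties toward heavier smoothing).
#' Every record in the batch is corrected multiplicatively,
#' `area * exp(m_b - s(injection))`, where `s` is the fitted log-trend and
#' `m_b` the batch's anchor log-median, so a flat anchor series leaves the
#' data untouched.  With `align = "median"` the corrected batches are
#' subsequently rescaled so their anchor medians agree with the pooled
#' anchor median, removing between-batch level shifts.
#'
#' Batches with fewer than 4 positive anchors fall back to a linear
#' log-trend (2-3 anchors) or, with fewer than 2, to median alignment only,
#' with a warning.  Non-positive anchor areas are excluded from the fit
#' with a warning.
#'
#' @param table A [peak_table()]; for `anchors = "pseudoqc"` it must
#'   already contain pseudoQC rows (see [estimate_pseudoqc()]).
#' @param anchors `"trueqc"` or `"pseudoqc"`.
#' @param compound Compound id to correct.
#' @param align `"median"` (default) to align batch levels, or `"none"`.
#' @param params Optional [pseudoqc_params()] recorded in the result.
#' @return A [correction_result].
#' @export
qcrsc_correct <- function(table, anchors = c("trueqc", "pseudoqc"), compound,
                          align = c("median", "none"), params = NULL) {
  anchors <- match.arg(anchors)
  align <- match.arg(align)
  anchor_class <- if (anchors == "trueqc") "qc" else "pseudoqc"
  tab <- table[table$compound_id == compound, , drop = FALSE]
  if (!nrow(tab)) stop("compound '", compound, "' not present", call. = FALSE)

  corrected <- as.data.frame(tab)[tab$sample_class != "pseudoqc", , drop = FALSE]
  trend <- list()
  batch_anchor_median <- numeric(0)
  for (b in batches(tab)) {
    sel_b <- corrected$batch_id == b
    a <- tab[tab$batch_id == b & tab$sample_class == anchor_class &
               !is.na(tab$peak_area), , drop = FALSE]
    if (any(a$peak_area <= 0)) {
      warning("batch ", b, ": ", sum(a$peak_area <= 0),
              " non-positive anchor area(s) excluded from the trend fit",
              call. = FALSE)
      a <- a[a$peak_area > 0, , drop = FALSE]
    }
    if (nrow(a) < 2L) {
      warning("batch ", b, " has fewer than 2 usable '", anchor_class,
              "' anchors; applying median alignment only", call. = FALSE)
    }
    a <- a[order(a$injection_order), , drop = FALSE]
    s_fun <- fit_log_trend(a$injection_order, log(a$peak_area))
    inj_b <- corrected$injection_order[sel_b]
    if (!is.null(s_fun)) {
      m_b <- stats::median(log(a$peak_area))
      log_corr <- m_b - s_fun(inj_b)
      corrected$peak_area[sel_b] <- corrected$peak_area[sel_b] * exp(log_corr)
      grid_x <- sort(unique(inj_b))
      trend[[b]] <- data.frame(batch_id = b, injection_order = grid_x,
                               trend_factor = exp(s_fun(grid_x) - m_b),
                               stringsAsFactors = FALSE)
    } else {
      trend[[b]] <- data.frame(batch_id = b,
                               injection_order = sort(unique(inj_b)),
                               trend_factor = 1, stringsAsFactors = FALSE)
    }
    ## anchor medians recomputed on the post-correction scale for alignment
    if (nrow(a)) {
      a_corr <- if (is.null(s_fun)) a$peak_area else
        a$peak_area * exp(stats::median(log(a$peak_area)) - s_fun(a$injection_order))
      batch_anchor_median[b] <- stats::median(a_corr)
    } else {
      batch_anchor_median[b] <- NA_real_
    }
  }

  if (align == "median") {
    usable <- !is.na(batch_anchor_median)
    if (any(usable)) {
      global_med <- stats::median(batch_anchor_median[usable])
      for (b in names(batch_anchor_median)[usable]) {
        sel_b <- corrected$batch_id == b
        corrected$peak_area[sel_b] <-
          corrected$peak_area[sel_b] * global_med / batch_anchor_median[b]
      }
    }
  }

  bad <- !is.na(corrected$peak_area) & corrected$peak_area <= 0
  if (any(bad)) {
    warning(sum(bad), " corrected area(s) were non-positive and set to NA",
            call. = FALSE)
    corrected$peak_area[bad] <- NA_real_
  }

  structure(
    list(corrected = peak_table(corrected),
         augmented = peak_table(as.data.frame(tab)),
         anchors_used = anchors, per_batch_trend = trend, params = params),
    class = "correction_result"
  )
}

#' Train/test pseudoQC estimation and drift correction
#'
#' The full workflow for data with partial QC coverage: the four pseudoQC
#' parameters are grid-optimized against the true QC samples of
#' `train_batch` ([optimize_params()]), the optimized parameters are
#' applied to estimate pseudoQC anchors in every batch
#' ([estimate_pseudoqc()]), and the QC-robust spline correction is run with
#' those anchors ([qcrsc_correct()]).  The uncorrected table augmented with
#' the pseudoQC rows is returned alongside the corrected data so that
#' alternative correction methods can be applied to the anchors.
#'
#' @param table A [peak_table()] with true QC records in `train_batch`.
#' @param train_batch Batch id to optimize on.
#' @param grid A [param_grid()].
#' @param compound Compound id; defaults to the single compound present.
#' @param align Batch alignment mode passed to [qcrsc_correct()].
#' @return A [correction_result] with `params` set.
#' @export
pseudo_sdc <- function(table, train_batch, grid = param_grid(), compound = NULL,
                       align = "median") {
  if (is.null(compound)) {
    cmp <- compounds(table)
    if (length(cmp) != 1L) {
      stop("table holds ", length(cmp),
           " compounds; supply `compound` explicitly", call. = FALSE)
    }
    compound <- cmp
  }
  params <- optimize_params(table, train_batch, grid, compound)
  augmented <- estimate_pseudoqc(table, params, compound)
  qcrsc_correct(augmented, anchors = "pseudoqc", compound = compound,
                align = align, params = params)
}

#' Per-batch location-scale baseline correction
#'
#' A deliberately simple comparison baseline: per batch, log areas are
#' centered and scaled to the compound's global log mean and standard
#' deviation.  It removes between-batch level/scale differences but leaves
#' intra-batch drift untouched, which is what distinguishes it from
#' [qcrsc_correct()] in comparison plots.
#'
#' @param table A [peak_table()].
#' @param compound Compound id.
#' @return A corrected [peak_table()].
#' @export
location_scale_batch_correct <- function(table, compound) {
  tab <- as.data.frame(table)[table$compound_id == compound, , drop = FALSE]
  if (!nrow(tab)) stop("compound '", compound, "' not present", call. = FALSE)
  if (length(unique(tab$batch_id)) < 2L) {
    warning("single batch: location-scale correction is the identity",
            call. = FALSE)
    return(peak_table(tab))
  }
  usable <- !is.na(tab$peak_area) & tab$peak_area > 0 &
    tab$sample_class %in% c("experimental", "qc")
  lx <- log(tab$peak_area[usable])
  g_mean <- mean(lx)
  ## scale reference is the pooled *within*-batch sd, so that equalizing
  ## batch levels does not inflate each batch by the between-batch spread
  b_sds <- tapply(lx, tab$batch_id[usable], stats::sd)
  g_sd <- sqrt(mean(b_sds[is.finite(b_sds)]^2))
  for (b in unique(tab$batch_id)) {
    sel <- usable & tab$batch_id == b
    bx <- log(tab$peak_area[sel])
    b_sd <- stats::sd(bx)
    z <- if (is.finite(b_sd) && b_sd > 0) (bx - mean(bx)) / b_sd else bx - mean(bx)
    tab$peak_area[sel] <- exp(g_mean + z * g_sd)
  }
  peak_table(tab)
}
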