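#' Simulation scenario for drift and batch effects
#'
#' Describes an LC-MS run-sequence scenario: how many injections per batch,
#' how often a pooled QC sample is injected, the severity of signal-drift
#' and batch effects, and the noise levels of the lognormal error model.
#'
#' @param batch_sizes Integer vector, injections per batch (QCs included).
#' @param qc_every Every `qc_every`-th injection within a batch is a pooled
#'   QC sample (default 25).
#' @param slope_magnitude Severity of intra-batch monotone drift: the
#'   maximal fold change reached at the end of a batch (default 1.25;
#'   1 means no drift).
#' @param batch_magnitude Severity of between-batch level shifts: batch
#'   factors are drawn from `[1/batch_magnitude, batch_magnitude]`
#'   (default 1.25; 1 means no shift).
#' @param replicate_group_size Number of consecutive replicate injections
#'   sharing one biological sample (default 3).
#' @param biological_cv Lognormal coefficient of variation of biological
#'   levels across samples (default 0.10).
#' @param technical_cv Lognormal CV between replicate injections of the same
#'   sample (default 0.12).
#' @param qc_cv Lognormal CV of repeated QC injections (default 0.15).
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @return An object of class `drift_config`.
#' @export
drift_config <- function(batch_sizes = c(100L, 200L, 300L),
                         qc_every = 25L,
                         slope_magnitude = 1.25,
                         batch_magnitude = 1.25,
                         replicate_group_size = 3L,
                         biological_cv = 0.10,
                         technical_cv = 0.12,
                         qc_cv = 0.15,
                         seed = 1L) {
  batch_sizes <- as.integer(batch_sizes)
  qc_every <- as.integer(qc_every)
  if (!length(batch_sizes) || any(batch_sizes < 1L)) {
    stop("batch_sizes must be positive integers", call. = FALSE)
  }
  if (qc_every < 2L) stop("qc_every must be at least 2", call. = FALSE)
  if (any(batch_sizes < qc_every)) {
    stop("every batch must hold at least qc_every injections", call. = FALSE)
  }
  if (slope_magnitude < 1 || batch_magnitude < 1) {
    stop("slope_magnitude and batch_magnitude must be >= 1", call. = FALSE)
  }
  for (cv in c(biological_cv, technical_cv, qc_cv)) {
    if (cv < 0 || cv >= 1) stop("coefficients of variation must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(batch_sizes = batch_sizes, qc_every = qc_every,
         slope_magnitude = slope_magnitude, batch_magnitude = batch_magnitude,
         replicate_group_size = as.integer(replicate_group_size),
         biological_cv = biological_cv, technical_cv = technical_cv,
         qc_cv = qc_cv, seed = as.integer(seed)),
    class = "drift_config"
  )
}

## Derived sub-seeds keep the control draw and each effect's draw on
## independent, reproducible streams so that apply_effect() is deterministic
## regardless of call order.  Offsets stay well below 2^31.
sub_seed <- function(config, offset) {
  (abs(config$seed) %% 2000000000L) + offset
}

#' Simulate a drift-free peak table for one compound
#'
#' Builds the run sequence batch by batch: every `qc_every`-th injection is
#' a pooled QC at the compound's reference intensity, and the remaining
#' injections are consecutive replicate groups (default triplets) of
#' experimental samples.  Noise is lognormal: each sample draws one
#' biological level, each replicate injection a technical factor, and each
#' QC injection a QC factor.
#'
#' @param meta A [compound_meta()].
#' @param config A [drift_config()].
#' @return A [peak_table()] with `sum(batch_sizes)` records.
#' @export
simulate_control <- function(meta, config) {
  stopifnot(inherits(meta, "compound_meta"), inherits(config, "drift_config"))
  set.seed(sub_seed(config, 0L))
  ref <- meta$reference_intensity
  rows <- vector("list", length(config$batch_sizes))
  for (b in seq_along(config$batch_sizes)) {
    n <- config$batch_sizes[b]
    batch <- sprintf("B%d", b)
    inj <- seq_len(n)
    is_qc <- inj %% config$qc_every == 0L
    n_qc <- sum(is_qc)
    n_exp <- n - n_qc

    g <- config$replicate_group_size
    group_idx <- ceiling(seq_len(n_exp) / g)
    rep_idx <- seq_len(n_exp) - (group_idx - 1L) * g
    bio <- stats::rnorm(max(group_idx), 0, config$biological_cv)[group_idx]
    tech <- stats::rnorm(n_exp, 0, config$technical_cv)
    exp_area <- ref * exp(bio) * exp(tech)
    qc_area <- ref * exp(stats::rnorm(n_qc, 0, config$qc_cv))

    sample_id <- character(n); replicate_id <- character(n)
    cls <- character(n); area <- numeric(n)
    sample_id[!is_qc] <- sprintf("%s_S%03d", batch, group_idx)
    replicate_id[!is_qc] <- as.character(rep_idx)
    cls[!is_qc] <- "experimental"
    area[!is_qc] <- exp_area
    sample_id[is_qc] <- sprintf("%s_QC%02d", batch, seq_len(n_qc))
    replicate_id[is_qc] <- "1"
    cls[is_qc] <- "qc"
    area[is_qc] <- qc_area

    rows[[b]] <- data.frame(
      sample_id = sample_id, replicate_id = replicate_id, batch_id = batch,
      sub_batch_id = NA_character_, injection_order = inj,
      compound_id = meta$compound_id, sample_class = cls, peak_area = area,
      sample_weight = NA_real_, stringsAsFactors = FALSE
    )
  }
  peak_table(do.call(rbind, rows))
}

## Per-record multiplicative drift factors for one effect type, computed on
## a derived seed stream per type so type 4 is exactly type 1 x type 2.
effect_factors <- function(control, effect_type, config) {
  bids <- batches(control)
  f <- numeric(nrow(control))
  if (effect_type == 1L) {
    set.seed(sub_seed(config, 1L))
    dirs <- sample(c(-1, 1), length(bids), replace = TRUE)
    for (b in seq_along(bids)) {
      sel <- control$batch_id == bids[b]
      n <- max(control$injection_order[sel])
      pos <- control$injection_order[sel]
      frac <- if (n > 1L) (pos - 1) / (n - 1) else 0
      f[sel] <- config$slope_magnitude^(dirs[b] * frac)
    }
  } else if (effect_type == 2L) {
    set.seed(sub_seed(config, 2L))
    fb <- c(1, stats::runif(length(bids) - 1L, 1 / config$batch_magnitude,
                            config$batch_magnitude))
    for (b in seq_along(bids)) f[control$batch_id == bids[b]] <- fb[b]
  } else if (effect_type == 3L) {
    set.seed(sub_seed(config, 3L))
    for (b in seq_along(bids)) {
      sel <- control$batch_id == bids[b]
      n <- max(control$injection_order[sel])
      walk <- cumsum(stats::rnorm(n))
      sm <- as.numeric(stats::filter(walk, rep(1 / 5, 5), sides = 2))
      pad <- which(is.na(sm))
      sm[pad] <- walk[pad]            # ends keep the raw walk
      sm <- sm - sm[1]
      amp <- max(abs(sm))
      lf <- if (amp > 0) sm * (log(config$slope_magnitude) / amp) else sm * 0
      f[sel] <- exp(lf)[control$injection_order[sel]]
    }
  } else if (effect_type == 4L) {
    f <- effect_factors(control, 1L, config) * effect_factors(control, 2L, config)
  } else {
    stop("effect_type must be 1, 2, 3 or 4", call. = FALSE)
  }
  f
}

#' Apply a signal-drift/batch effect to a control table
#'
#' Multiplies each record's peak area by an effect-type-specific factor:
#' * **type 1** — per batch, a geometric ramp from 1 at the first injection
#'   to `slope_magnitude^d` at the last, with direction `d` (up or down)
#'   drawn per batch: monotone intra-batch drift;
#' * **type 2** — a constant per-batch factor drawn uniformly from
#'   `[1/batch_magnitude, batch_magnitude]`, with the first batch pinned to
#'   1: pure between-batch shifts;
#' * **type 3** — the exponential of a smoothed Gaussian random walk over
#'   injection order, rescaled so the largest log-deviation equals
#'   `log(slope_magnitude)`: irregular drift;
#' * **type 4** — the elementwise product of the type-1 and type-2 factors:
#'   monotone drift plus batch shifts, the pattern most commonly seen in
#'   real run sequences.
#'
#' @param control A control table from [simulate_control()].
#' @param effect_type Integer 1-4.
#' @param config The [drift_config()] used for the control (its seed drives
#'   the effect draws on independent streams).
#' @return A list with `table` (the drifted [peak_table()]) and `truth`
#'   (a `data.frame` of the per-record multiplicative factors applied).
#' @export
apply_effect <- function(control, effect_type, config) {
  stopifnot(inherits(config, "drift_config"))
  effect_type <- as.integer(effect_type)
  f <- effect_factors(control, effect_type, config)
  drifted <- control
  drifted$peak_area <- control$peak_area * f
  truth <- data.frame(
    sample_id = control$sample_id, replicate_id = control$replicate_id,
    batch_id = control$batch_id, compound_id = control$compound_id,
    injection_order = control$injection_order,
    factor = f, stringsAsFactors = FALSE
  )
  list(table = peak_table(drifted), truth = truth)
}

#' Simulate a control table plus all four drift/batch effect variants
#'
#' @param meta A [compound_meta()] (e.g. from [read_sdf_metadata()]).
#' @param config A [drift_config()].
#' @return An object of class `simulation_bundle`: a list with `meta`,
#'   `config`, `control`, `type1` ... `type4` peak tables sharing identical
#'   keys and injection orders, and `truth`, a `data.frame` with one row per
#'   record and one factor column per effect type (the control factor is
#'   identically 1).
#' @export
simulate_data <- function(meta, config = drift_config()) {
  control <- simulate_control(meta, config)
  eff <- lapply(1:4, function(k) apply_effect(control, k, config))
  truth <- eff[[1]]$truth[, c("sample_id", "replicate_id", "batch_id",
                              "compound_id", "injection_order")]
  truth$control <- 1
  for (k in 1:4) truth[[sprintf("type%d", k)]] <- eff[[k]]$truth$factor
  structure(
    list(meta = meta, config = config, control = control,
         type1 = eff[[1]]$table, type2 = eff[[2]]$table,
         type3 = eff[[3]]$table, type4 = eff[[4]]$table, truth = truth),
    class = "simulation_bundle"
  )
}

#' @export
print.simulation_bundle <- function(x, ...) {
  cat(sprintf("<simulation_bundle> compound %s | %d batches (%s) | %d records per table\n",
              x$meta$compound_id, length(x$config$batch_sizes),
              paste(x$config$batch_sizes, collapse = "/"), nrow(x$control)))
  invisible(x)
}
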