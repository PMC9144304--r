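#' Cross-validated agreement between corrected data and a reference
#'
#' Records are paired by their (sample, replicate, batch, compound) key,
#' partitioned into `folds` folds by a seeded uniform permutation, and for
#' each fold an ordinary least-squares regression of the corrected on the
#' reference areas is fitted on the remaining folds and used to predict the
#' held-out records.  The pooled held-out residuals give
#' `RMSE = sqrt(mean(residual^2))` and `R^2 = 1 - SS_res / SS_tot`, with
#' `SS_tot` taken about the mean of the corrected areas.  Pooling the
#' held-out predictions (rather than averaging per-fold statistics) keeps
#' the estimate stable for small folds.
#'
#' @param corrected A [peak_table()] (pseudoQC rows, if any, are ignored).
#' @param control The reference [peak_table()] with identical keys, e.g.
#'   the drift-free table of a [simulate_data()] bundle.
#' @param folds Number of folds (default 10); `folds = n` gives
#'   leave-one-out.
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_metrics`: list with `r2`, `rmse`,
#'   `folds`, `seed`, `n`, and the per-record `fold_assignments`.
#' @export
cv_regression_metrics <- function(corrected, control, folds = 10L, seed = 1L) {
  key_of <- function(t) paste(t$sample_id, t$replicate_id, t$batch_id,
                              t$compound_id, sep = "\r")
  a <- corrected[corrected$sample_class != "pseudoqc", , drop = FALSE]
  b <- control[control$sample_class != "pseudoqc", , drop = FALSE]
  ka <- key_of(a); kb <- key_of(b)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched)) {
    stop("tables do not share identical keys; e.g. ",
         paste(utils::head(gsub("\r", "/", unmatched), 5L), collapse = "; "),
         call. = FALSE)
  }
  y <- a$peak_area
  x <- b$peak_area[match(ka, kb)]
  ok <- !is.na(x) & !is.na(y)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  folds <- as.integer(folds)
  if (n < folds) stop("need at least `folds` paired observations", call. = FALSE)

  set.seed(seed)
  assignment <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    held <- assignment == f
    cf <- stats::coef(stats::lm(y[!held] ~ x[!held]))
    pred[held] <- cf[1] + cf[2] * x[held]
  }
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / n),
         folds = folds, seed = seed, n = n, fold_assignments = assignment),
    class = "cv_metrics"
  )
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> R2 = %.4f, RMSE = %.6g (%d-fold CV, n = %d, seed = %d)\n",
              x$r2, x$rmse, x$folds, x$n, x$seed))
  invisible(x)
}

#' Maximum QC distance in principal-component space
#'
#' Pivots the table into a samples x compounds matrix (missing cells
#' imputed by the compound median), scales columns to zero mean and unit
#' variance, computes principal components by singular value
#' decomposition, and returns the maximum pairwise Euclidean distance
#' between true QC samples in the PC1-PC2 score plane.  Tightly clustered
#' QCs (small `maxdist`) indicate well-corrected technical variation.
#'
#' @param table A [peak_table()] with at least 2 QC samples and 2
#'   compounds.
#' @return An object of class `maxdist_result`: list with `maxdist`,
#'   `qc_scores` (PC1/PC2 coordinates of the QC samples), and
#'   `var_explained` (PC1 and PC2 variance fractions).
#' @export
pca_maxdist <- function(table) {
  tab <- table[table$sample_class != "pseudoqc" & !is.na(table$peak_area), ,
               drop = FALSE]
  cmp <- compounds(tab)
  if (length(cmp) < 2L) stop("need at least 2 compounds", call. = FALSE)
  row_key <- paste(tab$sample_id, tab$replicate_id, tab$batch_id, sep = "\r")
  rows <- unique(row_key)
  mat <- matrix(NA_real_, length(rows), length(cmp),
                dimnames = list(rows, cmp))
  mat[cbind(match(row_key, rows), match(tab$compound_id, cmp))] <- tab$peak_area
  for (j in seq_along(cmp)) {
    miss <- is.na(mat[, j])
    if (any(miss)) mat[miss, j] <- stats::median(mat[!miss, j])
  }
  is_qc_row <- vapply(rows, function(r) {
    any(tab$sample_class[row_key == r] == "qc")
  }, logical(1))
  if (sum(is_qc_row) < 2L) {
    stop("need at least 2 trueQC samples to define maxdist", call. = FALSE)
  }
  keep <- apply(mat, 2, stats::sd) > 0
  if (sum(keep) < 2L) stop("need at least 2 non-constant compounds", call. = FALSE)
  z <- scale(mat[, keep, drop = FALSE])
  sv <- svd(z)
  scores <- sv$u %*% diag(sv$d)
  var_frac <- sv$d^2 / sum(sv$d^2)
  qc_scores <- scores[is_qc_row, 1:2, drop = FALSE]
  d <- as.matrix(stats::dist(qc_scores))
  structure(
    list(maxdist = max(d),
         qc_scores = data.frame(sample = rows[is_qc_row],
                                pc1 = qc_scores[, 1], pc2 = qc_scores[, 2],
                                stringsAsFactors = FALSE),
         var_explained = var_frac[1:2]),
    class = "maxdist_result"
  )
}

#' @export
print.maxdist_result <- function(x, ...) {
  cat(sprintf("<maxdist_result> maxDist = %.4f (PC1 %.1f%%, PC2 %.1f%% variance)\n",
              x$maxdist, 100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}
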