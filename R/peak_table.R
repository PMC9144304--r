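#' @keywords internal
"_PACKAGE"

## Canonical long-format column order for peak tables on disk and in memory.
PEAK_TABLE_COLUMNS <- c(
  "sample_id", "replicate_id", "batch_id", "sub_batch_id",
  "injection_order", "compound_id", "sample_class", "peak_area",
  "sample_weight"
)

SAMPLE_CLASSES <- c("experimental", "qc", "pseudoqc", "blank", "external_standard")

#' Construct a validated peak table
#'
#' A peak table is the package's universal currency: a long-format
#' `data.frame` with one row per observed peak area, i.e. per
#' (sample, replicate, batch, compound) combination.  Mandatory columns are
#' `sample_id`, `batch_id`, `injection_order`, `compound_id` and
#' `peak_area`; `replicate_id` defaults to `"1"`, `sample_class` to
#' `"experimental"`, and `sub_batch_id` / `sample_weight` to `NA`.
#'
#' Injection order is 1-based and local to each batch: each batch is an
#' independently acquired run sequence, and a global run order (when one is
#' needed) is obtained by concatenating batches in their declared order.
#'
#' @param x A `data.frame` (or something coercible) in long format.
#' @param validate Run invariant checks (default `TRUE`).
#' @return A `data.frame` of class `peak_table` with canonical column order.
#' @details Validation enforces:
#' * `sample_class` is one of `experimental`, `qc`, `pseudoqc`, `blank`,
#'   `external_standard`;
#' * `peak_area` is non-negative or `NA` (missing areas are allowed and are
#'   never imputed here);
#' * `injection_order` is a positive integer, unique within each
#'   `(batch_id, compound_id)` slice among non-pseudoqc records (pseudoQC
#'   anchor rows may share a position with the observation they summarise);
#' * no duplicated `(sample_id, replicate_id, batch_id, compound_id)` keys.
#' Violations are reported with the offending row numbers or keys.
#' @seealso [read_peak_table()], [write_peak_table()]
#' @export
peak_table <- function(x, validate = TRUE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  mandatory <- c("sample_id", "batch_id", "injection_order", "compound_id", "peak_area")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    stop("peak table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(x)
  if (is.null(x$replicate_id)) x$replicate_id <- rep("1", n)
  if (is.null(x$sub_batch_id)) x$sub_batch_id <- rep(NA_character_, n)
  if (is.null(x$sample_class)) x$sample_class <- rep("experimental", n)
  if (is.null(x$sample_weight)) x$sample_weight <- rep(NA_real_, n)

  x$sample_id <- as.character(x$sample_id)
  x$replicate_id <- as.character(x$replicate_id)
  x$batch_id <- as.character(x$batch_id)
  x$sub_batch_id <- as.character(x$sub_batch_id)
  x$injection_order <- as.integer(x$injection_order)
  x$compound_id <- as.character(x$compound_id)
  x$sample_class <- as.character(x$sample_class)
  x$peak_area <- as.numeric(x$peak_area)
  x$sample_weight <- as.numeric(x$sample_weight)

  x <- x[, PEAK_TABLE_COLUMNS]
  rownames(x) <- NULL
  if (validate) validate_peak_table(x)
  class(x) <- c("peak_table", "data.frame")
  x
}

#' Validate peak-table invariants
#'
#' @param x A long-format `data.frame` with peak-table columns.
#' @return Invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_peak_table <- function(x) {
  bad_class <- which(!x$sample_class %in% SAMPLE_CLASSES)
  if (length(bad_class)) {
    stop("invalid sample_class at row(s) ",
         paste(utils::head(bad_class, 10L), collapse = ", "),
         ": must be one of ", paste(SAMPLE_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  bad_area <- which(!is.na(x$peak_area) & x$peak_area < 0)
  if (length(bad_area)) {
    stop("negative peak_area at row(s) ",
         paste(utils::head(bad_area, 10L), collapse = ", "), call. = FALSE)
  }
  bad_inj <- which(is.na(x$injection_order) | x$injection_order < 1L)
  if (length(bad_inj)) {
    stop("injection_order must be a positive integer; offending row(s): ",
         paste(utils::head(bad_inj, 10L), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$sample_id, x$replicate_id, x$batch_id, x$compound_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(paste(x$sample_id, x$replicate_id, x$batch_id,
                              x$compound_id, sep = "/")[dup])
    stop("duplicate (sample_id, replicate_id, batch_id, compound_id) key(s): ",
         paste(utils::head(offenders, 10L), collapse = "; "), call. = FALSE)
  }
  nonpseudo <- x$sample_class != "pseudoqc"
  slice <- paste(x$batch_id, x$compound_id, x$injection_order, sep = "\r")[nonpseudo]
  dup_inj <- duplicated(slice)
  if (any(dup_inj)) {
    offenders <- unique(gsub("\r", "/", slice[dup_inj]))
    stop("injection_order not unique within (batch_id, compound_id) among ",
         "non-pseudoqc records: ",
         paste(utils::head(offenders, 10L), collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a peak table from a delimited text file
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(sample_id = "Sample", peak_area = "Area")`.
#' @return A validated [peak_table()].
#' @export
read_peak_table <- function(path, column_map = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(x)) {
        stop("column_map refers to absent column '", src, "'", call. = FALSE)
      }
      names(x)[names(x) == src] <- canonical
    }
  }
  peak_table(x)
}

#' Write a peak table to CSV
#'
#' Columns are written in canonical order; output is byte-stable for
#' identical input, and `read_peak_table(write_peak_table(t))` recovers `t`
#' (numeric fields to full double precision).
#'
#' @param table A [peak_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(table, path) {
  table <- peak_table(table)
  out <- as.data.frame(table)[, PEAK_TABLE_COLUMNS]
  for (col in c("peak_area", "sample_weight")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.15g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Batches of a peak table, in declared (first-appearance) order
#' @param table A [peak_table()].
#' @return Character vector of batch ids.
#' @export
batches <- function(table) unique(table$batch_id)

#' Compounds present in a peak table
#' @param table A [peak_table()].
#' @return Character vector of compound ids.
#' @export
compounds <- function(table) unique(table$compound_id)

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d records | %d compound(s) | %d batch(es)\n",
              nrow(x), length(compounds(x)), length(batches(x))))
  cls <- table(x$sample_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  NextMethod()
}
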