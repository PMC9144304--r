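#' Limit-of-detection table from blank injections
#'
#' For every (compound, sub-batch) cell holding blank records, the limit of
#' detection (LOD) is three times the mean blank peak area of that cell.
#' Cells without blanks are absent from the result.
#'
#' @param table A [peak_table()] with `sample_class == "blank"` records
#'   carrying `sub_batch_id`.
#' @return A `data.frame` of class `lod_table` with columns `compound_id`,
#'   `sub_batch_id`, `lod`, `n_blank`.
#' @export
compute_lod <- function(table) {
  blanks <- table[table$sample_class == "blank" & !is.na(table$peak_area), ,
                  drop = FALSE]
  if (!nrow(blanks)) {
    warning("table contains no blank records; LOD table is empty", call. = FALSE)
    out <- data.frame(compound_id = character(), sub_batch_id = character(),
                      lod = numeric(), n_blank = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("lod_table", "data.frame")
    return(out)
  }
  agg <- stats::aggregate(peak_area ~ compound_id + sub_batch_id, data = blanks,
                          FUN = mean)
  n <- stats::aggregate(peak_area ~ compound_id + sub_batch_id, data = blanks,
                        FUN = length)
  out <- data.frame(compound_id = agg$compound_id,
                    sub_batch_id = agg$sub_batch_id,
                    lod = 3 * agg$peak_area,
                    n_blank = as.integer(n$peak_area),
                    stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, out$sub_batch_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lod_table", "data.frame")
  out
}

#' Remove compounds with widespread sub-LOD signal
#'
#' Per compound, the fraction of experimental records falling strictly
#' below their (compound, sub-batch) LOD is computed over the records that
#' have a defined LOD cell; compounds with a fraction exceeding
#' `max_below_frac` are removed entirely.  Surviving compounds keep all
#' their records — individual sub-LOD values are retained, not masked.
#'
#' @param table A [peak_table()].
#' @param lods A [compute_lod()] table.
#' @param max_below_frac Removal threshold on the sub-LOD fraction
#'   (default 0.25; removal requires strictly more than this fraction).
#' @return A list with `table` (filtered [peak_table()]) and
#'   `removed_compounds` (character vector).
#' @export
filter_lod <- function(table, lods, max_below_frac = 0.25) {
  removed <- character(0)
  if (nrow(lods)) {
    key <- paste(table$compound_id, table$sub_batch_id, sep = "\r")
    lod_key <- paste(lods$compound_id, lods$sub_batch_id, sep = "\r")
    cell_lod <- lods$lod[match(key, lod_key)]
    in_scope <- table$sample_class == "experimental" & !is.na(cell_lod) &
      !is.na(table$peak_area)
    for (cmp in compounds(table)) {
      sel <- in_scope & table$compound_id == cmp
      denom <- sum(sel)
      if (!denom) next
      frac <- sum(table$peak_area[sel] < cell_lod[sel]) / denom
      if (frac > max_below_frac) removed <- c(removed, cmp)
    }
  }
  out <- as.data.frame(table)[!table$compound_id %in% removed, , drop = FALSE]
  list(table = peak_table(out), removed_compounds = removed)
}

#' Normalize peak areas by sample weight
#'
#' Divides each experimental record's peak area by its sample weight (mg),
#' yielding arbitrary units of area per unit weight, then drops blank and
#' external-standard records, which have served their purpose (LOD
#' thresholds, relative scale) by this point.  The returned table carries a
#' `weight_normalized` attribute; re-normalizing such a table is an error,
#' preventing accidental double division.
#'
#' @param table A [peak_table()] whose experimental records carry
#'   `sample_weight`.
#' @return A weight-normalized [peak_table()] without blank or
#'   external-standard records.
#' @export
weight_normalize <- function(table) {
  if (isTRUE(attr(table, "weight_normalized"))) {
    stop("table is already weight-normalized", call. = FALSE)
  }
  is_exp <- table$sample_class == "experimental"
  bad <- is_exp & (is.na(table$sample_weight) | table$sample_weight <= 0)
  if (any(bad)) {
    keys <- paste(table$sample_id[bad], table$replicate_id[bad],
                  table$batch_id[bad], table$compound_id[bad], sep = "/")
    stop("experimental record(s) without a positive sample_weight: ",
         paste(utils::head(keys, 10L), collapse = "; "), call. = FALSE)
  }
  out <- as.data.frame(table)
  out$peak_area[is_exp] <- out$peak_area[is_exp] / out$sample_weight[is_exp]
  out <- out[!out$sample_class %in% c("blank", "external_standard"), ,
             drop = FALSE]
  out <- peak_table(out)
  attr(out, "weight_normalized") <- TRUE
  out
}
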