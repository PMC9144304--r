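#' Compound metadata record
#'
#' Holds the identity and intensity scale of a compound used to seed
#' simulations.  `reference_intensity` anchors the simulated peak-area
#' scale, typically the most intense peak of a library spectrum.
#'
#' @param compound_id Compound name.
#' @param reference_intensity Positive scale anchor (arbitrary units of area).
#' @param accession Optional repository accession (e.g. a MoNA ID).
#' @param extra Named list of additional metadata fields.
#' @return An object of class `compound_meta`.
#' @export
compound_meta <- function(compound_id, reference_intensity,
                          accession = NULL, extra = list()) {
  reference_intensity <- as.numeric(reference_intensity)
  if (!is.finite(reference_intensity) || reference_intensity <= 0) {
    stop("reference_intensity must be a positive number", call. = FALSE)
  }
  structure(
    list(compound_id = as.character(compound_id),
         reference_intensity = reference_intensity,
         accession = if (is.null(accession)) NA_character_ else as.character(accession),
         extra = extra),
    class = "compound_meta"
  )
}

#' @export
print.compound_meta <- function(x, ...) {
  cat(sprintf("<compound_meta> %s (accession: %s), reference intensity %.6g\n",
              x$compound_id, x$accession, x$reference_intensity))
  invisible(x)
}

#' Read compound metadata from a structure-data file (SDF)
#'
#' Parses a V2000-style SDF, such as the per-spectrum records distributed by
#' the MassBank of North America (MoNA), into a list of [compound_meta()]
#' objects.  Truncated records (no `M  END` before the `$$$$` terminator)
#' are skipped with a warning naming the record index; the connection table
#' and data items of intact records are parsed with \pkg{ChemmineR}.
#'
#' The reference intensity of each compound is taken as, in order of
#' preference: the maximum intensity in a `MASS SPECTRAL PEAKS`-style data
#' item (lines of `m/z intensity` pairs); the numeric value of
#' `intensity_tag` when supplied; otherwise `default_intensity`, with a
#' warning.
#'
#' @param path Path to the SDF file.
#' @param intensity_tag Optional data-item tag holding a numeric reference
#'   intensity, used when no spectral peak list is present.
#' @param default_intensity Fallback scale (default `1e5`).
#' @return A list of [compound_meta()] objects, one per intact SDF record.
#' @export
read_sdf_metadata <- function(path, intensity_tag = NULL, default_intensity = 1e5) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("SDF file is empty: ", path, call. = FALSE)
  term <- grep("^\\${4}", lines)
  starts <- c(1L, term + 1L)
  ends <- c(term, length(lines))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  recs <- Map(function(s, e) lines[s:e], starts, ends)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (!length(recs)) stop("no SDF records found in ", path, call. = FALSE)

  intact <- vapply(recs, function(r) any(grepl("^M  END", r)), logical(1))
  if (any(!intact)) {
    warning("skipping truncated SDF record(s) at index: ",
            paste(which(!intact), collapse = ", "), call. = FALSE)
  }
  recs <- recs[intact]
  if (!length(recs)) stop("no intact SDF records in ", path, call. = FALSE)

  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(unlist(lapply(recs, function(r) {
    r <- r[!grepl("^\\${4}", r)]
    c(r, "$$$$")
  })), tmp)
  ## metadata-only records (no atoms) are valid input here, but trip
  ## ChemmineR's connection-table validity warning; truncation is already
  ## handled by the pre-scan above
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))

  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    sdf <- sdfset[[i]]
    db <- as.list(ChemmineR::datablock(sdf))
    tags <- names(db)
    name_tag <- tags[grepl("^name$|^compound[ _]?name$", tags, ignore.case = TRUE)]
    compound_id <- if (length(name_tag)) db[[name_tag[1]]] else ChemmineR::sdfid(sdf)
    acc_tag <- tags[grepl("id$|accession", tags, ignore.case = TRUE)]
    acc_tag <- setdiff(acc_tag, name_tag)
    accession <- if (length(acc_tag)) db[[acc_tag[1]]] else NULL

    peaks_tag <- tags[grepl("spectral peaks|^peaks$", tags, ignore.case = TRUE)]
    ref <- NA_real_
    if (length(peaks_tag)) {
      ref <- max_spectrum_intensity(db[[peaks_tag[1]]])
    }
    if (!is.finite(ref) && !is.null(intensity_tag) && intensity_tag %in% tags) {
      ref <- suppressWarnings(as.numeric(db[[intensity_tag]]))
    }
    if (!is.finite(ref)) {
      warning("record ", i, " (", compound_id, "): no usable intensity field; ",
              "using default reference intensity ", default_intensity,
              call. = FALSE)
      ref <- default_intensity
    }
    out[[i]] <- compound_meta(compound_id, ref, accession = accession, extra = db)
  }
  out
}

## A spectrum data item is whitespace/newline-separated "mz intensity" pairs;
## the intensity is every second number.
max_spectrum_intensity <- function(txt) {
  nums <- suppressWarnings(as.numeric(strsplit(trimws(paste(txt, collapse = " ")),
                                               "[[:space:]]+")[[1]]))
  nums <- nums[is.finite(nums)]
  if (length(nums) < 2L) return(NA_real_)
  intensities <- nums[seq(2L, length(nums), by = 2L)]
  if (!length(intensities)) NA_real_ else max(intensities)
}

#' Write a minimal MoNA-style SDF file
#'
#' Writes one V2000 record per [compound_meta()] with an empty connection
#' table, the compound name, accession, and a two-column spectral peak list
#' whose maximum intensity equals the reference intensity.  Intended for
#' generating small synthetic fixtures and round-trip testing of
#' [read_sdf_metadata()].
#'
#' @param metas List of [compound_meta()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdf_metadata <- function(metas, path) {
  if (inherits(metas, "compound_meta")) metas <- list(metas)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in metas) {
    writeLines(c(
      m$compound_id,
      "  driftanchor",
      "",
      "  0  0  0  0  0  0  0  0  0  0999 V2000",
      "M  END",
      "> <NAME>",
      m$compound_id,
      "",
      "> <ACCESSION>",
      if (is.na(m$accession)) "NA" else m$accession,
      "",
      "> <MASS SPECTRAL PEAKS>",
      sprintf("100.0 %.6g", m$reference_intensity / 2),
      sprintf("250.0 %.6g", m$reference_intensity),
      "",
      "$$$$"
    ), con)
  }
  invisible(path)
}
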