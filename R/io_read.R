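#' Read a GeneMapper-style exported character table
#'
#' The exact byte layout of commercial genotyping exports varies between
#' program versions, so the dialect implemented here is deliberately
#' simple and documented: a delimited text table whose header row names
#' the bins (first field is the sample-ID column), followed by one row
#' per sample with its presence/absence calls. Cells that are not `0` or
#' `1` — blanks, `NA`, `?`, or anything unparseable — are read as
#' missing (`?`). When every bin label parses as a number and the
#' numbers are strictly increasing they are taken as fragment-size
#' centers in bases. `sep`, `missing` and the CEQ count-row names (see
#' [read_ceq_table()]) are the dialect options that absorb real-world
#' variants.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param source_tag provenance label; defaults to the file name.
#' @return An [aflp_matrix()].
#' @export
read_genemapper_table <- function(path, sep = "\t",
                                  source_tag = basename(path)) {
  rows <- read_delim_rows(path, sep)
  parse_call_rows(rows$header, rows$body, source_tag)
}

#' Read a CEQ-style fragment-analysis table with per-bin counts
#'
#' Same layout as the GeneMapper-style dialect, plus two count rows
#' (named `Fragments` and `Samples` in the sample-ID column) preceding
#' the sample rows. For each bin, `Fragments` counts the called peaks
#' and `Samples` the samples with at least one peak; `Fragments >
#' Samples` means some sample has two peaks (a double peak) inside the
#' bin, i.e. the bin's sizing is suspect, and the bin is pre-masked
#' before any reliability analysis.
#'
#' @inheritParams read_genemapper_table
#' @param fragments_row,samples_row labels of the two count rows.
#' @return A list with `matrix` (an [aflp_matrix()] of the analyzable
#'   bins only) and `prelim_masked_bins` (character vector of
#'   double-peak bin IDs).
#' @export
read_ceq_table <- function(path, sep = "\t",
                           fragments_row = "Fragments",
                           samples_row = "Samples",
                           source_tag = basename(path)) {
  rows <- read_delim_rows(path, sep)
  ids <- vapply(rows$body, `[`, character(1), 1L)
  fi <- which(ids == fragments_row)
  si <- which(ids == samples_row)
  if (length(fi) != 1 || length(si) != 1)
    stop("CEQ table must contain exactly one '", fragments_row,
         "' and one '", samples_row, "' row")
  nbin <- length(rows$header) - 1L
  frag <- as.numeric(rows$body[[fi]][-1])
  samp <- as.numeric(rows$body[[si]][-1])
  if (any(is.na(frag)) || any(is.na(samp)))
    stop("non-numeric Fragments/Samples count")
  if (any(frag < samp))
    stop("impossible counts: Fragments < Samples at bin(s) ",
         paste(rows$header[-1][frag < samp], collapse = ", "))
  prelim <- rows$header[-1][frag != samp]
  mat <- parse_call_rows(rows$header, rows$body[-c(fi, si)], source_tag)
  if (length(prelim))
    mat <- subset_matrix(mat, bins = setdiff(bin_ids(mat), prelim))
  list(matrix = mat, prelim_masked_bins = prelim)
}

#' Read a generic delimited 0/1/? matrix
#'
#' Comma- (default) or otherwise-delimited matrix with bin labels in the
#' header and sample IDs in the first column; a convenience dialect for
#' matrices not exported by genotyping software.
#'
#' @inheritParams read_genemapper_table
#' @return An [aflp_matrix()].
#' @export
read_generic_matrix <- function(path, sep = ",",
                                source_tag = basename(path)) {
  read_genemapper_table(path, sep = sep, source_tag = source_tag)
}

# -- shared low-level parsing -------------------------------------------

read_delim_rows <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty table: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  body <- lapply(fields[-1], trimws)
  width <- length(header)
  len <- vapply(body, length, integer(1))
  if (any(len != width))
    stop("ragged row(s) at line ",
         paste(which(len != width) + 1L, collapse = ", "),
         " (expected ", width, " fields)")
  list(header = header, body = body)
}

parse_call_rows <- function(header, body, source_tag) {
  if (length(body) == 0) stop("empty table: no sample rows")
  bin_labels <- header[-1]
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sample row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  calls <- do.call(rbind, lapply(body, function(f) f[-1]))
  calls[!(calls %in% c("0", "1"))] <- "?"
  sizes <- suppressWarnings(as.numeric(bin_labels))
  if (anyNA(sizes) || any(diff(sizes) <= 0)) sizes <- NULL
  aflp_matrix(calls, sample_ids = ids, bin_ids = bin_labels,
              bin_size = sizes, source_tag = source_tag)
}
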