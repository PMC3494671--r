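#' Construct an AFLP presence/absence character matrix
#'
#' The central container of the package: a samples-by-bins matrix of
#' presence/absence calls as produced by genotyping software after bin
#' definition and peak calling. Each bin is a fragment-size category
#' (roughly one base wide) within which fragments are treated as a single
#' homologous character; a call is `"1"` (fragment present), `"0"`
#' (fragment absent) or `"?"` (ambiguous / reaction failed).
#'
#' @param calls character (or integer) matrix of calls; values must be
#'   `0`, `1` or `?` (`NA` is accepted as `?`). Row names are taken as
#'   sample IDs and column names as bin IDs when `sample_ids`/`bin_ids`
#'   are not given.
#' @param sample_ids unique sample labels, one per row.
#' @param bin_ids unique bin labels, one per column.
#' @param bin_size optional numeric vector of fragment-length centers in
#'   bases, strictly increasing along bin order, or `NULL` when sizes are
#'   unknown.
#' @param source_tag free-text provenance label (primer combination or
#'   file of origin); used to namespace bin IDs on concatenation.
#'
#' @return An object of class `aflp_matrix`: a list with elements
#'   `calls` (character matrix with dimnames), `bin_size`, `source_tag`.
#' @examples
#' m <- aflp_matrix(rbind(s1 = c("0", "1", "1"),
#'                        s2 = c("1", "1", "?")),
#'                  bin_ids = c("b100", "b101", "b103"),
#'                  bin_size = c(100, 101, 103))
#' m
#' @export
aflp_matrix <- function(calls, sample_ids = rownames(calls),
                        bin_ids = colnames(calls), bin_size = NULL,
                        source_tag = "matrix") {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  force(sample_ids); force(bin_ids)
  calls <- matrix(as.character(calls), nrow = nrow(calls))
  calls[is.na(calls)] <- "?"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(bin_ids)) bin_ids <- paste0("B", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  bin_ids <- as.character(bin_ids)
  dimnames(calls) <- list(sample_ids, bin_ids)
  obj <- structure(
    list(calls = calls,
         bin_size = if (!is.null(bin_size)) as.numeric(bin_size),
         source_tag = as.character(source_tag)[1]),
    class = "aflp_matrix")
  validate_aflp_matrix(obj)
  obj
}

validate_aflp_matrix <- function(x) {
  calls <- x$calls
  bad <- !(calls %in% c("0", "1", "?"))
  if (any(bad))
    stop("invalid call value(s): ",
         paste(unique(calls[bad]), collapse = ", "),
         " (allowed: 0, 1, ?)")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ID(s): ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate bin ID(s): ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  if (!is.null(x$bin_size)) {
    if (length(x$bin_size) != ncol(calls))
      stop("bin_size length (", length(x$bin_size),
           ") does not match number of bins (", ncol(calls), ")")
    if (any(!is.finite(x$bin_size)) || any(diff(x$bin_size) <= 0))
      stop("bin_size must be finite and strictly increasing")
  }
  invisible(x)
}

#' @export
print.aflp_matrix <- function(x, ...) {
  calls <- x$calls
  tab <- table(factor(calls, levels = c("0", "1", "?")))
  cat(sprintf("AFLP character matrix '%s': %d samples x %d bins\n",
              x$source_tag, nrow(calls), ncol(calls)))
  cat(sprintf("  calls: %d absent (0), %d present (1), %d ambiguous (?)\n",
              tab[["0"]], tab[["1"]], tab[["?"]]))
  if (!is.null(x$bin_size))
    cat(sprintf("  bin sizes: %.2f - %.2f bases\n",
                min(x$bin_size), max(x$bin_size)))
  invisible(x)
}

#' @export
dim.aflp_matrix <- function(x) dim(x$calls)

#' Sample and bin labels of an AFLP matrix
#' @param x an `aflp_matrix`.
#' @return Character vector of labels.
#' @export
sample_ids <- function(x) rownames(x$calls)

#' @rdname sample_ids
#' @export
bin_ids <- function(x) colnames(x$calls)

#' Subset an AFLP matrix by samples and/or bins
#'
#' @param x an `aflp_matrix`.
#' @param samples,bins index vectors (logical, integer or label).
#' @return An `aflp_matrix` restricted to the selected rows/columns.
#' @export
subset_matrix <- function(x, samples = NULL, bins = NULL) {
  calls <- x$calls
  keep_s <- if (is.null(samples)) seq_len(nrow(calls)) else samples
  keep_b <- if (is.null(bins)) seq_len(ncol(calls)) else bins
  calls <- calls[keep_s, keep_b, drop = FALSE]
  size <- x$bin_size
  if (!is.null(size)) {
    names(size) <- bin_ids(x)
    size <- unname(size[colnames(calls)])
  }
  aflp_matrix(calls, bin_size = size, source_tag = x$source_tag)
}

# calls as integer matrix: 0/1 with NA for "?"
calls_int <- function(x) {
  m <- x$calls
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "0"] <- 0L
  out[m == "1"] <- 1L
  out
}
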