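#' Concatenate multi-primer character matrices into a supermatrix
#'
#' AFLP studies typically score several primer combinations per sample;
#' the per-primer matrices are concatenated column-wise into one
#' supermatrix before masking. The sample set of the result is the
#' union of the input sample sets; a sample absent from a source matrix
#' receives `?` at all of that source's bins. Bins are the disjoint
#' union, namespaced as `sourceTag:binID` to guarantee uniqueness, with
#' each source's internal bin order preserved.
#'
#' Fragment-size centers are retained only when they remain strictly
#' increasing across the concatenation (sizes usually restart per
#' primer, in which case they are dropped and the bin-distance check
#' should be applied per source matrix beforehand).
#'
#' @param matrices list of [aflp_matrix()] objects (length >= 1; a
#'   single matrix is returned unchanged).
#' @return An [aflp_matrix()] supermatrix.
#' @export
concatenate_matrices <- function(matrices) {
  if (!length(matrices)) stop("empty input: no matrices to concatenate")
  stopifnot(all(vapply(matrices, inherits, logical(1), "aflp_matrix")))
  if (length(matrices) == 1) return(matrices[[1]])
  tags <- vapply(matrices, function(m) m$source_tag, character(1))
  if (anyDuplicated(tags)) {
    raw_bins <- unlist(lapply(matrices, bin_ids))
    if (anyDuplicated(raw_bins))
      stop("colliding bin IDs across sources without distinct source tags")
  }
  samples <- unique(unlist(lapply(matrices, sample_ids)))
  blocks <- lapply(matrices, function(m) {
    block <- matrix("?", length(samples), ncol(m$calls),
                    dimnames = list(samples,
                                    paste(m$source_tag, bin_ids(m),
                                          sep = ":")))
    block[sample_ids(m), ] <- m$calls
    block
  })
  calls <- do.call(cbind, blocks)
  sizes <- unlist(lapply(matrices, function(m)
    if (is.null(m$bin_size)) rep(NA_real_, ncol(m$calls)) else m$bin_size))
  if (anyNA(sizes) || any(diff(sizes) <= 0)) sizes <- NULL
  aflp_matrix(calls, bin_size = sizes,
              source_tag = paste(tags, collapse = "+"))
}
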