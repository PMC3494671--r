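#' Write a (masked) character matrix to text or NEXUS
#'
#' Masked bins (and optionally samples) are omitted; surviving bins keep
#' their original relative order. The text format mirrors the
#' GeneMapper-style input layout (tab-delimited, header of bin labels,
#' one row per sample) so written matrices can be re-read with
#' [read_genemapper_table()]. The NEXUS output is a standard-datatype
#' characters block (`SYMBOLS="01"`, `MISSING=?`) directly loadable by
#' downstream phylogeny programs.
#'
#' @param matrix an [aflp_matrix()].
#' @param path output file path.
#' @param format `"txt"` or `"nexus"`.
#' @param mask bin IDs to omit (character vector or a `mask_result`,
#'   whose `masked_bins` are used). Default: none.
#' @param drop_samples sample IDs to omit (e.g. masked replicate
#'   profiles).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, format = c("txt", "nexus"),
                         mask = character(), drop_samples = character()) {
  format <- match.arg(format)
  if (inherits(mask, "mask_result")) mask <- mask$masked_bins
  unknown <- setdiff(mask, bin_ids(matrix))
  if (length(unknown))
    stop("mask references unknown bin(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  keep_b <- setdiff(bin_ids(matrix), mask)
  if (length(keep_b) == 0)
    stop("all bins masked: nothing to write")
  keep_s <- setdiff(sample_ids(matrix), drop_samples)
  m <- subset_matrix(matrix, samples = keep_s, bins = keep_b)
  if (format == "txt") write_matrix_txt(m, path) else write_matrix_nexus(m, path)
  invisible(path)
}

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Sample", bin_ids(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m$calls)))
    writeLines(paste(c(sample_ids(m)[i], m$calls[i, ]), collapse = "\t"),
               con)
}

write_matrix_nexus <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- sample_ids(m)
  safe <- gsub("[^A-Za-z0-9_.]", "_", ids)
  seqs <- apply(m$calls, 1, paste, collapse = "")
  pad <- formatC(safe, width = max(nchar(safe)), flag = "-")
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m$calls), ncol(m$calls)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", pad, seqs), con)
  writeLines(c("  ;", "END;"), con)
}

#' Write the main sweep log
#'
#' Plain-text summary of a [threshold_sweep()]: one record per emitted
#' candidate matrix (BR/RR ranges, masked bin and pair counts, both
#' error rates) followed by the full threshold table with one row per
#' grid cell.
#'
#' @param sweep a `mask_sweep`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_run_log <- function(sweep, path) {
  stopifnot(inherits(sweep, "mask_sweep"))
  con <- file(path, "w")
  on.exit(close(con))
  thr <- sweep$thr
  writeLines(sprintf(
    "Masking sweep log: %d grid cells, %d analyzable bins, emission r_%s < %g and > %d bins",
    nrow(sweep$grid), sweep$n_analyzable_bins, thr$error_metric,
    thr$error_cutoff, thr$min_bins), con)
  g <- sweep$groups[sweep$groups$emitted, , drop = FALSE]
  writeLines(sprintf("Emitted matrices: %d", nrow(g)), con)
  if (nrow(g) > 0)
    writeLines(sprintf(
      "  EMITTED BR=%.2f-%.2f RR=%.1f-%.1f bins=%d pairs=%d r_Bonin=%.5f r_Jaccard=%.5f",
      g$br_min, g$br_max, g$rr_min, g$rr_max, g$n_bins, g$n_pairs,
      g$r_bonin, g$r_jaccard), con)
  writeLines("Threshold table (BR RR bins pairs r_Bonin r_Jaccard status):",
             con)
  grd <- sweep$grid
  status <- ifelse(grd$failed, "failed",
                   ifelse(grd$emitted, "emitted", "recorded"))
  writeLines(sprintf("  %.2f %.1f %s %s %s %s %s",
                     grd$br, grd$rr,
                     ifelse(is.na(grd$n_bins), "-", grd$n_bins),
                     ifelse(is.na(grd$n_pairs), "-", grd$n_pairs),
                     ifelse(is.na(grd$r_bonin), "-",
                            sprintf("%.5f", grd$r_bonin)),
                     ifelse(is.na(grd$r_jaccard), "-",
                            sprintf("%.5f", grd$r_jaccard)),
                     status), con)
  invisible(path)
}

#' Render a graphical overview of a replicate pair-state table
#'
#' One row per replicate pair, one column per bin. Light blue marks
#' reproducible shared absences (0,0), dark blue reproducible shared
#' presences (1,1), red unreproducible states (0,1)/(1,0), and grey any
#' ambiguous state containing `?`.
#'
#' @param table a `pair_state_table`.
#' @param path output image path; `.png` or `.svg` inferred from the
#'   extension.
#' @param main plot title.
#' @return Invisibly, `path`.
#' @export
render_replicate_overview <- function(table, path,
                                      main = "Replicate pair states") {
  s <- pair_states(table)
  code <- matrix(4L, nrow(s), ncol(s))          # ambiguous
  code[s == "0,0"] <- 1L
  code[s == "1,1"] <- 2L
  code[s %in% c("0,1", "1,0")] <- 3L
  cols <- c("lightblue", "darkblue", "red", "grey80")
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 8, height = 4)
  else grDevices::png(path, width = 900, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 6, 3, 1))  # settings die with the device
  np <- nrow(code); nb <- ncol(code)
  graphics::image(x = seq_len(nb), y = seq_len(np),
                  z = t(code[rev(seq_len(np)), , drop = FALSE]),
                  zlim = c(1, 4), col = cols, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = pretty(seq_len(nb)))
  graphics::axis(2, at = seq_len(np), labels = rev(rownames(s)),
                 las = 2, cex.axis = 0.7)
  graphics::mtext("bin", side = 1, line = 2)
  graphics::box()
  invisible(path)
}
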