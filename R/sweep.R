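#' Sweep the BR x RR threshold grid
#'
#' Runs [mask_fixpoint()] for every combination of bin-reliability and
#' replicate-reliability threshold on the grid defined by
#' [thresholds()]. With the default `br_min = 0.7` the grid has 26 BR
#' values (0.70, 0.71, ..., 0.95) crossed with 10 RR values (0.0, 0.1,
#' ..., 0.9), i.e. 260 combinations. Many combinations converge to the
#' same masked set; results with identical masked bins and pairs are
#' grouped into one representative row labelled by its BR and RR ranges,
#' and in practice only a handful of distinct candidate matrices emerge.
#'
#' A result is flagged *emitted* when its selected mismatch error rate
#' is strictly below the cutoff and strictly more than `min_bins` bins
#' survive. Grid cells whose fixpoint fails (e.g. an RR threshold that
#' masks every pair) are recorded as failed, not fatal.
#'
#' @inheritParams classify_pairs
#' @param thr a [thresholds()] object.
#' @return An object of class `mask_sweep`: `results` (one
#'   `mask_result` or `NULL` per grid cell), `grid` (data.frame with one
#'   row per cell: `br`, `rr`, `failed`, `n_bins`, `n_pairs`,
#'   `r_bonin`, `r_jaccard`, `emitted`, `group`), `groups` (one row per
#'   distinct masked set: BR/RR ranges, error rates, bin counts,
#'   emission flag, `representative` index into `results`), `thr`, and
#'   `n_analyzable_bins`.
#' @export
threshold_sweep <- function(matrix, reps, thr = thresholds()) {
  stopifnot(inherits(thr, "mask_thresholds"))
  table <- classify_pairs(matrix, reps)
  grid <- expand.grid(rr = thr$rr_grid, br = thr$br_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("br", "rr")]
  n <- nrow(grid)
  results <- vector("list", n)
  failed <- logical(n)
  for (k in seq_len(n)) {
    res <- tryCatch(
      mask_fixpoint_table(table, matrix, grid$br[k], grid$rr[k],
                          bd = thr$bd,
                          mask_all_absent_bins = thr$mask_all_absent_bins),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[k] <- TRUE
    } else {
      results[[k]] <- res
    }
  }
  metric <- if (thr$error_metric == "bonin") "r_bonin" else "r_jaccard"
  pull <- function(field, default = NA_real_)
    vapply(results, function(r)
      if (is.null(r)) default else r[[field]], numeric(1))
  grid$failed <- failed
  grid$n_bins <- pull("n_bins_remaining")
  grid$n_pairs <- pull("n_pairs_remaining")
  grid$r_bonin <- pull("r_bonin")
  grid$r_jaccard <- pull("r_jaccard")
  err <- grid[[metric]]
  grid$emitted <- !failed & !is.na(err) & err < thr$error_cutoff &
    grid$n_bins > thr$min_bins
  # group identical masked sets
  key <- vapply(seq_len(n), function(k) {
    r <- results[[k]]
    if (is.null(r)) return("<failed>")
    paste(paste(sort(r$masked_bins), collapse = ","),
          paste(sort(r$masked_pairs), collapse = ","), sep = ";")
  }, character(1))
  grid$group <- match(key, unique(key[!failed]))
  gidx <- sort(unique(grid$group[!failed]))
  groups <- do.call(rbind, lapply(gidx, function(g) {
    rows <- which(!failed & grid$group == g)
    rep_k <- rows[1]
    r <- results[[rep_k]]
    data.frame(group = g,
               br_min = min(grid$br[rows]), br_max = max(grid$br[rows]),
               rr_min = min(grid$rr[rows]), rr_max = max(grid$rr[rows]),
               n_cells = length(rows),
               n_bins = r$n_bins_remaining,
               n_pairs = r$n_pairs_remaining,
               r_bonin = r$r_bonin, r_jaccard = r$r_jaccard,
               emitted = grid$emitted[rep_k],
               representative = rep_k)
  }))
  structure(list(results = results, grid = grid, groups = groups,
                 thr = thr,
                 n_analyzable_bins = length(bin_ids(matrix))),
            class = "mask_sweep")
}

#' @export
print.mask_sweep <- function(x, ...) {
  cat(sprintf(
    "Threshold sweep: %d grid cells (%d BR x %d RR), %d failed\n",
    nrow(x$grid), length(x$thr$br_grid), length(x$thr$rr_grid),
    sum(x$grid$failed)))
  cat(sprintf("  %d distinct masked set(s), %d emitted (r_%s < %g, > %d bins)\n",
              nrow(x$groups), sum(x$groups$emitted),
              x$thr$error_metric, x$thr$error_cutoff, x$thr$min_bins))
  g <- x$groups
  lab <- sprintf("  BR %.2f-%.2f RR %.1f-%.1f: %4d bins, r_Bonin %.4f, r_Jaccard %.4f%s",
                 g$br_min, g$br_max, g$rr_min, g$rr_max, g$n_bins,
                 g$r_bonin, g$r_jaccard,
                 ifelse(g$emitted, "  [emitted]", ""))
  cat(lab, sep = "\n")
  invisible(x)
}

#' Emitted candidate matrices of a sweep
#'
#' @param sweep a `mask_sweep`.
#' @return The subset of `sweep$groups` rows flagged as emitted, ordered
#'   by decreasing number of surviving bins (the user would most likely
#'   choose the largest surviving matrix first).
#' @export
emitted_matrices <- function(sweep) {
  g <- sweep$groups[sweep$groups$emitted, , drop = FALSE]
  g[order(-g$n_bins), , drop = FALSE]
}
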