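#' Masking thresholds and sweep configuration
#'
#' Bundles the three masking criteria and the emission rules. Bin
#' reliability (BR) and replicate reliability (RR) thresholds are
#' inclusive: a bin with \eqn{BR_x \le BR} or a pair with
#' \eqn{RR_y \le RR} is masked. The sweep explores BR from `br_min` to
#' `br_max` in steps of `br_step` crossed with every RR in `rr_values`;
#' a fixpoint result is *emitted* (written out as a candidate matrix)
#' when its selected mismatch error rate is strictly below
#' `error_cutoff` and strictly more than `min_bins` bins survive.
#'
#' Threshold grids are generated in integer hundredths/tenths so that no
#' floating-point drift can shift a grid point.
#'
#' @param br_min minimal BR threshold of the sweep (default 0.7).
#' @param br_max maximal BR threshold (default and conventional cap
#'   0.95).
#' @param br_step BR increment (default 0.01).
#' @param rr_values RR thresholds (default 0, 0.1, ..., 0.9).
#' @param bd bin-distance threshold in bases, in \[0, 1): adjacent bins
#'   whose size centers differ by `bd` or less are both masked. 0
#'   disables the check for strictly increasing sizes.
#' @param error_metric which mismatch rate gates emission: `"bonin"`
#'   (default) or `"jaccard"`.
#' @param error_cutoff emission cutoff for the selected error rate
#'   (default 0.1, strict `<`).
#' @param min_bins minimum surviving bin count for emission (default 5,
#'   strict `>`).
#' @param mask_all_absent_bins mask bins whose unambiguous pair states
#'   are all `(0,0)` (default `TRUE`): shared fragment absences are
#'   conflict-free but particularly homoplasy-prone, so all-absent bins
#'   carry no reliable signal.
#' @return An object of class `mask_thresholds`.
#' @export
thresholds <- function(br_min = 0.7, br_max = 0.95, br_step = 0.01,
                       rr_values = seq(0, 0.9, by = 0.1),
                       bd = 0, error_metric = c("bonin", "jaccard"),
                       error_cutoff = 0.1, min_bins = 5,
                       mask_all_absent_bins = TRUE) {
  error_metric <- match.arg(error_metric)
  if (bd < 0 || bd >= 1)
    stop("BD must be between 0 and 1")
  if (br_min < 0 || br_min > br_max || br_max > 0.95 + 1e-9)
    stop("BR thresholds must satisfy 0 <= br_min <= br_max <= 0.95")
  if (error_cutoff <= 0 || error_cutoff > 1)
    stop("error_cutoff must be in (0, 1]")
  # exact decimal grids: integer hundredths / tenths
  br_grid <- seq(round(br_min * 100), round(br_max * 100),
                 by = max(1L, round(br_step * 100))) / 100
  rr_grid <- round(rr_values * 10) / 10
  structure(list(br_min = br_min, br_max = br_max, br_step = br_step,
                 br_grid = br_grid, rr_grid = rr_grid, bd = bd,
                 error_metric = error_metric,
                 error_cutoff = error_cutoff, min_bins = min_bins,
                 mask_all_absent_bins = mask_all_absent_bins),
            class = "mask_thresholds")
}

#' @export
print.mask_thresholds <- function(x, ...) {
  cat(sprintf(
    "Masking thresholds: BR %.2f..%.2f step %.2f, RR {%s}, BD %.2f\n",
    x$br_min, x$br_max, x$br_step,
    paste(format(x$rr_grid), collapse = ", "), x$bd))
  cat(sprintf("  emission: r_%s < %g and > %d bins remaining\n",
              x$error_metric, x$error_cutoff, x$min_bins))
  invisible(x)
}

#' Mask bins closer in size than the sequencer's sizing precision
#'
#' Capillary sizing is only reproducible to a fraction of a base, so two
#' bins whose fragment-length centers lie within that precision are
#' suspect splits of one allele. Adjacent bins (in size order, among the
#' currently unmasked bins) with center distance `<= bd` are both
#' masked.
#'
#' @param matrix an [aflp_matrix()]; when it carries no bin sizes the
#'   check is a no-op.
#' @param unmasked_bins bin IDs still under consideration (default: all
#'   bins).
#' @param bd distance threshold in bases, in \[0, 1).
#' @return Character vector of bin IDs to mask (possibly empty).
#' @examples
#' m <- aflp_matrix(matrix("1", 2, 3), bin_ids = c("b1", "b2", "b3"),
#'                  bin_size = c(100.0, 100.1, 102.0))
#' bin_distance_mask(m, bd = 0.15)  # b1 and b2
#' @export
bin_distance_mask <- function(matrix, unmasked_bins = bin_ids(matrix),
                              bd = 0) {
  if (bd < 0 || bd >= 1)
    stop("BD must be between 0 and 1")
  if (is.null(matrix$bin_size)) return(character())
  sizes <- matrix$bin_size
  names(sizes) <- bin_ids(matrix)
  sizes <- sizes[unmasked_bins]
  sizes <- sizes[order(sizes)]
  if (length(sizes) < 2) return(character())
  close_pair <- diff(sizes) <= bd
  hit <- unique(c(names(sizes)[-length(sizes)][close_pair],
                  names(sizes)[-1][close_pair]))
  hit
}

# one fixpoint run on a prebuilt pair-state table; shared by
# mask_fixpoint() and threshold_sweep()
mask_fixpoint_table <- function(table, matrix, br, rr, bd = 0,
                                mask_all_absent_bins = TRUE,
                                count_ambiguous = FALSE) {
  ind <- state_indicators(table)
  alive_p <- rep(TRUE, length(table$pair_ids))
  alive_b <- rep(TRUE, length(table$bin_ids))
  names(alive_p) <- table$pair_ids
  names(alive_b) <- table$bin_ids
  iterations <- 0L
  eps <- 1e-9   # guard against representation error in ratio comparisons
  repeat {
    iterations <- iterations + 1L
    changed <- FALSE
    # step 1: replicate reliability over surviving bins
    num <- rowSums(ind$repro[, alive_b, drop = FALSE])
    den <- rowSums(ind$unamb[, alive_b, drop = FALSE])
    rr_y <- ifelse(den > 0, num / den, NA_real_)
    kill_p <- alive_p & (is.na(rr_y) | rr_y <= rr + eps)
    if (any(kill_p)) {
      alive_p[kill_p] <- FALSE
      changed <- TRUE
    }
    if (!any(alive_p))
      stop("all replicate pairs masked at RR threshold ", rr,
           ": no basis for reliability scoring")
    # step 2: bin reliability over surviving pairs
    n_rep  <- colSums(ind$repro[alive_p, , drop = FALSE])
    n_un   <- colSums(ind$unamb[alive_p, , drop = FALSE])
    n_11   <- colSums(ind$is11[alive_p, , drop = FALSE])
    n_00   <- colSums(ind$is00[alive_p, , drop = FALSE])
    br_x <- ifelse(n_un > 0, n_rep / n_un, NA_real_)
    low_br <- is.na(br_x) | br_x <= br + eps
    no_11  <- n_11 == 0
    all_00 <- n_un > 0 & n_00 == n_un
    if (!mask_all_absent_bins)
      no_11 <- no_11 & !all_00   # retain pure shared-absence bins
    kill_b <- alive_b &
      (low_br | no_11 | (mask_all_absent_bins & all_00))
    if (any(kill_b)) {
      alive_b[kill_b] <- FALSE
      changed <- TRUE
    }
    # step 3: bin-distance check among survivors (permanent)
    if (bd > 0 && any(alive_b)) {
      hit <- bin_distance_mask(matrix, names(alive_b)[alive_b], bd)
      if (length(hit)) {
        alive_b[hit] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  surv <- subset_table(table, pairs = alive_p, bins = alive_b)
  r_b <- tryCatch(bonin_error(surv, count_ambiguous = count_ambiguous),
                  error = function(e) NA_real_)
  r_j <- tryCatch(jaccard_error(surv), error = function(e) NA_real_)
  structure(
    list(br_threshold = br, rr_threshold = rr, bd = bd,
         masked_bins = names(alive_b)[!alive_b],
         masked_pairs = names(alive_p)[!alive_p],
         r_bonin = r_b, r_jaccard = r_j,
         n_bins_remaining = sum(alive_b),
         n_pairs_remaining = sum(alive_p),
         iterations = iterations),
    class = "mask_result")
}

#' Iterative masking of unreliable bins and replicates to a fixpoint
#'
#' One pass of the masking loop at a fixed pair of reliability
#' thresholds. Each iteration (1) masks replicate pairs with
#' \eqn{RR_y \le RR} (an undefined RR also masks), then (2) masks bins
#' with \eqn{BR_x \le BR}, bins with no `(1,1)` pair, bins whose
#' unambiguous states are all `(0,0)` (by default), and bins with
#' undefined BR — all recomputed over the current survivors — then (3)
#' masks bins violating the bin-distance criterion. Because masking a
#' pair or bin changes the other criterion's denominators, the loop
#' repeats until an iteration masks nothing; termination is guaranteed
#' since masks only grow over a finite set. Mismatch error rates are
#' finally computed on the surviving sub-table.
#'
#' @inheritParams classify_pairs
#' @param br,rr inclusive masking thresholds in \[0, 1\].
#' @param bd bin-distance threshold in bases, in \[0, 1).
#' @param mask_all_absent_bins see [thresholds()].
#' @param count_ambiguous see [bonin_error()].
#' @return A `mask_result`: thresholds used, `masked_bins`,
#'   `masked_pairs`, both error rates over the survivors,
#'   `n_bins_remaining`, `n_pairs_remaining`, `iterations`.
#' @export
mask_fixpoint <- function(matrix, reps, br, rr, bd = 0,
                          mask_all_absent_bins = TRUE,
                          count_ambiguous = FALSE) {
  table <- classify_pairs(matrix, reps)
  mask_fixpoint_table(table, matrix, br, rr, bd,
                      mask_all_absent_bins, count_ambiguous)
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf(
    "Mask result (BR=%.2f, RR=%.1f, BD=%.2f): %d bin(s) and %d pair(s) masked in %d iteration(s)\n",
    x$br_threshold, x$rr_threshold, x$bd,
    length(x$masked_bins), length(x$masked_pairs), x$iterations))
  cat(sprintf("  surviving: %d bins, %d pairs; r_Bonin = %s, r_Jaccard = %s\n",
              x$n_bins_remaining, x$n_pairs_remaining,
              format(x$r_bonin, digits = 4),
              format(x$r_jaccard, digits = 4)))
  invisible(x)
}

#' Apply a mask to the complete character matrix
#'
#' Reliability is scored on replicates only, but masking is applied to
#' the full matrix of all sampled individuals: masked bins are removed
#' everywhere. Replicate profiles whose pair was masked can either be
#' dropped as duplicates (default: only the second profile of each
#' masked pair is removed, keeping one profile of the individual),
#' dropped entirely, or retained.
#'
#' @param matrix the complete [aflp_matrix()] (all individuals, not only
#'   replicates).
#' @param result a `mask_result` derived from this matrix's bins.
#' @param reps the [replicate_set()] used to derive `result`; needed to
#'   resolve masked pair IDs to sample IDs (may be omitted when
#'   `drop_masked_replicates = "none"`).
#' @param drop_masked_replicates `"duplicate"` (drop the second profile
#'   of each masked pair), `"both"` (drop both profiles) or `"none"`.
#' @return The masked `aflp_matrix`.
#' @export
apply_mask <- function(matrix, result, reps = NULL,
                       drop_masked_replicates = c("duplicate", "both",
                                                  "none")) {
  drop_masked_replicates <- match.arg(drop_masked_replicates)
  unknown <- setdiff(result$masked_bins, bin_ids(matrix))
  if (length(unknown))
    stop("mask references bin(s) absent from the matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  keep_b <- setdiff(bin_ids(matrix), result$masked_bins)
  keep_s <- sample_ids(matrix)
  if (drop_masked_replicates != "none" && length(result$masked_pairs)) {
    if (is.null(reps))
      stop("`reps` is required to drop masked replicate profiles")
    pr <- reps$pairs[reps$pairs$pair_id %in% result$masked_pairs, ]
    drop <- if (drop_masked_replicates == "both") c(pr$a, pr$b) else pr$b
    keep_s <- setdiff(keep_s, drop)
  }
  subset_matrix(matrix, samples = keep_s, bins = keep_b)
}
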