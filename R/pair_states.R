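#' Classify replicate pairs into per-bin states
#'
#' For every replicate pair and every bin, the two calls are combined into
#' an ordered state (i,j) with i the call of the first and j the call of
#' the second replicate. There are exactly nine states: `(0,0)` and
#' `(1,1)` are *reproducible*, `(0,1)` and `(1,0)` are *unreproducible*
#' (a genotyping error in one of the two profiles), and any state
#' containing `?` is *ambiguous* and excluded from all reliability
#' arithmetic.
#'
#' @param matrix an [aflp_matrix()].
#' @param reps a [replicate_set()]; every pair's samples must exist in
#'   `matrix` and at least one pair is required.
#' @return An object of class `pair_state_table`: integer call matrices
#'   `a` and `b` (pairs x bins, `NA` for `?`), `pair_ids`, `bin_ids`,
#'   `bin_size`.
#' @examples
#' m <- aflp_matrix(rbind(A1 = c("0","0","1","1","0","0","1","1","0","0"),
#'                        A2 = c("0","0","1","1","1","1","1","1","0","?")))
#' tab <- classify_pairs(m, replicate_set(cbind("A1", "A2")))
#' pair_states(tab)
#' @export
classify_pairs <- function(matrix, reps) {
  check_replicates(reps, matrix)
  if (nrow(reps$pairs) == 0)
    stop("at least one replicate pair is required")
  ci <- calls_int(matrix)
  a <- ci[reps$pairs$a, , drop = FALSE]
  b <- ci[reps$pairs$b, , drop = FALSE]
  rownames(a) <- rownames(b) <- reps$pairs$pair_id
  structure(list(a = a, b = b,
                 pair_ids = reps$pairs$pair_id,
                 bin_ids = colnames(ci),
                 bin_size = matrix$bin_size),
            class = "pair_state_table")
}

#' @export
print.pair_state_table <- function(x, ...) {
  cat(sprintf("Pair-state table: %d replicate pair(s) x %d bin(s)\n",
              length(x$pair_ids), length(x$bin_ids)))
  cnt <- rowSums(state_counts(x))
  cat("  state counts:",
      paste(sprintf("(%s)=%d", names(cnt), cnt), collapse = " "), "\n")
  invisible(x)
}

#' The nine pair-state labels
#'
#' Ordered as: ambiguous first, then reproducible absences/presences and
#' the two mismatch states.
#' @return Character vector of length nine, e.g. `"0,1"`.
#' @export
pair_state_levels <- function() {
  c("?,?", "0,?", "?,0", "1,?", "?,1", "0,0", "1,0", "0,1", "1,1")
}

#' Pair states as a labelled character matrix
#'
#' @param table a `pair_state_table`.
#' @return Character matrix (pairs x bins) with entries from
#'   [pair_state_levels()].
#' @export
pair_states <- function(table) {
  tok <- function(m) ifelse(is.na(m), "?", as.character(m))
  s <- matrix(paste(tok(table$a), tok(table$b), sep = ","),
              nrow = nrow(table$a),
              dimnames = list(table$pair_ids, table$bin_ids))
  s
}

# logical indicator matrices shared by all reliability arithmetic
state_indicators <- function(table) {
  a <- table$a; b <- table$b
  unamb <- !is.na(a) & !is.na(b)
  list(unamb = unamb,
       repro = unamb & a == b,
       mism  = unamb & a != b,
       is11  = unamb & a == 1L & b == 1L,
       is00  = unamb & a == 0L & b == 0L)
}

#' Per-bin and per-pair state counts
#'
#' `state_counts` tallies, for each bin, the number of replicate pairs
#' in each of the nine states (the per-bin counts N_x(i,j)); with
#' `margin = "pair"` it tallies per replicate pair over bins
#' (M_y(i,j)).
#'
#' @param table a `pair_state_table`.
#' @param margin `"bin"` (columns of the result are bins) or `"pair"`.
#' @return Integer matrix, nine states x bins (or pairs).
#' @export
state_counts <- function(table, margin = c("bin", "pair")) {
  margin <- match.arg(margin)
  s <- pair_states(table)
  lv <- pair_state_levels()
  if (margin == "pair") s <- t(s)
  out <- apply(s, 2, function(col)
    as.integer(table(factor(col, levels = lv))))
  out <- matrix(out, nrow = length(lv),
                dimnames = list(lv, colnames(s)))
  out
}

# subset a pair_state_table to surviving pairs/bins (logical or index)
subset_table <- function(table, pairs = NULL, bins = NULL) {
  ip <- if (is.null(pairs)) seq_along(table$pair_ids) else pairs
  ib <- if (is.null(bins)) seq_along(table$bin_ids) else bins
  a <- table$a[ip, ib, drop = FALSE]
  structure(list(a = a,
                 b = table$b[ip, ib, drop = FALSE],
                 pair_ids = rownames(a),
                 bin_ids = colnames(a),
                 bin_size = if (!is.null(table$bin_size))
                   table$bin_size[ib]),
            class = "pair_state_table")
}

#' Bin reliability
#'
#' The fraction of reproducible states among unambiguous states at one
#' bin across all replicate pairs:
#' \deqn{BR_x = \frac{N_x(0,0)+N_x(1,1)}
#'                  {N_x(0,0)+N_x(1,1)+N_x(0,1)+N_x(1,0)}.}
#' States containing `?` are not considered. `NA` is returned when a bin
#' has no unambiguous state (reliability undefined).
#'
#' @param table a `pair_state_table`.
#' @param bin optional single bin ID or index; default: all bins.
#' @return Named numeric vector of BR values in \[0, 1\] (`NA` =
#'   undefined).
#' @export
bin_reliability <- function(table, bin = NULL) {
  ind <- state_indicators(table)
  num <- colSums(ind$repro)
  den <- colSums(ind$unamb)
  br <- ifelse(den > 0, num / den, NA_real_)
  names(br) <- table$bin_ids
  if (is.null(bin)) return(br)
  if (is.character(bin) && !all(bin %in% table$bin_ids))
    stop("unknown bin: ", paste(setdiff(bin, table$bin_ids), collapse = ", "))
  br[bin]
}

#' Replicate reliability
#'
#' The fraction of reproducible states among unambiguous states for one
#' replicate pair across all (currently unmasked) bins:
#' \deqn{RR_y = \frac{M_y(0,0)+M_y(1,1)}
#'                  {M_y(0,0)+M_y(1,1)+M_y(0,1)+M_y(1,0)}.}
#'
#' @param table a `pair_state_table` (subset to unmasked bins when
#'   scoring mid-masking).
#' @param pair optional single pair ID or index; default: all pairs.
#' @return Named numeric vector of RR values in \[0, 1\] (`NA` =
#'   undefined).
#' @export
replicate_reliability <- function(table, pair = NULL) {
  ind <- state_indicators(table)
  num <- rowSums(ind$repro)
  den <- rowSums(ind$unamb)
  rr <- ifelse(den > 0, num / den, NA_real_)
  names(rr) <- table$pair_ids
  if (is.null(pair)) return(rr)
  if (is.character(pair) && !all(pair %in% table$pair_ids))
    stop("unknown pair: ",
         paste(setdiff(pair, table$pair_ids), collapse = ", "))
  rr[pair]
}

#' Replicate mismatch error rates
#'
#' Two summary error rates over all (unmasked) pairs and bins. The Bonin
#' mismatch rate is the fraction of unreproducible states among all
#' unambiguous states,
#' \deqn{r_{Bonin} = \frac{\sum N(0,1)+N(1,0)}
#'                       {\sum N(0,0)+N(1,1)+N(0,1)+N(1,0)},}
#' while the Jaccard rate drops shared absences `(0,0)` from the
#' denominator,
#' \deqn{r_{Jaccard} = \frac{\sum N(0,1)+N(1,0)}
#'                         {\sum N(1,1)+N(0,1)+N(1,0)},}
#' so that \eqn{r_{Bonin} \le r_{Jaccard}} always. Shared absences are
#' conflict-free by construction, which is why the Bonin denominator can
#' make a matrix look cleaner than it is; the Jaccard rate is the more
#' conservative of the two.
#'
#' @param table a `pair_state_table`.
#' @param count_ambiguous if `TRUE` the Bonin denominator counts all
#'   pair states including ambiguous ones; default `FALSE` (ambiguous
#'   states are never informative about reproducibility).
#' @return Single numeric error rate in \[0, 1\].
#' @export
bonin_error <- function(table, count_ambiguous = FALSE) {
  ind <- state_indicators(table)
  num <- sum(ind$mism)
  den <- if (count_ambiguous) length(ind$unamb) else sum(ind$unamb)
  if (den == 0)
    stop("Bonin error rate undefined: no unambiguous pair state")
  num / den
}

#' @rdname bonin_error
#' @export
jaccard_error <- function(table) {
  ind <- state_indicators(table)
  num <- sum(ind$mism)
  den <- sum(ind$is11) + num
  if (den == 0)
    stop("Jaccard error rate undefined: no (1,1), (0,1) or (1,0) state")
  num / den
}
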