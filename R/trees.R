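#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (Q-criterion join selection
#' with the usual branch-length assignment, as implemented in
#' \pkg{ape}), which recovers the generating tree exactly — topology
#' and branch lengths — whenever the distance matrix is additive.
#' Negative estimated branch lengths, which arise on noisy
#' non-additive input, are recorded and clamped to zero.
#'
#' @param dist a `dist` object or square symmetric matrix with at least
#'   three labels; all entries must be finite.
#' @return An unrooted `phylo` tree (class from \pkg{ape}) with
#'   attribute `n_negative_edges`, the count of clamped branches.
#' @export
neighbor_joining <- function(dist) {
  d <- stats::as.dist(dist)
  if (attr(d, "Size") < 3) stop("need at least three labels")
  if (any(!is.finite(d))) stop("non-finite distances")
  tree <- ape::nj(d)
  neg <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_negative_edges") <- neg
  tree
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Resamples bins (characters) with replacement, rebuilds the NJ tree
#' from each pseudo-matrix, and scores every internal edge of the
#' point-estimate tree by the percentage of replicate trees containing
#' the same bipartition of the leaf set. A replicate whose distance
#' matrix is undefined (e.g. a resample leaving some pair with no
#' jointly scored bin) is skipped and counted in `n_failed`; support
#' percentages are taken over the successful replicates.
#'
#' @param matrix an [aflp_matrix()].
#' @param distance_kind `"neili"` or `"uncorrected"`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; the run is fully reproducible.
#' @return An object of class `supported_tree`: `tree` (the
#'   point-estimate `phylo`), `support` (percentage per internal edge,
#'   named by edge index into `tree$edge`), `n_reps`, `n_failed`.
#' @export
bootstrap_support <- function(matrix, distance_kind = c("neili",
                                                        "uncorrected"),
                              n_reps = 1000, seed = 1) {
  distance_kind <- match.arg(distance_kind)
  if (n_reps < 1) stop("n_reps must be >= 1")
  tree <- neighbor_joining(aflp_distance(matrix, distance_kind))
  nb <- ncol(matrix$calls)
  set.seed(seed)
  boot <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nb, nb, replace = TRUE)
    rep_m <- subset_matrix_cols(matrix, cols)
    tr <- tryCatch(neighbor_joining(aflp_distance(rep_m, distance_kind)),
                   error = function(e) NULL)
    if (is.null(tr)) n_failed <- n_failed + 1L else boot[[r]] <- tr
  }
  boot <- boot[!vapply(boot, is.null, logical(1))]
  if (!length(boot))
    stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  # counts are per internal node of `tree` (first = basal node, whose
  # bipartition is trivial); internal edges are those whose child is an
  # internal node
  ntip <- ape::Ntip(tree)
  internal_edge <- tree$edge[, 2] > ntip
  child_node <- tree$edge[internal_edge, 2]
  support <- 100 * counts[child_node - ntip] / length(boot)
  names(support) <- which(internal_edge)
  structure(list(tree = tree, support = support,
                 n_reps = n_reps, n_failed = n_failed),
            class = "supported_tree")
}

# column-subset that tolerates repeated bins (bootstrap resampling)
subset_matrix_cols <- function(x, cols) {
  calls <- x$calls[, cols, drop = FALSE]
  colnames(calls) <- paste0("c", seq_along(cols))
  aflp_matrix(calls, source_tag = x$source_tag)
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf(
    "NJ tree with bootstrap support: %d leaves, %d internal edge(s), %d/%d replicates used\n",
    ape::Ntip(x$tree), length(x$support),
    x$n_reps - x$n_failed, x$n_reps))
  if (length(x$support))
    cat(sprintf("  support: min %.1f, median %.1f, max %.1f\n",
                min(x$support), stats::median(x$support), max(x$support)))
  invisible(x)
}

#' Bootstrap resolution score of a supported tree
#'
#' Bootstrap supports above 50% are summed and divided by the maximum
#' possible number of internal branches of an unrooted fully binary
#' tree on the same leaves (\eqn{n - 3}), giving a value between 0 and
#' 100 that rewards matrices producing many well-supported edges. With
#' fewer than four leaves there is no internal edge and the score is 0.
#'
#' @param stree a `supported_tree`.
#' @param inclusive if `TRUE`, count supports `>= 50` instead of the
#'   default strict `> 50`.
#' @return Resolution score in \[0, 100\].
#' @export
resolution_score <- function(stree, inclusive = FALSE) {
  n <- ape::Ntip(stree$tree)
  if (n < 4) return(0)
  s <- stree$support
  kept <- if (inclusive) s[s >= 50] else s[s > 50]
  sum(kept) / (n - 3)
}

#' Stemminess of a tree
#'
#' The proportion of total branch length found in internal branches. A
#' low value indicates a star-like tree (terminal branches dominate), a
#' high value a more tree-like, internally structured topology. The
#' measure is invariant under uniform rescaling of all branch lengths.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return Stemminess in \[0, 1\].
#' @export
stemminess <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  total <- sum(tree$edge.length)
  if (total <= 0) stop("zero total branch length")
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  sum(tree$edge.length[internal]) / total
}

#' Variance captured by the leading PCoA axes
#'
#' Classical metric scaling (principal coordinate analysis): squared
#' distances are double-centered and eigendecomposed; the statistic is
#' the percentage of the sum of positive eigenvalues captured by the
#' largest `n_axes` eigenvalues. Negative eigenvalues, which arise for
#' non-Euclidean distance matrices, are excluded from both numerator
#' and denominator and their count is attached as attribute
#' `n_negative_eigenvalues`.
#'
#' @param dist a `dist` object (>= 2 samples).
#' @param n_axes number of leading axes (default 3).
#' @return Percentage in \[0, 100\].
#' @export
pcoa_variance <- function(dist, n_axes = 3) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (n < 2) stop("need at least two samples")
  D2 <- as.matrix(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > sum(abs(ev)) * 1e-12]
  if (!length(pos)) stop("no positive eigenvalue: degenerate configuration")
  top <- utils::head(sort(pos, decreasing = TRUE), n_axes)
  out <- 100 * sum(top) / sum(pos)
  attr(out, "n_negative_eigenvalues") <- sum(ev < -sum(abs(ev)) * 1e-12)
  out
}

#' Re-root a tree on a designated outgroup for display
#'
#' @param tree a `phylo` tree.
#' @param outgroup leaf label(s).
#' @return A rooted `phylo` tree.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Evaluate one character matrix with the full quality suite
#'
#' Computes the column set used to compare candidate matrices: both
#' replicate mismatch error rates (when replicates are supplied),
#' matrix dimensions, the bootstrap resolution score, stemminess of the
#' NJ tree, and the variance captured by the first `n_axes` PCoA axes.
#'
#' @param matrix an [aflp_matrix()].
#' @param reps optional [replicate_set()] for the error-rate columns.
#' @param distance_kind `"neili"` or `"uncorrected"`.
#' @param n_boot bootstrap replicates for the resolution score.
#' @param seed bootstrap seed.
#' @param n_axes PCoA axes.
#' @return A one-row `data.frame` with columns `n_samples`, `n_bins`,
#'   `r_bonin`, `r_jaccard`, `resolution_score`, `pcoa_pct`,
#'   `stemminess`.
#' @export
evaluate_matrix <- function(matrix, reps = NULL,
                            distance_kind = c("neili", "uncorrected"),
                            n_boot = 1000, seed = 1, n_axes = 3) {
  distance_kind <- match.arg(distance_kind)
  r_b <- r_j <- NA_real_
  if (!is.null(reps)) {
    tab <- classify_pairs(matrix, reps)
    r_b <- tryCatch(bonin_error(tab), error = function(e) NA_real_)
    r_j <- tryCatch(jaccard_error(tab), error = function(e) NA_real_)
  }
  d <- aflp_distance(matrix, distance_kind)
  st <- bootstrap_support(matrix, distance_kind, n_reps = n_boot,
                          seed = seed)
  data.frame(n_samples = nrow(matrix$calls),
             n_bins = ncol(matrix$calls),
             r_bonin = r_b, r_jaccard = r_j,
             resolution_score = resolution_score(st),
             pcoa_pct = as.numeric(pcoa_variance(d, n_axes)),
             stemminess = stemminess(st$tree))
}
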