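#' Binary genetic distances between AFLP profiles
#'
#' Both distances treat `?` by pairwise deletion: for each pair of
#' samples only bins with unambiguous calls in both profiles are
#' counted, since matrices retain `?` after concatenation fill.
#'
#' `nei_li_distance()` computes the restriction-fragment distance of
#' Nei and Li: with presence counts \eqn{n_u}, \eqn{n_v} and shared
#' presences \eqn{n_{uv}} over jointly scored bins, the similarity is
#' \eqn{F = 2 n_{uv} / (n_u + n_v)} and the distance \eqn{d = 1 - F}.
#' It is undefined (an error naming the pair) when both profiles are
#' all-absent over their jointly scored bins.
#'
#' `uncorrected_distance()` is the plain mismatch proportion: the
#' number of jointly scored bins with differing calls divided by the
#' number of jointly scored bins.
#'
#' @param matrix an [aflp_matrix()] with at least two samples.
#' @return A `dist` object over the matrix's samples.
#' @examples
#' m <- aflp_matrix(rbind(u = c("1", "1", "0"), v = c("1", "0", "1")))
#' nei_li_distance(m)       # 1 - 2*1/(2+2) = 0.5
#' uncorrected_distance(m)  # 2/3
#' @export
nei_li_distance <- function(matrix) {
  ci <- calls_int(matrix)
  if (nrow(ci) < 2) stop("need at least two samples")
  P <- ci; P[is.na(P)] <- 0L                    # presence indicator
  J <- (!is.na(ci)) * 1L                        # scored indicator
  shared <- P %*% t(P)                          # joint presences
  n_u <- P %*% t(J)                             # presences of u at bins scored in v
  tot <- n_u + t(n_u)
  bad <- tot == 0 & upper.tri(tot)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("Nei-Li distance undefined for pair (",
         rownames(ci)[ij[1]], ", ", rownames(ci)[ij[2]],
         "): no shared fragment presence over jointly scored bins")
  }
  d <- 1 - 2 * shared / tot
  diag(d) <- 0
  stats::as.dist(d)
}

#' @rdname nei_li_distance
#' @export
uncorrected_distance <- function(matrix) {
  ci <- calls_int(matrix)
  if (nrow(ci) < 2) stop("need at least two samples")
  P <- ci; P[is.na(P)] <- 0L
  Q <- 1L - ci; Q[is.na(Q)] <- 0L               # absence indicator
  J <- (!is.na(ci)) * 1L
  n_joint <- J %*% t(J)
  matches <- P %*% t(P) + Q %*% t(Q)
  bad <- n_joint == 0 & upper.tri(n_joint)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("uncorrected distance undefined for pair (",
         rownames(ci)[ij[1]], ", ", rownames(ci)[ij[2]],
         "): no jointly scored bin")
  }
  d <- (n_joint - matches) / pmax(n_joint, 1)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Distance matrix dispatcher
#'
#' @param matrix an [aflp_matrix()].
#' @param kind `"neili"` or `"uncorrected"`.
#' @return A `dist` object.
#' @export
aflp_distance <- function(matrix, kind = c("neili", "uncorrected")) {
  kind <- match.arg(kind)
  if (kind == "neili") nei_li_distance(matrix) else uncorrected_distance(matrix)
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param d a `dist` object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  lab <- formatC(rownames(m), width = max(10, max(nchar(rownames(m)))),
                 flag = "-")
  writeLines(paste(lab, apply(m, 1, function(r)
    paste(sprintf("%.6f", r), collapse = " "))), con)
  invisible(path)
}
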