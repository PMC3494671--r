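# Shared fixtures: build AFLP matrices and replicate declarations from
# raw call matrices, plus an independent brute-force masking oracle.

# matrix + replicate set from two call matrices (rows = pairs)
make_pair_data <- function(a, b, bin_size = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  np <- nrow(a)
  ids1 <- sprintf("p%02d_1", seq_len(np))
  ids2 <- sprintf("p%02d_2", seq_len(np))
  calls <- rbind(a, b)
  rownames(calls) <- c(ids1, ids2)
  colnames(calls) <- sprintf("B%02d", seq_len(ncol(a)))
  list(matrix = aflp_matrix(calls, bin_size = bin_size),
       reps = replicate_set(cbind(ids1, ids2)))
}

# random pair-call matrices with a given missing-call probability
random_calls <- function(n_pairs, n_bins, p_missing = 0.05,
                         p_present = 0.5) {
  matrix(sample(c("0", "1", "?"), n_pairs * n_bins, replace = TRUE,
                prob = c((1 - p_missing) * (1 - p_present),
                         (1 - p_missing) * p_present, p_missing)),
         n_pairs, n_bins)
}

# The Table-style worked example: one replicate pair over ten bins with
# two unreproducible bins and one failed reaction.
worked_example <- function() {
  r1 <- c("0", "0", "1", "1", "0", "0", "1", "1", "0", "0")
  r2 <- c("0", "0", "1", "1", "1", "1", "1", "1", "0", "?")
  make_pair_data(rbind(r1), rbind(r2))
}

# Independent naive re-implementation of the masking loop, written with
# explicit per-cell loops and string states; used only as an oracle.
# Returns list(alive_pairs, alive_bins) or NULL when every pair dies.
naive_fixpoint <- function(a, b, br, rr, bd = 0, sizes = NULL,
                           mask_all_absent = TRUE) {
  np <- nrow(a); nb <- ncol(a)
  alive_p <- rep(TRUE, np); alive_b <- rep(TRUE, nb)
  state <- function(y, x) paste0(a[y, x], b[y, x])
  repeat {
    before <- c(alive_p, alive_b)
    # replicates
    for (y in which(alive_p)) {
      good <- tot <- 0
      for (x in which(alive_b)) {
        s <- state(y, x)
        if (!grepl("?", s, fixed = TRUE)) {
          tot <- tot + 1
          if (s %in% c("00", "11")) good <- good + 1
        }
      }
      if (tot == 0 || good / tot <= rr) alive_p[y] <- FALSE
    }
    if (!any(alive_p)) return(NULL)
    # bins
    for (x in which(alive_b)) {
      good <- tot <- n11 <- n00 <- 0
      for (y in which(alive_p)) {
        s <- state(y, x)
        if (!grepl("?", s, fixed = TRUE)) {
          tot <- tot + 1
          if (s == "11") n11 <- n11 + 1
          if (s == "00") n00 <- n00 + 1
          if (s %in% c("00", "11")) good <- good + 1
        }
      }
      kill <- FALSE
      if (tot == 0 || good / tot <= br) kill <- TRUE
      if (n11 == 0 && !(!mask_all_absent && tot > 0 && n00 == tot))
        kill <- TRUE
      if (mask_all_absent && tot > 0 && n00 == tot) kill <- TRUE
      if (kill) alive_b[x] <- FALSE
    }
    # bin distance
    if (!is.null(sizes) && bd > 0) {
      ord <- which(alive_b)[order(sizes[alive_b])]
      if (length(ord) >= 2)
        for (k in seq_len(length(ord) - 1)) {
          if (abs(sizes[ord[k + 1]] - sizes[ord[k]]) <= bd) {
            alive_b[ord[k]] <- FALSE
            alive_b[ord[k + 1]] <- FALSE
          }
        }
    }
    if (identical(before, c(alive_p, alive_b))) break
  }
  list(alive_pairs = alive_p, alive_bins = alive_b)
}
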