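#' Configuration for the synthetic AFLP matrix generator
#'
#' The generator emulates the error structure that replicated profiles
#' expose in real AFLP studies: a binary genotype signal structured
#' into groups (populations), overlaid with per-bin technical noise.
#' Bins fall into two discrete classes — reliable bins with a small
#' per-call flip probability and unreliable bins with a large one —
#' mirroring the reliable/unreliable dichotomy that reliability-based
#' masking is designed to separate. Replicates are independent
#' re-observations of the same true genotype at the call level.
#'
#' Defaults describe a mid-sized AFLP study: 50 individuals, 200 bins,
#' 10 replicated individuals (20%, comfortably above the recommended
#' >10% replicate coverage), baseline fragment presence 0.5, a 1% flip
#' rate in reliable bins versus 30% in the 20% of bins that are
#' unreliable, and 1% ambiguous calls.
#'
#' @param n_individuals number of individuals.
#' @param n_bins number of size-ordered bins.
#' @param n_replicated number of individuals with a second, replicated
#'   profile (must not exceed `n_individuals`).
#' @param n_groups number of populations; individuals are assigned in
#'   balanced blocks. Alternatively pass explicit labels via
#'   `group_labels`.
#' @param group_labels optional explicit group label per individual
#'   (overrides `n_groups`).
#' @param p_presence baseline probability that a group carries a
#'   fragment at a bin.
#' @param within_group_diversity probability that an individual's true
#'   genotype differs from its group's at a bin.
#' @param epsilon_good per-call flip probability of reliable bins.
#' @param epsilon_bad per-call flip probability of unreliable bins.
#' @param frac_bad_bins fraction of bins that are unreliable.
#' @param dropout probability that an observed call becomes `?`.
#' @param bin_size_start,bin_size_spacing fragment-length grid in
#'   bases.
#' @param seed integer seed; simulation is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_individuals = 50, n_bins = 200,
                              n_replicated = 10, n_groups = 4,
                              group_labels = NULL, p_presence = 0.5,
                              within_group_diversity = 0.05,
                              epsilon_good = 0.01, epsilon_bad = 0.3,
                              frac_bad_bins = 0.2, dropout = 0.01,
                              bin_size_start = 100,
                              bin_size_spacing = 1, seed = 1) {
  probs <- c(p_presence, within_group_diversity, epsilon_good,
             epsilon_bad, frac_bad_bins, dropout)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0, 1]")
  if (n_individuals < 1 || n_bins < 1)
    stop("need at least one individual and one bin")
  if (n_replicated > n_individuals)
    stop("n_replicated cannot exceed n_individuals")
  if (bin_size_spacing <= 0) stop("bin_size_spacing must be positive")
  if (!is.null(group_labels) && length(group_labels) != n_individuals)
    stop("group_labels must have one label per individual")
  structure(list(n_individuals = n_individuals, n_bins = n_bins,
                 n_replicated = n_replicated, n_groups = n_groups,
                 group_labels = group_labels, p_presence = p_presence,
                 within_group_diversity = within_group_diversity,
                 epsilon_good = epsilon_good, epsilon_bad = epsilon_bad,
                 frac_bad_bins = frac_bad_bins, dropout = dropout,
                 bin_size_start = bin_size_start,
                 bin_size_spacing = bin_size_spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an AFLP matrix with replicate pairs and known error rates
#'
#' True genotypes are drawn per group and bin, individualized with a
#' small within-group flip, and each observed profile is an independent
#' noisy read of its individual's true genotype: every call flips with
#' its bin's error probability and is blanked to `?` with the dropout
#' probability. The first `n_replicated` individuals receive a second
#' profile (`<id>_r2`), declared as replicate pairs.
#'
#' @param config a [simulation_config()].
#' @return A list: `matrix` (an [aflp_matrix()] including replicate
#'   profiles), `reps` (a [replicate_set()]), and `truth` with per-bin
#'   `epsilon`, `bad_bins` (IDs of unreliable bins), `groups` (named
#'   label per individual) and `true_genotypes` (individuals x bins
#'   0/1 matrix).
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ni <- config$n_individuals; nb <- config$n_bins
  ind_ids <- sprintf("ind%03d", seq_len(ni))
  bin_lab <- format(config$bin_size_start +
                      config$bin_size_spacing * (seq_len(nb) - 1),
                    trim = TRUE, nsmall = 2)
  sizes <- config$bin_size_start +
    config$bin_size_spacing * (seq_len(nb) - 1)
  groups <- config$group_labels
  if (is.null(groups))
    groups <- paste0("G", sort(rep_len(seq_len(config$n_groups), ni)))
  groups <- as.character(groups)
  names(groups) <- ind_ids
  # bin error classes
  n_bad <- round(config$frac_bad_bins * nb)
  bad <- sort(sample.int(nb, n_bad))
  eps <- rep(config$epsilon_good, nb)
  eps[bad] <- config$epsilon_bad
  names(eps) <- bin_lab
  # group and individual true genotypes
  glev <- unique(groups)
  ganc <- matrix(stats::rbinom(length(glev) * nb, 1, config$p_presence),
                 length(glev), nb, dimnames = list(glev, bin_lab))
  truth <- ganc[groups, , drop = FALSE]
  flip <- matrix(stats::rbinom(ni * nb, 1,
                               config$within_group_diversity), ni, nb)
  truth <- abs(truth - flip)
  rownames(truth) <- ind_ids
  observe <- function(tg) {
    err <- matrix(stats::rbinom(length(tg), 1,
                                rep(eps, each = nrow(tg))), nrow(tg))
    obs <- abs(tg - err)
    mode(obs) <- "character"
    drop <- matrix(stats::runif(length(tg)) < config$dropout, nrow(tg))
    obs[drop] <- "?"
    obs
  }
  prof1 <- observe(truth)
  rownames(prof1) <- ind_ids
  # spread replicated individuals evenly so every group is represented
  rep_idx <- unique(round(seq(1, ni, length.out = config$n_replicated)))
  if (length(rep_idx) < config$n_replicated)
    rep_idx <- seq_len(config$n_replicated)
  rep_ids <- ind_ids[rep_idx]
  calls <- prof1
  reps <- NULL
  if (config$n_replicated > 0) {
    prof2 <- observe(truth[rep_ids, , drop = FALSE])
    rownames(prof2) <- paste0(rep_ids, "_r2")
    calls <- rbind(prof1, prof2)
    reps <- replicate_set(cbind(rep_ids, paste0(rep_ids, "_r2")))
  }
  colnames(calls) <- bin_lab
  mat <- aflp_matrix(calls, bin_size = sizes, source_tag = "simulated")
  list(matrix = mat, reps = reps,
       truth = list(epsilon = eps, bad_bins = bin_lab[bad],
                    groups = groups, true_genotypes = truth))
}

#' Closed-form expected mismatch error rates of a simulation
#'
#' For a bin with flip probability \eqn{\epsilon}, two independent
#' reads of the same genotype disagree with probability
#' \eqn{2\epsilon(1-\epsilon)}. Conditional on both calls being
#' observed, the expected Bonin rate is the bad/good mixture of that
#' mismatch probability (independent of the presence probability,
#' since its denominator counts all unambiguous states). The Jaccard
#' denominator keeps only (1,1) and mismatch states, so its
#' expectation also involves the marginal presence probability of a
#' true genotype. Both are ratios of expectations, the usual large-
#' matrix approximation.
#'
#' @param config a [simulation_config()].
#' @return Named numeric vector `c(bonin = ..., jaccard = ...)`.
#' @export
expected_error_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q <- config$p_presence * (1 - config$within_group_diversity) +
    (1 - config$p_presence) * config$within_group_diversity
  mism <- function(e) 2 * e * (1 - e)
  p11 <- function(e) q * (1 - e)^2 + (1 - q) * e^2
  fb <- config$frac_bad_bins
  mix <- function(f) fb * f(config$epsilon_bad) +
    (1 - fb) * f(config$epsilon_good)
  m <- mix(mism)
  c(bonin = m, jaccard = m / (mix(p11) + m))
}

#' Write a simulated matrix in the CEQ-style dialect
#'
#' Builds the per-bin `Fragments` and `Samples` count rows from the
#' matrix (each `1` call is one fragment of one sample) and optionally
#' inflates the fragment count of selected bins to emulate double
#' peaks, which the CEQ reader pre-masks.
#'
#' @param matrix an [aflp_matrix()].
#' @param path output file path.
#' @param double_peak_bins bin IDs whose `Fragments` count is written
#'   as `Samples + 1`.
#' @return Invisibly, `path`.
#' @export
write_ceq_fixture <- function(matrix, path,
                              double_peak_bins = character()) {
  samp <- colSums(matrix$calls == "1")
  frag <- samp + as.integer(bin_ids(matrix) %in% double_peak_bins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Sample", bin_ids(matrix)), collapse = "\t"), con)
  writeLines(paste(c("Fragments", frag), collapse = "\t"), con)
  writeLines(paste(c("Samples", samp), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix$calls)))
    writeLines(paste(c(sample_ids(matrix)[i], matrix$calls[i, ]),
                     collapse = "\t"), con)
  invisible(path)
}
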