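test_that("threshold configuration enumerates exact decimal grids", {
  thr <- thresholds(br_min = 0.7)
  expect_length(thr$br_grid, 26)
  expect_length(thr$rr_grid, 10)
  expect_equal(thr$br_grid[1], 0.70)
  expect_equal(thr$br_grid[26], 0.95)
  thr1 <- thresholds(br_min = 0.95)
  expect_length(thr1$br_grid, 1)
  expect_error(thresholds(bd = 1), "BD must be between 0 and 1")
  expect_error(thresholds(bd = -0.1), "BD must be between 0 and 1")
})

test_that("bin distance masking hits both members of close adjacent pairs", {
  m <- aflp_matrix(random_calls(2, 3), bin_ids = c("b1", "b2", "b3"),
                   bin_size = c(100.0, 100.1, 102.0))
  expect_setequal(bin_distance_mask(m, bd = 0.15), c("b1", "b2"))
  # zero threshold with distinct sizes: nothing
  expect_length(bin_distance_mask(m, bd = 0), 0)
  # no size information: nothing
  m2 <- aflp_matrix(random_calls(2, 3))
  expect_length(bin_distance_mask(m2, bd = 0.5), 0)
  expect_error(bin_distance_mask(m, bd = 1.2), "BD must be between")
})

test_that("a perfectly reproducible table masks nothing in one pass", {
  set.seed(5)
  calls <- random_calls(5, 8, p_missing = 0)
  # ensure every bin mixes (1,1) with something and has a (1,1)
  calls[1, ] <- "1"
  calls[2, ] <- "0"
  calls[3, ] <- "1"
  d <- make_pair_data(calls, calls)
  res <- mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0.5)
  expect_length(res$masked_bins, 0)
  expect_length(res$masked_pairs, 0)
  expect_equal(res$iterations, 1)
  expect_equal(res$r_bonin, 0)
  expect_equal(res$r_jaccard, 0)
})

test_that("a single bad bin is masked and error rates recover", {
  base <- matrix("1", 4, 5)
  base[1, ] <- "0"  # keep a (0,0) mix so bins are not all-present only
  a <- base; b <- base
  # bin 3: three mismatches, one (1,1) -> BR = 0.25
  a[1:3, 3] <- "0"; b[1:3, 3] <- "1"
  a[4, 3] <- b[4, 3] <- "1"
  d <- make_pair_data(a, b)
  res <- mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0)
  expect_equal(res$masked_bins, "B03")
  expect_equal(res$r_bonin, 0)
  expect_equal(res$n_bins_remaining, 4)
})

test_that("pair masking precedes bin masking within an iteration", {
  # pair 1 is unreliable (RR = 1/3 <= 0.5); once it is masked, every
  # bin scores BR = 1 over the surviving pair and survives. If bins
  # were masked first, bins 1 and 2 (BR = 1/2) would die.
  a <- rbind(c("0", "0", "1"), c("1", "1", "1"))
  b <- rbind(c("1", "1", "1"), c("1", "1", "1"))
  d <- make_pair_data(a, b)
  res <- mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0.5)
  expect_equal(res$masked_pairs, "p01_1|p01_2")
  expect_length(res$masked_bins, 0)
  expect_equal(res$n_bins_remaining, 3)
})

test_that("all-absent bins are masked by default but retainable", {
  a <- rbind(c("0", "1"), c("0", "1"))
  d <- make_pair_data(a, a)
  res <- mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0)
  expect_equal(res$masked_bins, "B01")
  res2 <- mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0,
                        mask_all_absent_bins = FALSE)
  expect_length(res2$masked_bins, 0)
})

test_that("masking an RR threshold that kills every pair is an error", {
  d <- make_pair_data(rbind(c("0", "1")), rbind(c("1", "0")))
  expect_error(mask_fixpoint(d$matrix, d$reps, br = 0.7, rr = 0.5),
               "all replicate pairs masked")
})

test_that("survivors satisfy the masking postconditions exactly", {
  set.seed(101)
  for (k in 1:200) {
    d <- make_pair_data(random_calls(6, 15, p_missing = 0.08),
                        random_calls(6, 15, p_missing = 0.08))
    br <- sample(seq(0.5, 0.9, 0.05), 1)
    rr <- sample(seq(0, 0.6, 0.1), 1)
    res <- tryCatch(mask_fixpoint(d$matrix, d$reps, br = br, rr = rr),
                    error = function(e) NULL)
    if (is.null(res)) next
    tab <- classify_pairs(d$matrix, d$reps)
    alive_p <- setdiff(tab$pair_ids, res$masked_pairs)
    alive_b <- setdiff(tab$bin_ids, res$masked_bins)
    surv <- aflpmask:::subset_table(tab, match(alive_p, tab$pair_ids),
                                    match(alive_b, tab$bin_ids))
    br_x <- bin_reliability(surv)
    rr_y <- replicate_reliability(surv)
    expect_true(all(!is.na(br_x)) && all(br_x > br))
    expect_true(all(!is.na(rr_y)) && all(rr_y > rr))
    cnt <- state_counts(surv, "bin")
    expect_true(all(cnt["1,1", ] >= 1))
    unamb <- colSums(cnt[c("0,0", "1,1", "0,1", "1,0"), , drop = FALSE])
    expect_true(all(cnt["0,0", ] < unamb))
    # fixpoint idempotence: re-masking the surviving data masks nothing
    if (res$n_bins_remaining == 0) next
    msk <- apply_mask(d$matrix, res, d$reps, "both")
    reps2 <- replicate_set(d$reps$pairs[
      d$reps$pairs$pair_id %in% alive_p, 1:2])
    res2 <- mask_fixpoint(msk, reps2, br = br, rr = rr)
    expect_length(res2$masked_bins, 0)
    expect_length(res2$masked_pairs, 0)
  }
})

test_that("the fixpoint agrees with a naive brute-force oracle", {
  set.seed(202)
  n_checked <- 0
  for (k in 1:300) {
    np <- sample(1:4, 1); nb <- sample(1:6, 1)
    a <- random_calls(np, nb, p_missing = 0.15)
    b <- random_calls(np, nb, p_missing = 0.15)
    sizes <- sort(100 + cumsum(stats::runif(nb, 0.05, 1)))
    bd <- sample(c(0, 0.1, 0.3), 1)
    br <- sample(seq(0.3, 0.9, 0.1), 1)
    rr <- sample(seq(0, 0.8, 0.2), 1)
    d <- make_pair_data(a, b, bin_size = sizes)
    res <- tryCatch(mask_fixpoint(d$matrix, d$reps, br = br, rr = rr,
                                  bd = bd),
                    error = function(e) NULL)
    oracle <- naive_fixpoint(a, b, br, rr, bd = bd, sizes = sizes)
    if (is.null(res)) {
      expect_null(oracle)
      next
    }
    n_checked <- n_checked + 1
    expect_equal(setdiff(d$reps$pairs$pair_id, res$masked_pairs),
                 d$reps$pairs$pair_id[oracle$alive_pairs])
    expect_equal(setdiff(bin_ids(d$matrix), res$masked_bins),
                 bin_ids(d$matrix)[oracle$alive_bins])
  }
  expect_gt(n_checked, 100)
})

test_that("identical inputs give identical mask results", {
  sim <- simulate_matrix(simulation_config(n_individuals = 12,
                                           n_bins = 30,
                                           n_replicated = 5, seed = 8))
  r1 <- mask_fixpoint(sim$matrix, sim$reps, br = 0.8, rr = 0.2)
  r2 <- mask_fixpoint(sim$matrix, sim$reps, br = 0.8, rr = 0.2)
  expect_identical(r1, r2)
})

test_that("surviving bin count is non-increasing in the BR threshold", {
  sim <- simulate_matrix(simulation_config(n_individuals = 20,
                                           n_bins = 60,
                                           n_replicated = 8, seed = 13))
  sw <- threshold_sweep(sim$matrix, sim$reps)
  for (rr in unique(sw$grid$rr)) {
    rows <- sw$grid[sw$grid$rr == rr & !sw$grid$failed, ]
    rows <- rows[order(rows$br), ]
    expect_true(all(diff(rows$n_bins) <= 0))
  }
})

test_that("sweep groups identical masked sets into threshold ranges", {
  sim <- simulate_matrix(simulation_config(n_individuals = 20,
                                           n_bins = 80,
                                           n_replicated = 8, seed = 2))
  sw <- threshold_sweep(sim$matrix, sim$reps)
  expect_equal(nrow(sw$grid), 260)
  # two discrete bin-quality classes collapse into a handful of groups
  expect_lte(nrow(sw$groups), 15)
  expect_gte(nrow(sw$groups), 1)
  # every non-failed cell belongs to exactly one group
  expect_true(all(!is.na(sw$grid$group[!sw$grid$failed])))
  # representatives reproduce their group's bin count
  for (i in seq_len(nrow(sw$groups))) {
    rep_res <- sw$results[[sw$groups$representative[i]]]
    expect_equal(rep_res$n_bins_remaining, sw$groups$n_bins[i])
  }
  # emitted matrices obey the emission rule
  em <- emitted_matrices(sw)
  expect_true(all(em$r_bonin < 0.1 & em$n_bins > 5))
})

test_that("apply_mask projects the mask onto the full matrix", {
  sim <- simulate_matrix(simulation_config(n_individuals = 15,
                                           n_bins = 40,
                                           n_replicated = 6, seed = 4))
  res <- mask_fixpoint(sim$matrix, sim$reps, br = 0.8, rr = 0.3)
  out <- apply_mask(sim$matrix, res, sim$reps, "none")
  expect_equal(ncol(out$calls),
               ncol(sim$matrix$calls) - length(res$masked_bins))
  expect_equal(nrow(out$calls), nrow(sim$matrix$calls))
  # duplicate-profile dropping removes one sample per masked pair
  if (length(res$masked_pairs)) {
    out2 <- apply_mask(sim$matrix, res, sim$reps, "duplicate")
    expect_equal(nrow(out2$calls),
                 nrow(sim$matrix$calls) - length(res$masked_pairs))
  }
  # empty mask is the identity on the calls
  empty <- res; empty$masked_bins <- character()
  empty$masked_pairs <- character()
  expect_identical(apply_mask(sim$matrix, empty, sim$reps)$calls,
                   sim$matrix$calls)
  bad <- res; bad$masked_bins <- "no-such-bin"
  expect_error(apply_mask(sim$matrix, bad, sim$reps), "absent")
})
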