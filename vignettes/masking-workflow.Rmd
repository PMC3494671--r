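---
title: "Replicate-based masking of AFLP character matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-based masking of AFLP character matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpmask)
```

## The model

AFLP genotyping yields anonymous dominant markers: a sample either shows
a fragment in a size bin (1) or it does not (0). Unlike a sequencing
read, a call carries no internal quality signal, so the only direct
measurement of scoring reliability is *reproducibility*: when the same
DNA source is amplified and run twice, a trustworthy marker should give
the same call twice. This package treats replicate pairs as the unit of
evidence. Every pair is transformed, bin by bin, into one of nine ordered
states; `(0,0)` and `(1,1)` are reproducible, `(0,1)` and `(1,0)` are
genotyping errors in one of the two profiles, and any state containing
`?` (failed reaction, missing concatenation fill) is ambiguous and
carries no information about reliability, so it is excluded from every
denominator.

Three criteria drive masking:

* **Bin reliability** `BR_x`: the reproducible fraction of unambiguous
  states at bin *x* across pairs. A low value flags a bin whose peaks are
  called inconsistently — typically size-homoplasic or weak-intensity
  markers.
* **Replicate reliability** `RR_y`: the same fraction for pair *y* across
  bins. A low value flags a failed replicate experiment rather than bad
  markers; removing it prevents one poor DNA extraction from condemning
  many bins.
* **Bin distance** `BD`: capillary sizing is reproducible only to a
  fraction of a base, so two bins whose size centers differ by no more
  than the sizing standard deviation are plausibly one allele split in
  two; both are masked.

Masking one pair changes every bin's denominator and vice versa, so the
procedure iterates — pairs, then bins, then the distance check — until a
full pass masks nothing. Termination is guaranteed because masks only
grow over a finite set. Two further bin rules apply during the bin step:
a bin with no `(1,1)` pair at all is masked (a marker never reproducibly
present is indistinguishable from background noise), and by default a bin
showing only `(0,0)` states is masked as well, because shared fragment
absences are conflict-free yet particularly homoplasy-prone; they deflate
the apparent error rate without contributing reliable signal. The mask
derived from replicates is then projected onto the complete matrix of all
sampled individuals.

The method's central assumption is that the replicated individuals are
*representative* of the whole data set — reliability is only measured
where replicates exist. A replicate fraction above 10% of individuals is
the working minimum; the synthetic-data experiments below use more.

## Thresholds and the sweep

All reliability comparisons are inclusive (`BR_x <= BR`, `RR_y <= RR`
mask), and a bin or pair whose reliability is undefined — no unambiguous
state left — is masked: there is no evidence of reproducibility.
Because no single threshold pair is optimal a priori, `threshold_sweep()`
explores BR from a user minimum (default 0.7) to 0.95 in steps of 0.01
crossed with RR from 0.0 to 0.9 in steps of 0.1: 26 × 10 = 260 fixpoint
runs at the defaults. A run is *emitted* as a candidate matrix when its
selected mismatch error rate (Bonin by default) is strictly below 0.1 and
strictly more than 5 bins survive. Many grid cells converge to identical
masked sets; the sweep reports one representative per distinct set,
labelled by the BR and RR ranges that produced it, which is why a 260-cell
grid typically yields only a handful of candidates.

Two mismatch error rates summarize a table. The Bonin rate divides
mismatches by all unambiguous states; the Jaccard rate drops `(0,0)` from
the denominator and is therefore never smaller — a matrix rich in shared
absences can look deceptively clean under the Bonin rate. Both are
reported everywhere; the emission metric is selectable.

Choosing among emitted candidates is deliberately left to the user. The
quality suite computes, per candidate: both error rates, a
neighbor-joining tree on Nei-Li or uncorrected binary distances, a
nonparametric bootstrap resolution score (supports above 50% summed and
divided by the maximal internal-branch count `n - 3`), stemminess (the
internal fraction of total branch length; low values mean star-like
trees), and the percentage of variance captured by the first three
principal-coordinate axes. Masking tends to trade resolution score
(inflated by conflict-free shared absences) for higher stemminess and
PCoA concentration — the error rates and tree shape say *cleaner*, the
resolution score alone does not rank masked against unmasked matrices
fairly.

## Numerical choices

* Threshold grids are generated in integer hundredths/tenths and divided
  once, so `0.70 + k * 0.01` drift cannot move a grid point; ratio
  comparisons against thresholds add a `1e-9` guard so that an exactly
  attained threshold always masks, matching the inclusive definitions.
* Neighbor joining uses the standard Q-criterion agglomeration (via
  `ape::nj`, which recovers additive matrices exactly — verified in the
  test suite on hand-computed quartets and random additive trees).
  Negative estimated branch lengths are clamped to zero after their count
  is recorded on the tree (`n_negative_edges`).
* Bootstrap support resamples bins with replacement; a replicate whose
  resample leaves some sample pair with no jointly scored bin (or no
  shared presence, for Nei-Li) is skipped and counted, and support
  percentages are taken over the successful replicates.
* Distances use pairwise deletion of `?`, since concatenated
  supermatrices legitimately contain `?` blocks; a pair of profiles with
  no usable joint bins is an error, not a silent zero.
* PCoA eigenvalues below a relative `1e-12` of the spectrum are treated
  as zero; negative eigenvalues (non-Euclidean distance matrices) are
  excluded from numerator and denominator and counted separately. Other
  normalizations exist (e.g. dividing by the sum of absolute values);
  reproduction of any specific legacy tool's percentages is not claimed.
* The resolution score counts supports strictly above 50 by default, with
  an inclusive `>= 50` switch, and always divides by `n - 3` even when
  the tree contains clamped zero-length internal edges.

## Open design decisions

* **Error-rate denominators.** Ambiguous states are excluded from the
  Bonin denominator by default; `count_ambiguous = TRUE` provides the
  variant that counts all states, since legacy scripts differ on this
  point and the choice shifts the rate by the missing-data fraction.
* **Masked replicates in output matrices.** When a pair is masked, the
  default drops only the duplicate (second) profile from written
  matrices, keeping one profile of the individual — consistent with a
  one-taxon reduction per masked pair. Dropping both profiles, or
  keeping everything, are explicit options.
* **Bin-distance scope.** The distance check compares adjacent bins in
  size order among currently unmasked bins. For thresholds below the
  inter-bin spacing this equals the all-pairs check; it is re-evaluated
  each iteration and its masking is permanent.
* **All-absent bins.** With `mask_all_absent_bins = FALSE`, a bin whose
  unambiguous states are all `(0,0)` is exempted from the no-`(1,1)`
  rule; the default masks it.
* **Concatenation and sizes.** Multi-primer matrices are concatenated
  with `?` fill and source-namespaced bin IDs. Size centers are kept only
  if they remain strictly increasing across the junction; otherwise they
  are dropped and the bin-distance criterion should be applied per primer
  combination before concatenation.

## What the generator emulates — and what it does not

`simulate_matrix()` draws group-level genotypes (Bernoulli presence per
bin), individualizes them with a small within-group flip, and observes
each profile independently: every call flips with its bin's error
probability and blanks to `?` with a dropout probability. Bad bins are a
discrete class with a high flip rate — matching the reliable/unreliable
dichotomy the masking criteria are built to separate and making
selectivity measurable against ground truth. Replicates are independent
re-observations at the call level; re-amplification and re-extraction are
not distinguished.

The generator's defaults define the study conditions used throughout the
tests: 50 individuals, 200 bins, 10 replicated individuals (20%), presence
probability 0.5, flip rates 0.01/0.30 for good/bad bins, 20% bad bins, 1%
dropout, sizes on a 1-base grid. Closed-form companions exist for the
error rates: two independent reads disagree with probability
2ε(1 − ε), so the expected Bonin rate is the class mixture of that
quantity (independent of presence probability), and the Jaccard
expectation adds the expected `(1,1)` share to its denominator. The test
suite verifies observed rates against these expectations within 3σ
binomial tolerances at 20 pairs × 200 bins for ε = 0.02, 0.05 and 0.10.

One experiment deliberately deviates from the default replication level.
Bin-class *selectivity* — at least 90% of bad bins and at most 10% of
good bins masked in the largest emitted matrix — is a statement about
binomial tails: a bad bin with flip rate 0.3 has reproducibility
1 − 2·0.3·0.7 = 0.58, and with *n* pairs it escapes the `BR ≤ 0.70` mask
when at least ⌊0.7n⌋ + 1 of its states are reproducible. At the default
10 pairs that escape probability is 0.137, so the 90% bound fails *in
expectation*; at 40 pairs it is 0.043, putting the bound roughly 3σ below
the expected masked fraction over 90 bad bins. The selectivity
experiments therefore simulate 80 individuals, 300 bins and 40 replicate
pairs — a power calculation, not a tuned constant.

What is *not* simulated: electrophoretic mobility, peak heights, bin
width definition and size homoplasy. These upstream processes are too
poorly characterized to simulate faithfully, which is exactly why the
package starts from an exported presence/absence table. Passing tests on
synthetic data therefore demonstrate that the masking arithmetic and its
selectivity behave as designed under the stated error model — not that
any particular flip rate describes a given real instrument.

## Problem sizes and runtime

The fixpoint is vectorized over the pair × bin indicator matrices, so a
full 260-cell sweep on 40 pairs × 300 bins runs in about a second. The
test suite keeps bootstrap counts at 50–400 replicates and the
reproducibility experiments at up to 50 pairs × 200 bins; the acceptance
script uses 300 bootstrap replicates for the quality suite. These sizes
were chosen as comfortable desk-scale experiments; all statistics scale
to the conventional 1000 bootstrap replicates unchanged.

## Limitations

* Reliability is only measurable where replicates are; the mask inherits
  any unrepresentativeness of the replicate sample.
* The method selects *markers*, it does not correct calls or impute `?`.
* Threshold choice among emitted candidates remains a judgment call; the
  quality suite informs it but no single criterion is optimized.
* The two input dialects are documented simplifications of commercial
  export layouts; delimiter and count-row names are configurable, exotic
  variants may need external reshaping first.
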