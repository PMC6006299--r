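---
title: "Crossover mapping from low-coverage backcross sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover mapping from low-coverage backcross sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiomapr)
```

## The problem

In a BC1 population — an F1 hybrid backcrossed to one parent — every
individual carries exactly one recombinant gamete from the hybrid's
meiosis.  Along each chromosome the individual is either homozygous for
the recurrent parent (HOM) or heterozygous (HET), at an expected 50:50
ratio per marker, and every HOM↔HET transition marks a meiotic crossover
(CO).  Genotyping a few hundred individuals by whole-genome sequencing at
~1.5× coverage gives millions of informative SNPs, but at any one SNP most
individuals have 0–3 reads: single-marker genotype calls are unreliable
(a heterozygous marker covered by two reads shows only one allele half the
time), and roughly 1 in 100 reads is simply wrong.  The inference problem
is to locate each gamete's handful of crossovers to the precision of the
flanking SNPs despite this sparsity.

`meiomapr` implements the two-stage solution used in low-coverage CO
mapping, the downstream recombination-landscape statistics, and a
synthetic-data generator that makes every stage testable against known
ground truth.

## Crossover inference model

**Stage 1 — segmentation.**  For each individual, alternate-parent allele
frequencies are computed in non-overlapping 200-kbp bins.  A HOM segment
has a bin frequency near the read error rate; a HET segment sits near 0.5.
Candidate genotype breakpoints are the mean shifts of this series, found
by exact penalized least-squares changepoint detection
(`changepoint_fit()`): dynamic programming minimizes the residual sum of
squares plus a per-changepoint penalty.  This optimizes the same
piecewise-constant objective that mean-shift segmentation tools target,
but deterministically and in a form that can be verified against
exhaustive search (the unit tests compare against brute-force single- and
double-split enumeration).  The default penalty is `3 * sigma^2 * log(n)`
with `sigma` estimated robustly from successive differences
(`mad(diff(y))/sqrt(2)`, floored at `1e-3` so that noise-free steps are
still found).  The constant 3 is deliberately conservative: a HOM↔HET
shift moves the mean by ~0.5 while bin-level noise is ~0.03 at study
coverage, so detection power is not at stake, and the larger penalty
suppresses spurious candidates (which would only cost HMM time anyway).

**Stage 2 — HMM refinement.**  All SNPs in a 10-Mbp window centered on
each candidate are decoded by a two-state hidden Markov model
(`hmm_posterior()`):

* **Emissions.**  At a marker with depth $d$ and alternate count $a$:
  $P(a \mid \mathrm{HOM}) = \varepsilon^a (1-\varepsilon)^{d-a}$ and
  $P(a \mid \mathrm{HET}) = 0.5^d$, with $\varepsilon$ the per-read
  miscall rate (default 0.01).  Zero-depth markers emit likelihood 1 in
  both states — they are uninformative, not missing, so reported intervals
  stay anchored to real marker coordinates.
* **Transitions.**  Over an inter-marker gap of $d$ bp the switch
  probability is $\tfrac12(1 - e^{-2\tau d})$ — the two-state chain whose
  switch intensity is $\tau$ per bp, saturating at 1/2 over long gaps.
  The prior $\tau$ is the expected number of transmitted COs per gamete
  divided by genome length; after a first calling round $\tau$ is
  re-estimated from the observed call count and calling is repeated once
  (two rounds total), which breaks the circularity between the prior and
  the call rate without iterating to an unstable fixed point.
* **Decoding.**  Posteriors come from scaled forward–backward recursions;
  $P(\mathrm{HOM}) + P(\mathrm{HET}) = 1$ at every marker by construction,
  and the test suite verifies the posteriors against exhaustive
  enumeration over all $2^n$ state paths for windows of up to 10 markers
  (agreement to $10^{-12}$).

**Interval placement.**  A CO is located where the posterior $P(\mathrm{HET})$
crosses 0.5.  The *reported* interval, however, is anchored at the nearest
covered marker on each side whose posterior for its decoded state reaches
`min_posterior` (default 0.99).  This conservative anchoring matters at
1.5× coverage: a truly heterozygous flanking marker covered by a single
reference read has $P(\mathrm{HET}) \approx 1/3$, so the raw 0.5 crossing
routinely drifts one or two markers past the true CO.  Anchoring at
confidently decoded markers widens the interval slightly (a few markers)
but keeps the true CO inside the reported interval in >99% of calls —
resolution is traded for correctness, never the reverse.  Exact posterior
ties at 0.5 anchor nothing, which also widens rather than misplaces.
Candidates whose window decodes to a single state are dropped, and
duplicate calls from overlapping windows are merged.

A known blind spot is shared with any binned segmentation approach: two
COs inside a single 200-kbp bin (or one bin pair) cancel and are
invisible.  Recovery statistics are therefore quoted for COs at least
1 Mbp from their same-gamete neighbors; closer pairs are simulated but not
individually resolvable.

## Marker QC

Three composable filters precede calling (`apply_marker_filters()`), each
flagging its own failure reason:

* **Allele frequency** (closed interval 0.1–0.4): across a BC1 population
  the expected alternate-read fraction is ~0.26 (half the individuals HET
  contributing 0.5, plus read error), so markers far outside betray
  mismapping or segregation distortion.  Uncovered markers pass through
  flagged `no-data`.
* **LD concordance**: within 10-Mbp intervals, each marker's hard calls
  (any alt read ⇒ HET — biased at low coverage but adequate for a
  concordance screen; CO inference never uses hard calls) are tested by
  Fisher's exact test against its 20 nearest neighbors; markers are kept
  iff the *median* p-value is below 0.05.  Genuine SNPs travel with their
  neighbors; spurious heterozygosity from structural polymorphism between
  the parental genomes segregates independently (median p ≈ 0.5) and is
  removed.  This screen needs population sizes in the dozens to have
  power; markers alone in an interval are kept by convention.
* **Population depth** (closed bounds): summed depth far above expectation
  marks copy-number differences between the parents; far below marks
  inaccessible sequence.  Bounds default to 0.5–1.5× the observed mean
  depth, scaling the filter to the experiment's own coverage rather than
  hard-coding counts that only apply at one sequencing depth.

The structural-polymorphism defense of the whole pipeline lives here: a
region where all individuals show mixed alleles looks heterozygous to any
per-individual model, so it must be removed population-wise (AF and LD
filters) before the HMM ever sees it.  The tests verify that planted
noise regions produce zero CO calls after QC.

## Landscape statistics

* **Genetic maps** (`interval_recombination()`): per 1-Mbp interval and
  sex, $r$ = recombinant individuals / total (an individual counts once
  per interval, by CO midpoint), converted by the Haldane function
  $d = -50\ln(1-2r)$ cM.  Intervals tile the chromosome even where no
  marker exists, the supplemental-site convention for polymorphism
  deserts.  At small population sizes an interval can saturate
  ($r \ge 0.5$, which has no finite Haldane distance); such intervals are
  clipped to $(n-0.5)/2n$ with a warning rather than aborting the map.
  Male–female interval differences use the likelihood-ratio G test on the
  2×2 recombinant table, with Bonferroni, Benjamini–Hochberg and
  Benjamini–Yekutieli families reported side by side.  Marey tables are
  raw cumulative cM against Mbp.
* **Hotspots** (`window_rates()`): fixed non-overlapping 5-kbp windows
  flagged when the per-gamete CO rate is at least 5× the genome average
  (inclusive).  A fixed tiling, not a sliding window, because sharing
  statistics count discrete sites and sliding windows would inflate
  overlap.  Sharing is reported as shared/union; the male–female rate
  correlation is computed at the union of hotspot sites, optionally
  restricted to the strongest decile ranked by `max(male fold, female
  fold)`.
* **Bootstrap representativeness** (`bootstrap_correlation()`): sites are
  resampled with replacement (B = 1000), the correlation recomputed, and
  two p-values reported: `p_count`, the fraction of replicate correlations
  above the empirical one, and `p_z`, the matching one-sided normal tail
  $P(R^* > R_{emp})$.  Both sit near 0.5 when the empirical value is
  representative of the sampling distribution.  The one-sided form is
  deliberate: a two-sided Z of the empirical value against the replicate
  mean would be ≈1 for a representative value, which is not how this
  diagnostic is used.
* **Context profiles** (`anchored_profile()`, `scaled_region_profile()`):
  metaplots of CO density or chromatin signal in 50-bp bins over ±2 kbp
  around strand-oriented anchors (TSS, TTS, or CO midpoints), and
  length-normalized 100-bin profiles over regions such as knobs or
  chromosome ends (30 bins for nucleosome tracks, whose profiles are
  noisier).  Peaks are the argmax of a 3-bin moving average refined by
  parabolic interpolation: sub-bin continuity is required for the
  bootstrap peak test, since bin-quantized peaks make replicate
  distributions degenerate.  `profile_peak_test()` bootstraps each
  group's anchors, recomputes peaks, and applies a two-sided Z test to the
  replicate peak-difference distribution against zero.
  `random_placement_test()` compares observed nearest-feature distances
  against uniform random placement with a two-sided
  Mann–Whitney–Wilcoxon test; the mappable genome is taken as the whole
  assembly (the simulator has no gaps, and real gap exclusion is a
  preprocessing concern).

## The simulator, and what it does not emulate

`sim_config()` fixes the study conditions: Poisson marker placement at
1 SNP/kbp, Poisson read depth at 1.5× with symmetric per-read error 0.01,
genome-wide Poisson CO counts per meiosis apportioned by chromosome
length with optional per-chromosome obligate CO, transmission of each CO
to the sampled gamete with probability 1/2 (two of four chromatids are
involved in any one CO — the generative form of the factor-2 conversion
between gamete counts and per-meiosis rates), hotspot intensity folds,
polymorphism deserts, clustered spurious-het noise with optional coverage
multiplier, and chromatin tracks built as a flat baseline plus Gaussian
bumps (sd 150 bp) at CO + offset with per-site jitter (sd 100 bp — without
jitter, bootstrap peak replicates would be degenerate).  Crossover
interference is not simulated by default, matching the no-interference
Haldane analysis model; a gamma-renewal spacing option exists behind
`interference_shape` for sensitivity checks.

What passing tests on these simulations do **not** show: robustness to
alignment artifacts beyond the `alt_bias` abstraction, reference bias,
segregation distortion, non-uniform marker ascertainment, or real
chromatin track autocorrelation.  The simulator's marker density (1/kbp)
is also far sparser than a real 2.9M-SNP map, which bounds the achievable
interval resolution from below; the fraction of calls at ≤2 kbp reported
on simulations is therefore not comparable to a dense real map.

## Problem sizes and numerical choices

The package's own validation runs at these scales, chosen to exercise the
method at study-like density while staying desk-sized: the recovery
benchmark uses 10 chromosomes × 20 Mbp, 1 marker/kbp, 150 gametes at
1.5×/1% error and ~10 transmitted COs per gamete (≈1450 true COs); hotspot
detection plants ten fold-50 windows under ≈2600 gametes (≥2000 COs);
peak-offset recovery uses 20 simulation seeds × 3 planted offsets
{0, −250, −400} bp with 198 anchor sites each; HMM correctness uses 500
random configurations against exhaustive path enumeration.  The analysis
scripts under `analysis/` run a smaller narrative version (5 × 10 Mbp, 60
gametes per sex).

Other numerical details: forward–backward recursions are scaled (no log
underflow at any depth); Fisher exact p-values sum hypergeometric point
probabilities with the same relative tolerance R's `fisher.test` uses;
half-open binning assigns boundary midpoints to the right-hand window;
leftmost argmax breaks exact profile ties; bootstrap replicates with
zero-variance resamples are redrawn and counted.  All randomness flows
from one integer seed through `derive_seed(seed, stage)`, so any stage can
be re-run from its on-disk inputs bit-for-bit.

## Known limitations

Double COs within a bin pair are invisible (above).  Interval resolution
at 1.5× is several markers wide by design — chromatin-scale peak analyses
(hundred-bp offsets) require either deep coverage or restriction to the
best-resolved CO subset, and the stage-6 analysis script demonstrates how
midpoint jitter at low coverage destroys metaplot peaks.  The LD filter
is underpowered below ~40 individuals and should be disabled for pilot
runs (`filter_use = c("af", "dp")`).  Gene conversion (non-crossover)
events are out of scope entirely.
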