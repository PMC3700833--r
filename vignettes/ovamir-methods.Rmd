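---
title: "Two-library small RNA profiling with ovamir: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-library small RNA profiling with ovamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovamir)
```

## Scope and model

`ovamir` implements the analysis chain used in classic two-library small
RNA sequencing studies of miRNA expression — one pooled library per
biological condition, no replicates — together with the qRT-PCR statistics
used to validate such studies. The motivating design is a comparison of
two deeply sequenced ovary libraries (a sexually immature control and a
mature condition), but every stage is generic.

The chain is:

1. **Preprocess** — FASTQ reads are quality-filtered, 3' adapter-trimmed,
   length-selected to 18–30 nt, collapsed to unique tags, and stripped of
   single-read tags.
2. **Annotate** — tags are classified by exact matching against a
   reference bundle with fixed priority miRNA > rRNA/tRNA/snRNA/scRNA/
   snoRNA > genome > unmatched, and per-miRNA counts are accumulated.
3. **Differential expression** — counts are normalized to reads per
   million (NE), zeros imputed to 0.01, dual-low rows (NE < 1 in both
   libraries) removed, and each miRNA tested with the Audic–Claverie
   exact test; calls require |log2 ratio| ≥ 1 and P ≤ 0.05.
4. **qPCR** — relative expression by 2^−ΔΔCt against a reference assay,
   compared across groups with one-way ANOVA and Duncan's multiple range
   test with letter groupings.

A synthetic-data generator with full ground truth drives the test suite
end to end, so no external download is needed to exercise any stage.

## The exact test

For a transcript observed `x` times in library A (total `N_a` clean
reads) and `y` times in library B (total `N_b`), the Audic–Claverie
model conditions on `x` and gives the null law of `y`:

$$p(y\mid x) = \left(\frac{N_b}{N_a}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_b/N_a)^{x+y+1}},$$

which is a negative binomial with size `x + 1` and success probability
`N_a/(N_a+N_b)`. The two-sided P-value doubles the smaller of the two
inclusive tails at `y` and clips at 1. Numerical notes:

- Both tails are summed in log space (`lgamma` + log-sum-exp); the upper
  tail is summed upward from `y` until terms are negligible rather than
  computed as `1 − F(y−1)`, which loses all precision for P-values in the
  `1e-100` range that deep libraries routinely produce.
- The result is floored at the smallest positive normal double; a
  reported 0 would otherwise make `alpha = 0` configurations call
  everything at the boundary.
- The doubled-min-tail statistic is unimodal in `y` with its peak at the
  discrete crossover of the two tails, adjacent to (but not exactly at)
  the null expectation `(x+1) N_b/N_a`; swapping which count is
  conditioned on shifts each tail by one pmf mass, so the two
  orientations agree only up to that boundary term. The tests assert
  these discrete versions of symmetry and monotonicity.

The test is defined on raw integer counts. The 0 → 0.01 NE imputation
exists solely to keep log2 ratios finite; it never enters the test.

Fold-changes are reported as magnitudes `2^|log2 ratio|` with a separate
up/down direction relative to the control library, which is the only
reading consistent with published tables that print values above 1 under
both directions. Display rounds to 4 significant figures. A
Benjamini–Hochberg FDR column is emitted for modern eyes but plays no
role in calling, matching the original procedure's raw-P threshold.

## Preprocessing decisions

The source procedure names its filters ("low-quality sequences, empty
adaptors and single-read sequences") without defining them, so the
following are pinned here:

- *Low quality* means mean Phred below 20 (configurable). Reads are
  filtered before trimming so the reject ledger attributes each read to
  exactly one cause.
- *Single-read sequences* are unique tags with count 1, dropped after
  collapsing — the common practice in small-RNA pipelines of that
  generation.
- Reads with no detectable adapter are rejected by default (the insert
  cannot be delimited); `keep_no_adapter = TRUE` keeps them whole.
- Filter order is fixed: quality → adapter trim → length window →
  collapse → singleton drop. The order matters only for reject
  attribution; the conservation identity
  `raw_total = clean_total + Σ rejects` holds exactly in every run and is
  asserted by the test suite on every simulated library.

Adapter trimming takes the leftmost full-adapter match, falling back to
the longest adapter-prefix suffix of the read of at least `min_overlap`
(default 6) bases, which handles inserts long enough to truncate the
adapter at the read end.

## Annotation decisions

Exact substring matching replaces heuristic genome alignment: since only
perfect matches are retained downstream anyway, exact matching is
deterministic, dependency-free, and testable against a brute-force
oracle (the suite checks agreement on generated bundles). The priority
ordering (miRNA first, then ncRNA classes, then genome) gives each tag
exactly one category, so category totals partition the clean reads — the
second invariant asserted on every run. For perfect matches this is
equivalent to the publication-style order (map to genome, discard ncRNA,
then match the miRNA registry).

A tag counts as miRNA when it equals a mature or star sequence or lies
entirely inside an annotated arm of a hairpin. Identical arm sequences
shared by several identifiers resolve to the lexicographically smallest
with a warning. Genome-mapped percentages are rounded half away from
zero to two decimals, the convention of the published summary numbers
(66.14 / 74.59).

## The synthetic-data generator

The generator emulates the structure of the motivating study and is the
package's test harness; its defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_mirnas` | 300 | order of a species' known miRNA complement |
| `abundance_meanlog`, `abundance_sdlog` | log(200), 2 | log-normal read mass spanning tens to hundreds of thousands of reads per miRNA, matching the observed <20 to >10^6 range |
| `library_sizes` | 10^6 each | within the study's 10^5–10^7 clean-read scale while keeping desk runs fast |
| `length_probs` | mode 22 nt, then 23, then 21 | the Dicer-product signature of the published length profile |
| `contamination` | rRNA .08, tRNA .05, snRNA .02, scRNA .01, snoRNA .04, unannotated .40 | leaves a ~40% miRNA fraction and a genome-mapped share near the published 66–75% |
| `star_ratio_meanlog` | log(0.05) | star arms typically well below mature arms |
| `arm_inversion_prob` | 0.02 | occasional star-dominant duplexes (the miR-140-like case) |
| `de_fraction`, `effect_min` | 0.1, 1 | planted effects callable at the |log2| ≥ 1 threshold |
| `dispersion` | 0.05 | negative-binomial counts; see below |
| `adapter` | `TGGAATTCTCGG` | the source does not state its adapter; any fixed 12-mer suffices for round trips |

Counts are negative-binomial rather than Poisson by design: each
condition is a pool of biological material, and the exact test assumes
Poisson sampling of a fixed concentration. Simulating overdispersion
lets the suite demonstrate the known consequence — the type-I error of
per-library testing is controlled under Poisson nulls but inflates under
overdispersion — rather than hide it. A true log2 fold-change `f` is
split symmetrically (`×2^{−f/2}` to the control, `×2^{+f/2}` to the
other library), keeping total composition comparable.

Two calibration details make the generator's *population-level* targets
hold by construction rather than on average: per-length abundance mass
(and contaminant-pool weight mass) is rescaled to the configured length
law, so the 22-nt mode survives the heavy-tailed abundance draw that
would otherwise let one dominant 20-nt miRNA set the library mode; and
contaminant reads are drawn from finite, heavy-tail-weighted fragment
pools so that a realistic share of them recurs and survives the
single-read filter, as degradation products do in real libraries.

What the generator does *not* emulate: sequencing errors, quality-score
variation, 5' adapter artifacts, isomiR heterogeneity, and
multi-locus/paralogue sequence sharing beyond exact duplicates. Passing
tests therefore demonstrate the correctness of the pipeline's logic and
statistics under the stated count model, not robustness to base-call
noise or annotation ambiguity in real data.

## qPCR statistics

ΔΔCt is computed per biological replicate (ΔCt minus the calibrator
group's mean ΔCt) and exponentiated before averaging, because published
"mean ± SE of 2^−ΔΔCt over three replicates" figures require
replicate-level values; the calibrator group goes through the same
formula and equals 1 only in the zero-noise limit. The SE is the sample
SD over replicates divided by √n. With n = 3 the SE carries 2 degrees of
freedom, so a ±2 SE band has roughly 70% coverage (the t 97.5% point at
2 df is 4.3, not 2) — the simulation tests assert the observed coverage
and the estimator's median-unbiasedness rather than a nominal 95%.

Duncan's multiple range test uses least significant ranges
`R_p = q(α_p, p, df) √(MSE/n)` with protection level
`α_p = 1 − (1−α)^{p−1}`, studentized-range quantiles from `qtukey`, the
stepwise containment rule (a non-significant range shields everything
inside it), and the harmonic mean of group sizes when unbalanced (with a
warning). Letters are assigned to maximal homogeneous intervals of the
sorted means; the suite verifies against an all-pairs brute-force
enumeration that groups share a letter exactly when the procedure does
not separate them, at both the 0.05 (lowercase) and 0.01 (uppercase)
conventions. The all-equal degenerate case reports F = 0, P = 1, and a
shared letter, guarding against floating-point residue in the mean
squares.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely from simulation at
desk scale, chosen to finish in minutes while keeping Monte-Carlo error
small: null calibration uses 2,000 Poisson miRNA pairs at library totals
of 10^5; recovery uses 500 miRNAs at 10^6 reads per library with
|log2FC| ≥ 2 planted on 10% (sensitivity is assessed above a true
normalized expression of 50, since no two-library test can recover
effects from a handful of reads); exact-test accuracy is verified against
literal tail summation for every count pair with x + y ≤ 60; end-to-end
FASTQ runs use 40–60 miRNAs at 3–5 × 10^4 reads.

## Known limitations

- One library per condition: the exact test quantifies sampling noise
  only. Biological variance is invisible to it, and the package
  deliberately reproduces that historical design rather than estimating
  dispersion from replicates the design does not have.
- Exact matching cannot tolerate sequencing errors or isomiR end
  variation; counts are conservative relative to alignment-based
  quantification.
- No novel-miRNA discovery, target prediction, or enrichment analysis:
  the scope ends at the differential-expression table and the qPCR
  comparison statistics.
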