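---
title: "Copy-number instability from shallow WGS: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number instability from shallow WGS: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowCNA)
```

This vignette is the package's account of its own methods: the statistical
model each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a choice
had to be made.

## The coordinate frame

Everything downstream lives on a fixed bin grid. A genome is an ordered
list of chromosomes with lengths and centromere midpoints
(`genome_definition()`; `hg19_genome()` ships lengths and centromere
midpoints for chr1–22 and chrX, built in code). `make_bins()` tiles each
chromosome into consecutive windows of `bin_size` base pairs (default
200 kb, the classic resolution at which a few million reads give stable
per-bin counts). Coordinates are 0-based half-open internally and in BED
output; SEG output converts to 1-based inclusive.

Two small rules are worth stating because nothing downstream works without
them being fixed:

* **Terminal partial bins are kept**, with their true width, so bin widths
  sum exactly to the chromosome length. Statistics treat all bins equally —
  no width weighting. At 200 kb the terminal bin is at most 0.006% of a
  chromosome; weighting would complicate every formula for no visible gain.
* **Arm labels** come from the bin midpoint against the centromere
  midpoint; a midpoint exactly at the centromere goes to `q`. The tie rule
  is arbitrary but deterministic, which is all that matters.

## Normalization against a control cohort

For a sample with raw per-bin coverage $x_b$ and a control cohort with
per-bin mean $m_b$ and (n−1 denominator) standard deviation $s_b$:

$$Z_b = \frac{x_b - m_b}{s_b}, \qquad \mathrm{LR}_b = \log_2 (x_b / m_b).$$

The control baseline is the *only* normalization: no GC or mappability
correction is applied, because the shared per-bin baseline already absorbs
any bin-specific capture efficiency common to the batch. Bins where the
controls have zero variance or zero mean carry no standardizable
information and are masked (`NA`, never 0 — a zero would fake a perfectly
average bin).

Numerical choices:

* The **n−1 denominator** for $s_b$ is the conventional sample statistic;
  with cohorts of 10–20 controls the difference from n is immaterial but
  the convention should be stated.
* A **zero count** at a usable bin keeps its Z from the raw 0 (the formula
  is applied verbatim) but takes its log ratio from a 0.5-read pseudocount,
  `log2(0.5 / m_b)`, avoiding `-Inf` while leaving a strong negative
  signal.

## The sample QC gate

FFPE degradation and library failure show up as bin-to-bin scatter rather
than coherent segments. The gate statistic is the **median over
within-chromosome adjacent usable-bin pairs of the absolute difference of
the log2 copy ratio**; a sample passes while the statistic does not exceed
0.38 (a value of exactly 0.38 passes — the rule is strictly-exceeds).

Two readings of the underlying phrase "absolute median deviation of the
copy ratio between adjacent bins" were possible: median of absolute first
differences (chosen — the direct reading, and the median of a folded
distribution is robust), or the median absolute deviation about the median
of the differences. Both are implemented (`qc_sample(method = )`), as is a
natural-log option; the defaults are the chosen reading on log2. Adjacency
is restricted to within-chromosome pairs — a "difference" across a
chromosome boundary measures nothing biological. After masking, adjacency
means *consecutive usable bins*: masked bins do not contribute fabricated
pairs.

Why the default simulation passes the gate comfortably: for negative
binomial counts at depth $\mu = 200$ and dispersion 50 the log2 ratio has
per-bin standard deviation $\approx \log_2(e)\sqrt{1/\mu + 1/50} \approx
0.23$, so the median absolute adjacent difference concentrates near
$0.6745 \cdot 0.23\sqrt{2} \approx 0.22$ — safely under 0.38. The
QC-failure mode multiplies expected counts by independent per-bin jitter
$2^{N(0, 0.5)}$, lifting the statistic to $\approx 0.48$ plus counting
noise, safely above.

## Circular binary segmentation

Segmentation is an original implementation of the circular variant of
binary segmentation, applied per chromosome to the Z profile with unusable
bins dropped (coordinates are mapped back through the grid afterwards —
no signal is fabricated for masked bins).

**Statistic.** For an arc $(i, j]$ of the (circularly viewed) signal
against its complement, the pooled-variance two-sample t statistic. The
scan enumerates all $0 \le i < j \le n$ with both parts at least
`min_seg_bins` (default 3) long, which visits every unordered
{arc, complement} partition exactly once; ties go to smaller $i$, then
smaller $j$. Implementation notes that matter for correctness:

* The scan works on **squared t** with centered prefix sums; the centered
  sum is forced to end at exactly zero so that an arc and its complement
  score bitwise-identically and the tie rule is stable at floating-point
  resolution. The suite checks exact agreement with an exhaustive
  brute-force search that recomputes every arc's t from scratch.
* **Degenerate variance rule**: when the pooled within-variance is
  (numerically) zero, the statistic is $+\infty$ if the two means differ
  and 0 otherwise. Without this rule, noise-free step signals — the
  natural oracle cases — would divide by zero. The thresholds are relative
  (1e−9 of the total sum of squares; mean difference against 1e−9 of the
  signal's scale), so the rule is scale-invariant.

**Significance.** A candidate split is accepted when its permutation
p-value is below `alpha` (default 0.05). The null is the **full shuffle**:
`n_permutations` (default 1000, minimum 100) random permutations of the
tested stretch, each rescanned for its maximal arc statistic, with the
add-one estimator $p = (1 + \#\{T^{\max}_{perm} \ge T_{obs}\}) /
(1 + n_{perm})$. The faster tail approximations of later segmentation
literature are deliberately not used — the full shuffle is the simplest
faithful null, and permutation count is the speed dial. Shuffles draw from
R's RNG, so a single `set.seed()` upstream (or `seg_control(seed = )`)
makes entire fits reproducible.

**Recursion.** An accepted arc contributes its boundaries as cut points;
the recursion descends into each resulting piece (depth bound
`max_depth = 20`, never reached in practice) and stops when a piece is too
short, its best statistic is 0, or its split is not significant. A split
whose edge pieces would fall under `min_seg_bins` is rejected outright
rather than patched. Each final segment records the p-value of the split
that created it (1 for an unsplit chromosome), its usable-bin count, and
its mean Z.

**No pruning by default.** Adjacent segments whose means differ by less
than `merge_tol` can be merged back, but the default is 0 — the output is
the pure recursion. Mature segmentation packages add "undo" heuristics
here; this implementation documents instead that strong events are
occasionally over-split internally (the breakpoints stay correct), and
leaves `merge_tol` as the explicit knob.

**Which signal is segmented.** The Z-score vector, not the log2 ratio:
Z is the standardized quantity the normalization defines, and calling
thresholds are stated in Z units. The log2 ratio is retained for the QC
gate (stated in ratio terms) and reporting; `segment_profile(signal =
"log2_ratio")` exists for users who prefer ratio-space segmentation.

## Calling gains, losses and CIN status

A segment is called a gain at `seg_mean ≥ +3` Z, a loss at `seg_mean ≤ −3`
Z, requiring at least `min_event_bins = 50` bins (10 Mb at the default bin
size). A sample is **CIN-positive** when it has at least one called
segment and its called fraction of the usable genome reaches
`cin_min_aberrant_fraction` (default 0, i.e. any qualifying event
suffices); QC-failed samples carry no calls at all.

This rule is an explicit operationalization — the CIN+/− binary as used in
cohort practice has no single canonical definition. The defaults were
chosen so that whole-arm events (the recurrent lesions in colorectal
adenomas) are CIN-positive while flat diploid profiles are negative; every
threshold surfaces in `call_control()` and is recorded in reports. Two
further conventions:

* An arm is reported **aberrant** when called segments of one direction
  cover more than `arm_coverage_fraction = 0.5` of its usable bins —
  matching the "arm-level gain/loss" language used for such cohorts.
* **chrX is excluded by default** from CIN status and arm summaries: in a
  mixed-sex cohort normalized against mixed-sex controls, X dosage is a
  sex effect, not instability.

Gene-level calls take the call of the overlapping segment with the largest
usable-bin overlap; an exact tie between conflicting calls resolves to
neutral, and a gene lying entirely on masked bins is not evaluable. The
bundled loci (EGFR, MYC, SMAD4, DCC, ERBB2) use canonical hg19 placements —
including DCC and SMAD4 on 18q21, where descriptions in the surrounding
literature occasionally (and inconsistently) place them on 14q.

## The microbial read screen

A read "matches" the reference when some ungapped placement — forward
strand or the read's reverse complement — has Hamming distance at most
`max_mismatches = 1`. `N` never matches, in read or reference (a
conservative rule: missing evidence is a mismatch, so N-rich reads cannot
accumulate spurious hits). A sample is flagged positive when **strictly
more than four** reads match: five qualify, four do not.

The scan is a direct sliding comparison with per-placement early abort,
implemented in C++; a pure-R naive scan serves as the independent oracle in
the tests. At screen-scale references (kilobases to a few hundred
kilobases) the direct scan is effectively instantaneous, so no seed index
is layered on top. Bundled test references are short synthetic sequences
labelled as such; real reference genomes are supplied by the user as FASTA.

## Cohort statistics

CIN status against histological subtype is tested with the plain Pearson
chi-square — $\sum (O-E)^2/E$, margins-based expecteds, **no continuity
correction** — via `stats::chisq.test(correct = FALSE)` behind
`pearson_chi_square()`, with expected counts below 5 flagged rather than
warned about. On the published colorectal-adenoma cohort tables this
reproduces the printed p-values (0.049 for the three defined subtypes
against CIN status, χ² ≈ 6.03 on 2 df; 0.197 for sex against subtype) —
and the undetermined-subtype row must be excluded for the former, which is
why `cohort_test()` excludes it by default and records the rows used.
Fisher's exact test is available behind a flag for small-expected tables,
not as the default: the verifiable printed values come from the plain
chi-square.

Percentages are **truncated** to two decimals (`proportion_summary(12, 39)`
= 30.76), matching the convention of the cohort reports this package
mirrors; half-up rounding would print 30.77.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws per-bin counts negative-binomially
($\mathrm{Var} = \mu + \mu^2/\text{dispersion}$) around a per-bin baseline
shared by all samples, log-normal across bins (`bin_effect_sd`, default
0.1 on the natural-log scale). The shared baseline mimics the
mappability/GC structure of real binned coverage — bins differ, but
consistently so across a batch — without modeling GC explicitly. Planted
events multiply the baseline by the purity-diluted copy factor
$\text{purity}\cdot c/2 + (1-\text{purity})$, so a 4-copy event at purity
1 sits at log2 ratio 1.0 and at purity 0.5 at $\log_2 1.5 \approx 0.585$.
A master seed fans out to per-sample substreams, so enlarging a cohort
never reshuffles existing samples.

Defaults are desk-scale: toy genomes of a few hundred bins to the
~15,500-bin hg19 grid, `depth_mean = 200` reads per bin, `dispersion = 50`,
20 controls. Real shallow-WGS at ten million read pairs corresponds to
roughly 650 reads per 200-kb bin — same regime, slightly tighter noise;
the defaults are chosen so that planted whole-arm events at purity 1 sit
at $|\Delta Z| \approx 6$ and the QC gate has clear margins on both sides.

What passing tests on this generator shows: the pipeline's stages are
correct on data satisfying their own assumptions — independent counts,
shared baseline, abrupt events, noise that is either clean or
exchangeable. What it does not show: robustness to GC waves that differ
*between* sample and controls, FFPE fragment-length artifacts, within-bin
mappability dropouts, subclonal mixtures of events, or sequencing-error
structure in the microbial screen beyond planted substitutions. The
generator is a test harness, not an FFPE noise model; no public data
accompanies the cohort it stands in for, so its parameters are chosen for
testability.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the heavier studies at fixed
sizes, chosen as the smallest that make the binomial bounds meaningful:
500 random vectors (n ≤ 40) for brute-force agreement; 100 flat 200-bin
profiles at 1000 permutations for the type-I error bound
($\le \alpha + 3\,\mathrm{SE}$); 100 single-event samples (60-bin events
at $|\Delta Z| \ge 3$, the loss case sitting at the boundary ≈ 3.2) and a
40-sample mixed cohort for recovery; 200 simulations per side of the QC
gate. Event recovery is scored as stated: each planted breakpoint within
±2 bins of a segment boundary and all within-event segments carrying the
planted sign — a strong event that is internally over-split but correctly
bounded counts as recovered, which is the property the downstream calling
rule actually needs (sub-segments of a real arm event still exceed the
length and magnitude thresholds in aggregate only if boundaries are right).

## Known limitations

* No purity or ploidy estimation: calls are in Z units against the control
  cohort, not absolute copies; heavily diluted events shrink toward 0 and
  are missed by design at the default thresholds.
* The control cohort must match the cases' processing batch; no
  cross-batch harmonization is attempted.
* Single-sample segmentation only — no joint multi-sample breakpoints.
* The permutation null assumes exchangeability of bins within a
  chromosome; long-range autocorrelation (waves) inflates the split rate.
* The microbial screen is a counter, not a profiler: no gapped alignment,
  no abundance estimate, and the read set it screens is whatever the
  caller provides.
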