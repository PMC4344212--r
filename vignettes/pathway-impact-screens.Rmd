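---
title: "Pathway impact scoring of multi-readout siRNA screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway impact scoring of multi-readout siRNA screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenpi)
```

## Why pathway-level scoring

A genome-wide siRNA screen delivers, per readout, one noisy measurement per
gene. Gene-level hit calling by score thresholds has two well-known
weaknesses: siRNA off-target activity produces false positives that no
statistical threshold can distinguish from real hits, and variable knock-down
efficacy produces false negatives among genuine regulators. Aggregating over
a pathway changes both error modes. Off-target effects of probes targeting
*different* genes are plausibly independent, so they are unlikely to push a
whole pathway's aggregate score in one direction; and a pathway of genes each
with a small, real effect can reach significance jointly even when no member
passes a gene-level cut. `screenpi` implements this aggregation for screens
with several phenotypic readouts (the motivating application measures cell
viability and four APP cleavage products: Aβ40, Aβ42, sAPPα, sAPPβ).

## The processing model

Measured well intensities are modelled on the natural-log scale as a sum of
the biological signal and three nuisance terms the pipeline removes in fixed
order:

1. **Log transform** — intensities are strictly positive and
   multiplicative noise is the norm for plate readers, so all arithmetic is
   additive on log intensities. The log base is a pure convention (Z* is
   invariant to it as long as one base is used throughout); natural log is
   fixed here.
2. **Viability normalization** — peptide levels scale with the number of
   surviving cells, so each peptide channel has the same well's viability
   log-intensity subtracted (an intensity ratio). The viability channel
   passes through unchanged.
3. **Positional (edge) correction** — plate borders evaporate and warm
   differently, producing reproducible position effects. For every (row,
   column, readout) the pipeline subtracts the across-plate *median* of that
   position's deviation from its plate median. Positions seen on fewer than
   two plates (a trailing partial plate) are left untouched: their
   "positional median" would be the well's own value and subtracting it
   would flatten the plate. The correction can be switched off
   (`process_screen(edge_correct = FALSE)`).
4. **Robust standardization** — every well is scored within its plate and
   readout as `Z* = (Y − median) / (2 × MAD)`, with the raw MAD (no 1.4826
   consistency constant; the factor 2 is part of the score's definition).
   By construction each plate has median(Z*) = 0 and median(|Z*|) = 0.5
   exactly, and Z* is invariant under positive affine transforms of the log
   intensities — plate-to-plate gain and offset differences vanish.
5. **Gene collapse** — probes without a gene assignment are discarded;
   genes measured by several probe pools get the arithmetic mean of their
   pool Z* values (replicated control pools are treated the same way). A
   gene lacking data for a readout is absent (`NA`) there, never zero.

The order matters: edge artifacts estimated before viability normalization
would mix the cell-count component into the positional estimate. A
regression test asserts that permuting steps 2 and 3 changes the output.

## Pathway impact scores and their null

For a set with member scores $Z^*_1,\dots,Z^*_n$ (membership intersected
with the screened genes),

$$\mathrm{Net\ PI} = \frac{\sum_i Z^*_i}{\sqrt n},\qquad
  \mathrm{ABS\ PI} = \frac{\sum_i |Z^*_i|}{\sqrt n}.$$

The $\sqrt n$ denominator keeps the null variance of Net PI approximately
constant in $n$ (a sum of $n$ weakly dependent scores has variance
$\propto n$), so scores of different-sized pathways live on a comparable
scale. Because the normalization of a sum-based set statistic is a genuine
modelling choice, the denominator is exposed as
`denominator = c("sqrt_n", "n", "none")`.

Net PI cancels when a pathway holds both activators and inhibitors of the
readout; ABS PI is computed alongside precisely to catch such mixed-sign
pathways. `abs_pi(z) >= |net_pi(z)|` always, with equality exactly when all
member signs agree.

Significance is assessed against a **size-matched permutation null**: the
same statistic over 10,000 independent draws of $n$ distinct genes from the
scored genes of that readout (draws are size-matched because both statistics'
null distributions depend on $n$; nulls are built per readout because the Z*
distributions differ across readouts). Nulls are cached and shared across
all sets of equal size within a readout, with a deterministic sub-seed per
(readout, size) so a fit is reproducible from a single `seed`. For universes
small enough, `build_null(exhaustive = TRUE)` enumerates every
$\binom{N}{n}$ subset and the p-value becomes an exact proportion — this is
the oracle the sampled null is tested against.

The p-value is the plain proportion of null values at least as extreme as
the observed score — **no pseudo-count** — so p-values lie on the grid
$\{0, 1/M, \dots, 1\}$ and an observed score beyond every draw reports
exactly 0 (volcano exports display such values at $-\log_{10}(1/M)+1$ and
flag them). For ABS PI, "extreme" is the upper tail. For Net PI the default
is two-sided on the magnitude, $p = \#(|\mathrm{null}| \ge
|\mathrm{obs}|)/M$: because the observed and null statistics share a
distribution under the null, this proportion is exactly calibrated at every
level $\alpha$, which the test suite verifies empirically (type-I error
$\approx \alpha$, p-values uniform by Kolmogorov–Smirnov across seeds). The
alternative `net_sided = "signed"` — counting only the tail in the direction
of the observed sign — is offered as configuration, but note that on a
near-symmetric null it concentrates p-values on $(0, \tfrac12)$ and roughly
doubles the rejection rate at any nominal $\alpha$; we therefore do not use
it as the default. A set is flagged significant when either score's p-value
is at or below `alpha` (default 0.01). No multiple-testing correction is
applied — the decision rule is a raw per-readout threshold — but
`summary()` reports the expected false-positive count $\alpha \times$
(number of sets) so the reader can weigh the flag count against it.

## Gene-set collections

Collections arrive as GMT files (`read_gmt()`), or any named list of member
vectors. Processing order is fixed: **intersect** with the screened universe
(all statistics are defined on screened composition), then **size-filter**
to $3 \le n \le 1000$ (inclusive bounds; below 3 a "pathway" is a gene pair,
above 1000 interpretation dissolves), then **merge** sets with identical
screened composition into one entry (name = constituents joined by `" | "`,
provenance kept). Merging must follow intersection — identical composition
is only meaningful on the analysis-ready sets. Identifier matching is exact
string equality on one identifier space; no aliasing is attempted, because
silent symbol mis-mapping is worse than a dropped gene. `coverage_stats()`
reports both the set count and the count of distinct compositions, so either
convention for "number of sets" can be checked.

## The overlap landscape

Pathway databases overlap heavily. To expose redundancy and cross-talk among
the sets significant for a readout, the package builds the symmetric matrix
of overlap coefficients $O_c(A,B) = |A \cap B| / \min(|A|,|B|)$ — 1 whenever
the smaller set is contained in the larger, 0 for disjoint sets — and
clusters its rows with cosine distance and average linkage. Cutting the tree
at a user-chosen $k$ yields the landscape clusters. Choices made where the
procedure is genuinely open:

* **"Cosine-correlation"** is read as cosine distance between rows of the
  $O_c$ matrix; Pearson correlation distance is available as an alternate.
* **$k$ is a required user parameter.** No automatic cut criterion is
  imposed; `landscape_partitions()` reports the partitions over a range of
  $k$ for inspection.
* **Zero rows** (a set overlapping nothing — impossible for $O_c$ matrices
  with their unit diagonal, but reachable for user-supplied matrices) are
  assigned the maximal distance 1 to every other row, so isolated sets merge
  last rather than first.
* **Determinism**: labels are sorted before clustering, so the tree and the
  partition are invariant to input row order and ties break by label order
  on every platform.

Exports are text: the reordered matrix and cluster membership as TSV, the
dendrogram as Newick.

## Cross-readout comparison

`compare_readouts()` classifies every set as significant in both readouts,
one, or neither, at level `alpha` on the Net p-values by default (ABS and
either-mode available) — the tabular form of the familiar
$-\log_{10}p$-vs-$-\log_{10}p$ scatter. `profile_matrix()` assembles Net-PI
profiles (rows: union of sets significant anywhere, a configurable
selection; columns: readouts in screen order), and `cluster_profiles()`
groups them hierarchically. Euclidean distance is the default here, not a
correlation distance: profiles are *signed magnitudes*, and a pathway that
lowers amyloid strongly should not cluster with one that lowers it
negligibly just because the shapes correlate. A set unscorable for some
readout (fewer than 3 members carrying that readout's Z*) is entered as 0
and flagged in the `imputed` attribute rather than dropped, keeping the
matrix complete without inventing signal.

## The synthetic screen generator

`simulate_screen()` exists so that every downstream stage can be tested
against known ground truth. Its model, per well and readout on the log
scale: a channel baseline, a per-plate Gaussian offset (default SD 0.25), a
fixed offset on the border ring (default 0.2), a per-well cell-count factor
(default SD 0.1) entering viability with coefficient 1 and peptide channels
with coefficient `viability_coupling` (default 1 — peptide signal scales
with cell number, which is exactly what viability normalization removes),
and independent Gaussian well noise (default SD 0.3, log-intensity units).
Defaults emulate a 13,500-gene screen on 384-well (16×24) plates with five
channels; the readout list, pool replication (the motivating screen used 3
pools per gene) and all scales are configurable.

Planted pathway effects shift member genes' expected log intensity in the
targeted readouts (peptide channels by default; planting into viability is
the switch for testing the normalization). Shifts are expressed in MAD units
of the per-well noise that survives processing, so that a coherent planted
gene has expected Z* ≈ shift/2: for a peptide channel under viability
normalization the subtraction doubles the noise variance, and the unit
accounts for that. A `sign_mix` fraction of members (chosen at random,
recorded in the ground truth) has its sign flipped — `sign_mix = 0.5`
produces the balanced activator/inhibitor sets that Net PI cancels on and
ABS PI detects.

Two layout decisions matter for interpretation. Pools occupy a row-major
grid, one per well, but gene-to-well assignment is a seed-deterministic
random permutation: real libraries are arrayed independently of pathway
membership, and scattering prevents a planted set from piling onto a single
plate where it would tilt that plate's own median and MAD (and thereby
erase its own signal). And the border offset applies to all channels
equally, as a plate-physics artifact would; viability normalization then
cancels it in the peptide channels, while the positional correction removes
it from viability itself.

What the generator deliberately does **not** model: siRNA knock-down
efficiency, sequence-driven off-target structure (off-target influence is
represented only as independent per-gene noise, mirroring the independence
assumption that justifies pathway aggregation in the first place),
spatially correlated gradients other than the border ring, and
heavy-tailed measurement error. Passing tests on this generator therefore
demonstrate the statistical machinery — calibration, power, invariances —
not robustness to correlated off-target biology.

## Verification, problem sizes, and numerical choices

The test suite checks, among others: exact agreement of sampled permutation
p-values with an independent brute-force enumeration oracle on small
universes; exact per-plate Z* invariants and affine invariance; removal of a
constructed +0.5 border artifact to within ±0.05 log units; type-I error of
both PI modes within the 3σ binomial band of α = 0.01 on a no-effect
13,500-gene, 5-readout screen (500 random sets of sizes 5/20/100);
KS-uniformity of null p-values across 10 seeds (screens of 800 genes, 150
sets, 2,000-draw nulls); monotonicity of detection power over a 3×3 grid of
shift × set size (3,000-gene screens, 100 replicates per cell); ~99% power
on coherent planted pathways (shift = 1 MAD unit, n = 20, 3 pools/gene,
full-size screens) with balanced mixed-sign sets caught by ABS at ~70%
versus ~1% for Net, paired over 200 replicates; and exact recovery of
planted two-block overlap structure at the correct k. These problem sizes
were chosen to exercise genome-scale behaviour while keeping a full test run
in the tens of seconds; `scripts/acceptance.R` re-runs the headline
measurements end-to-end and writes them as JSON.

Remaining numerical conventions, collected: medians of even-sized groups are
midpoint medians (R's default); wells with missing intensity are dropped
before plate statistics; a plate with MAD = 0 or fewer than 4 wells per
readout is a hard error naming the plate; `n_draws` trades p-value
granularity (1/M) against runtime and memory linearly; all hierarchical
clusterings use `stats::hclust` with deterministic, label-order tie-breaking
after canonical sorting.

## Known limitations

* The permutation null conditions on the observed Z* distribution of each
  readout; it does not model inter-gene correlation within real pathways
  under the null, so p-values are calibrated against the "random gene set"
  hypothesis, which is the intended competitive question.
* Gene-level inference is out of scope by design; the package will not
  rank individual genes.
* The edge correction estimates one positional offset per (position,
  readout) across the whole run; screens with batch-dependent positional
  artifacts would need stratified correction before this pipeline.
* Spreadsheet ingestion (`read_gene_scores_xlsx()`) is a thin shim over
  readxl and expects an already tidy gene × readout layout.
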