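---
title: "Classifying parental dominance and non-additive expression in nascent allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying parental dominance and non-additive expression in nascent allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloexpr)
```

## The design and its confounder

The study design `alloexpr` analyses has eight sample groups: a tetraploid
parent (T), a diploid parent (D), one empirical mid-parent mixture (M) per
polyploid line — parental RNAs mixed 2:1 (T:D), matching the genomic dose
the polyploid inherits — and the polyploid itself (H) in two independent
lines at two successive selfed generations, all with two biological
replicates. Mixing happens on the linear transcript-abundance scale
*before* hybridization, so the expected mixture intensity is

\[ M = w_T a_T T + w_D a_D D, \qquad w = \text{mix ratio normalized to 1,} \]

where \(a_T, a_D\) are relative hybridization affinities of the two
parental transcript pools on the shared array. Those affinities are the
design's central confounder: a gene whose D-pool hybridizes poorly looks
"biased toward T" in the polyploid even under perfectly additive
expression. Because the *measured* mixture suffers the identical bias, it
doubles as the control: apparent dominance that the mixture reproduces is
discarded (`excluded_mpv_bias`) rather than interpreted.

## The testing machinery

Probe panels are normalized RMA-style (`rma()`): normexp background
correction, quantile normalization across samples at the probe level, and
per-probe-set median polish, with multiple probe-sets per gene summarized
separately and averaged. Detection (`detect_calls()`) follows the MAS5
convention on raw PM/MM values and is an independent path from
normalization; the expressed universe keeps genes with present calls in
all replicates of at least one group.

Differential tests (`contrast_table()`) are moderated two-group
comparisons. One variance prior \((d_0, s_0^2)\) is fitted per run from
the pooled within-group variances of *all* groups by matching the mean and
variance of \(\log s^2\) with digamma/trigamma identities; within each
(line, generation) cell the gene's variance pools the cell's four groups
(common-variance design, \(d = \sum_g (n_g - 1)\)), stabilizing the
duplicate-array situation. The moderated variance is
\(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\); \(\tilde s^2\) always lies
between \(s^2\) and \(s_0^2\). Significance is raw \(p < \alpha\) with
\(\alpha = 0.05\) and a *strict* inequality — no fold-change floor and no
multiple-testing correction enter the calls (BH-adjusted columns are
emitted for reference only), mirroring how such array studies defined
differential expression. "Statistically equal" is simply
non-significance; the package does not pretend to an equivalence test.

Classification (`classify_patterns()`) then applies, per gene and cell:

* **dominance** — parents differ, H equals exactly one parent, and M does
  not stick to that same parent; biased-to-the-*other*-parent mixtures do
  not exclude, since only same-direction affinity artifacts mimic
  dominance;
* **additivity** — H differs from M, with direction the sign of H − M;
* **non-additive categories** — over-/under-dominance (H beyond both
  parents), the four high/low diploid/tetraploid dominance categories, and
  a residual `other` (e.g. H between the parents but equal to neither).
  Published tables of these categories do not state whether the mixture
  filter was applied inside the non-additive set; by default it is not
  (non-additivity already requires H ≠ M), and
  `mpv_filter_table1 = TRUE` switches it on.

Transgenerational grouping (`assign_groups()`) classifies each flagged
gene as stochastic / heritable / persistent; combinations the three
published groups do not cover (such as both lines at one generation) are
reported explicitly as `shared_other` rather than merged. Overlap
percentages are percent of the two-set *union* — the convention that
reproduces published ratios such as 385/2,085 = 18.5% — and per-line
"average" rows average the two generations' counts while recomputing every
percentage from pooled counts (485+826 over 828+1,642 gives 53.1%, not the
mean of the per-generation percentages).

Enrichment (`enrich()`) is the singular-enrichment procedure: one-sided
Fisher exact tests of target against reference, Benjamini–Hochberg
adjustment ("FDR" is read as the BH procedure; the Hochberg step-up
family-wise variant is available via `adjust = "hochberg"`), stratified by
ontology namespace by default, with terms under five reference genes
flagged `low_support`. The reference list is the analyst's choice — all
expressed genes is the usual one — and annotations are taken as already
propagated to ancestor terms.

## What the simulator emulates

`sim_config()` / `build_truth()` / `simulate_panel()` generate the full
study with planted truth. Defaults encode the study conditions: 11 probes
per set, 2 replicates, 40% parent-divergent genes at ±2.0 log2, noise 0.1
log2, a 2:1 mix ratio, two lines by two generations. Pattern rates default
to a mix dominated by additivity with tetraploid dominance more common
than diploid dominance and over-dominance more common than
under-dominance, echoing the relative abundances such studies report;
persistence defaults to 70% stochastic / 20% heritable / 10% persistent.
Choices a scientist should know about:

* **Biological replicate noise.** Besides per-probe noise, each gene gets
  a replicate-level log2 deviation (`bio_sd_log2`, default equal to
  `noise_sd_log2`) shared across its probes. Eleven probes average
  per-probe noise down to ~0.03 log2; without a transcript-level component
  the within-group variance would be unrealistically tiny and *any*
  systematic normalization wobble would register as significance. Real
  biological replicates vary at the transcript level.
* **Balanced divergence directions.** Exactly half of the divergent genes
  are up in each parent (after honouring direction-forcing dominance
  labels). An imbalance shifts one parent's whole intensity distribution
  and quantile normalization converts that into a spurious global offset
  on every gene's parent contrast; real parental transcriptomes split
  nearly evenly.
* **Identifiable probe affinities.** Per-probe affinities (sd 0.5 log2)
  are median-centered within each probe-set, the same constraint under
  which median polish estimates the set's level; an uncentered common
  shift would be indistinguishable from the gene's expression.
* **Affinity artifacts.** A configurable fraction of divergent, truly
  additive genes get an affinity factor on one parental pool chosen so the
  measured mixture (and hence the additive polyploid) sits exactly at the
  other parent's level, times a small log-normal jitter — the precise
  failure mode the mixture filter exists to catch.
* **Silent genes.** A fraction of genes (default 30%) is
  tissue-silent: background intensity on PM and MM, detectable as absent.
  They are drawn among non-divergent genes so the exact divergent count
  and the pattern rates stay unconfounded.
* **Persistence realization.** Each patterned gene carries one pattern and
  one persistence label: stochastic activates it in one random cell,
  heritable in both generations of one random line, persistent in all
  four; inactive cells are additive. Group shares recovered from the
  planted signatures therefore match the configured rates.

What it does **not** emulate: sequence-dependent hybridization, spatial
array artifacts, batch effects, continuous effect-size spectra (every
divergent gene has the same ±2.0 log2 effect), and homoeolog-resolved
expression — compensating changes between homoeologous copies are
invisible at this resolution, as they are on the real array.

## Numerical choices

* Median polish: tolerance 1e-4, 20 iteration pairs (configurable). With
  even numbers of probes or samples the decomposition is not unique
  (averaged medians); odd-sized blocks have a unique fixed point, which is
  what the oracle tests pin exactly.
* Quantile normalization ties receive the mean of the reference values at
  their rank positions, making the result invariant to row permutation;
  on tied data this intentionally sacrifices exact idempotence and exact
  equality of column multisets, which hold tie-free.
* Detection p-values are exact (a generating-function convolution over
  doubled midranks, equivalent to enumerating all sign assignments,
  including ties) up to 25 informative probes; beyond that a
  continuity-corrected normal approximation with tie correction is used.
  Probe pairs with PM + MM = 0 are dropped; zero discrimination scores are
  dropped per the signed-rank convention.
* The background fit corrects the density mode for the normal+exponential
  convolution's mode shift (σ²α + σz*, with z* the inverse Mills ratio of
  ασ), iterating to self-consistency; when the observed mode density
  exceeds what the pure model allows (a background-dominated spike, the
  regime of arrays with many silent genes) the shift is dropped and the
  spike's peak is the background mean. Zero-variance samples are floored
  with a warning.
* The trigamma equation is inverted by damped Newton iteration; when the
  log-variance dispersion does not exceed the sampling component the prior
  degrees of freedom are unbounded and \(s_0^2\) is the mean variance.
* A p-value exactly at α counts as *not* significant throughout.

## What passing tests show — and what they do not

The test suite validates the kernels against independent brute-force
oracles (exhaustive sign enumeration, log-binomial tail sums, manual
step-up, explicit median sweeps), calibrates the moderated tests on
effect-free simulations, recovers planted variance hyperparameters
(d₀ = 4 within [3.2, 4.8] at 20,000 genes), and recovers planted patterns
on a 10,000-gene study at the default conditions (dominance labels ≥ 80%,
over/under-dominance ≥ 80%, false non-additive calls among additive genes
≤ 5%, artifact genes kept out of the dominance set ≥ 90%). Classifier
recovery is measured on gene-level simulations; the probe-level path is
held to its own contracts (summarized levels within 0.2 log2 of truth for
≥ 90% of genes on divergence-free panels, perfect noise-free
mixture/polyploid agreement, null calibration of the parent and mixture
contrasts).

One limitation deserves emphasis. Quantile normalization forces every
sample onto a common distribution; when 40% of genes differ by a full
±2 log2 between parents and the mixture compresses them, the *shapes* of
the group distributions genuinely differ, and the per-sample monotone maps
introduce deterministic gene-level offsets of order 0.1–0.2 log2 between
groups. These offsets do not shrink with array size, inflate the
polyploid-vs-parent equality tests, and attenuate dominance recovery
through the full probe-level path — a property of quantile normalization
under strong composition differences, not of the classifier, and a caveat
that applies equally to real parent/hybrid designs normalized this way.
Nothing in a passing synthetic suite certifies behaviour on real arrays
with sequence-specific probe chemistry and continuous effect spectra.

## Problem sizes

Simulation-based tests use 2,000–10,000 genes with two replicates — large
enough for stable binomial bounds on recovery rates while keeping the
default suite around a minute of compute; the acceptance script's
probe-level run uses 2,500 genes × 11 probes × 16 arrays. All
randomness flows from a single seed per run; panel and expression
generation derive stage seeds by fixed offsets so the truth table is
byte-identical across reruns.
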