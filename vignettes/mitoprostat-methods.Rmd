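---
title: "Methods: calcium calibration, co-regulation quadrants and translatome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium calibration, co-regulation quadrants and translatome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprostat)
```

This vignette is the package's own account of the three analyses it
implements, the statistical assumptions behind each, the parameters that
matter, and the places where the design was genuinely open and a choice
had to be made.

## 1. Aequorin luminescence to Ca²⁺

### Model

Aequorin luminescence reports free Ca²⁺ through its rate constant: the
fraction of the currently available photoprotein that discharges per read
interval. With stimulus-induced counts $CaL$ and the counts $DisL$
released when the remaining pool is deliberately discharged at the end of
the recording,

$$k = \frac{CaL}{DisL + CaL}, \qquad
  \mathrm{pCa} = 0.332588\,(-\log_{10} k) + 5.5593, \qquad
  [\mathrm{Ca^{2+}}] = 10^{-\mathrm{pCa}}\ \mathrm{M}.$$

The slope and intercept are the published constants for this reporter
system and are exposed in `calibration_params()` rather than hard-wired.
The logarithm is taken base 10: pCa is by convention a base-10 quantity,
and the intercept is the pCa returned at $k = 1$, which only makes sense
on that scale. The base is nonetheless a parameter (`log_base`) for users
calibrating against literature that defines $k$ differently.

### Two accounting modes

`calibrate_trace()` supports two denominators:

* **aggregate** (default): every interval's counts are compared against a
  fixed $DisL$, matching the single-$k$-per-seedling arithmetic used when
  only peak and rest values are quantified. It is exactly invariant under
  joint rescaling of all counts — calibration does not depend on detector
  gain.
* **pointwise**: the denominator at time $t$ is the pool still available
  at $t$ (discharge plus everything yet to be emitted). This is classical
  consumption accounting and exactly inverts the generator's forward
  model on noise-free data.

The distinction matters quantitatively: because
$k \propto [\mathrm{Ca^{2+}}]^{1/0.3326} \approx c^{3}$, a bright
transient consumes an appreciable share of the pool, and aggregate mode
(which pretends the pool is never depleted during the response)
underestimates peak concentration — by about 10 % at a 0.5 µM amplitude
with the default simulated pool. Analyses that need accurate full-trace
reconstruction should use pointwise mode; the recovery tests in the suite
do.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `resting_window` | 60 | s | the recording protocol reads resting luminescence for about a minute before the stimulus; the resting level is the mean calibrated concentration over that window |
| `count_floor` | 0.5 | counts | half-count continuity correction so a zero-count interval never produces $\log 0$ |
| `mode` | aggregate | — | see above |

Signature extraction (`extract_signature()`) searches for the peak only
after the stimulus, breaks ties by earliest time, reports a missing peak
time when the trace never exceeds the resting level, and integrates only
the positive baseline-subtracted excursion (negative dips are clipped:
the curve area is the area of the response peak, not a net balance).

An open question we had to decide: curve area can be computed on raw
normalized luminescence or on calibrated concentration. The package
computes it on **concentration** (molar·seconds) by default — areas are
then comparable across traces with different pools — and records the
choice in the output metadata.

## 2. Co-regulation quadrants

Transcript and protein log₂ fold-change tables are inner-joined on
`gene_id` (duplicates are an error, unmatched identifiers are counted and
reported). Classification gates **only on the protein side**: a gene is
eligible when $|FC_{prot}| > 1.5$ (linear scale, i.e.
$|\log_2 FC| > \log_2 1.5 \approx 0.585$) and $p_{prot} < 0.05$; no
criteria are applied to transcripts, whose fold-change sign alone decides
the quadrant:

| transcript | protein | quadrant |
|---|---|---|
| up | up | Q1 co-upregulated |
| down | up | Q2 post-transcriptionally increased |
| down | down | Q3 co-downregulated |
| up | down | Q4 post-transcriptionally repressed |

A transcript log₂FC of exactly 0 has no quadrant sign and is excluded
rather than tie-broken. A `strict_transcripts` mode additionally applies
the fold-change cutoff and an adjusted-p cutoff to transcripts, and a
`"relaxed"` preset lowers the protein cutoff to |FC| > 1.2 for
inspecting sparsely populated quadrants. Percentages are reported over
assigned (non-excluded) genes, with the total n alongside, and
`quadrant_summary()` can additionally split any user-supplied gene subset
(e.g. cytosolic ribosomal proteins) across quadrants.

Set enrichment of quadrant members is the classical upper-tail
hypergeometric test per term with Benjamini–Hochberg adjustment across
terms — the same procedure as a one-sided Fisher test — implemented on
`stats::phyper` and verified in the tests against exhaustive enumeration
of all draws for every universe of up to 12 genes.

## 3. Translational efficiency and saTE selection

### TE

With CPM-normalized libraries and replicate means per
(genotype, fraction) cell,

$$\mathrm{TE} = \log_2\frac{\overline{case}_{poly}/\overline{case}_{mono}}
                           {\overline{control}_{poly}/\overline{control}_{mono}}.$$

Numerical choices: a pseudocount of 0.5 is added to each cell mean after
CPM (avoids division by zero, preserves rank order); genes below 1 mean
CPM in all four cells are reported as missing rather than 0 (their ratio
is unstable and a 0 would be read as "unchanged"); `te_log2` is computed
as the difference of the two log-ratios, so swapping case and control
negates it exactly in floating point. Replicate means are taken on the
CPM scale — the scale on which the formula's ratios are defined — rather
than on raw or log counts.

### PLS-DA and VIP

`fit_plsda()` is NIPALS PLS1 on the mean-centered, unit-variance-scaled
predictor matrix against a centered ±½ two-class indicator. With a single
response the NIPALS inner loop is stationary after one pass, so the fit
is deterministic — no randomized initialization, no convergence
ambiguity; the tolerance (1e−10) only guards degenerate deflation, and
rank exhaustion truncates the requested number of components with a
warning. Scores are mutually orthogonal by construction and weights are
stored unit-norm.

VIP scores follow the standard chemometrics formula
$\mathrm{VIP}_j = \sqrt{p\,\sum_a SSY_a\, w_{ja}^2 / \sum_a SSY_a}$,
whose mean square is exactly 1; the conventional VIP ≥ 1 rule is the
default meaning of a "significant" VIP (the threshold is a parameter).
The implementation agrees with `mixOmics::vip` to machine precision on
random fixtures, which the test suite uses as an independent
cross-check.

An open design point: the per-gene VIP that gates the per-gene TE can
come from a PLS-DA on the monosomal libraries, the polysomal libraries,
or a per-replicate poly/mono ratio matrix. The package defaults to the
**ratio model** (case vs control classes on
$\log_2(\mathrm{CPM}_{poly}+0.5)/(\mathrm{CPM}_{mono}+0.5)$ per replicate
pair): it is the only construction in which the feature being weighted is
the same per-gene translational-shift signal the TE measures. The
per-fraction models remain available via `fit_te_plsda(source =)` for
library ordination, and the choice is recorded in the output metadata.

### saTE

`select_sate()` flags genes with linear TE fold change
$2^{|te\_log2|} \ge 1.25$ **and** VIP ≥ 1; direction `low` means
translationally repressed (shift toward monosomes).

## 4. What the generators emulate — and what they do not

* `gen_luminescence_trace()`: a difference-of-exponentials Ca²⁺ transient
  (fast rise, slower decay; defaults peak 12 s after the stimulus with
  3 s/12 s time constants, time-rescaled so the maximum lands exactly at
  `peak_time`) on a 0.1 µM resting baseline, 160 s at 1 s sampling with
  the stimulus at 60 s. The forward model inverts the calibration to a
  per-interval rate and emits Poisson counts from a finite pool of 10⁶
  expected counts, so the discharge is whatever remains — the kinetics
  were chosen so that even a 2 µM transient, which consumes >99.9 % of
  the pool under the cubic $k(c)$ law, still leaves a measurable
  discharge, as the real assay requires. Not emulated: film imaging,
  multi-seedling averaging, drift, or coelenterazine reconstitution
  variability.
* `gen_coreg_table()`: planted Q1–Q4 memberships (default 40/10/10/40 %
  of 1000 genes) with |log₂FC| centered on 1.5 (spread `fc_sd`, default
  0.2; 0 gives the noise-free setting in which recovery is exact) and
  planted p-values ≪ 0.05; nulls are zero-centered with uniform p. Not
  emulated: correlated errors between the transcript and protein assays,
  missingness patterns of mass-spectrometry data.
* `gen_polysome_counts()`: log-normal baseline abundances (median 100
  nominal CPM, log-sd 1) shared by all four cells; planted genes (default
  20 % of 2000) have the case-polysome mean multiplied by
  $2^{\pm 1}$ — by construction exactly a |te_log2| = 1 shift; NB counts
  with variance $\mu + \phi\mu^2$ at $\phi = 0.1$, three replicates per
  cell. Not emulated: gene-specific dispersions, batch effects,
  length-dependent coverage (RPKM-type corrections are out of scope).

Consequently, passing tests demonstrate correctness of the arithmetic
and recoverability under idealized noise — they do not certify
performance on real libraries with gene-wise dispersion, batch structure
or unbalanced designs.

## 5. Known limitations

**Selection error rates at realistic overdispersion.** The
fold-change + VIP rule inherits the noise of per-gene TE estimates. At
$\phi = 0.1$ the per-replicate log₂ CPM noise is
$\sqrt{(1/\mu + \phi)}/\ln 2 \approx 0.48$ for an abundant gene, so a
null gene's TE estimate (four cell means of three replicates) has
standard deviation ≈ 0.55 — larger than the $\log_2 1.25 = 0.32$
selection cutoff. More than half of all null genes therefore pass the
fold-change filter, and under the null the squared VIP is approximately
$\chi^2_1$-distributed (mean 1), so VIP ≥ 1 retains about a third of
them, strongly correlated with the same noise. The analysis drivers and
the test suite measure the consequence on the default simulation:
sensitivity ≈ 0.72–0.74 and false-discovery proportion ≈ 0.62 for the
planted-effect setting, and ≈ 30–36 % of genes selected under a fully
null simulation. Tightening the VIP threshold or increasing replication
is the remedy on real data; the package reports both filter values so
users can re-threshold.

**CPM composition bias.** Planting (or biologically having) many
one-sided shifts in a single library changes that library's total count,
and CPM normalization propagates the shift into every null gene's TE.
The effect scales with the planted imbalance (≈ 0.07 log₂ units at 25 %
planted genes with random signs, ≈ 0.01 at 5 %); median-of-ratios style
normalization would reduce it but is deliberately out of scope here,
where the normalization is the simple library-size scaling the TE
formula assumes.

**Aggregate-mode depletion bias** as described in section 1: prefer
pointwise mode when the pool consumption during the response is not
negligible.

**Problem sizes.** The test suite and drivers run the study at its
desk-scale defaults: 50 traces for amplitude-recovery sweeps, 1000-gene
co-regulation tables, 2000-gene × 12-library count matrices with 5–10
simulation seeds for operating-characteristic averages. These sizes give
stable medians/means for the quantities asserted while keeping the full
suite in the seconds-to-minutes range.
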