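---
title: "Methods: from ambient pesticide exposure to differential DNA methylation"
author: "pestewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ambient pesticide exposure to differential DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Chronic ambient exposure to copper-based agricultural pesticides has been
linked to neurodegeneration, and DNA methylation (DNAm) in blood is a
plausible biological mediator between environmental exposure and disease.
Testing that link epidemiologically requires a long chain of analysis
steps: reconstructing decades of ambient exposure from pesticide-use
records and residential histories, summarizing an Illumina-style beta
matrix into covariate-adjusted methylation signal, testing every CpG probe
for association with the exposure score, diagnosing and correcting
systematic inflation of the test statistics, aggregating probe-level
signal into differentially methylated regions (DMRs), and asking which
biological gene sets the findings concentrate in.

`pestewas` implements that chain end to end, and — because participant-level
exposure and covariate data for such studies are never public — ships a
synthetic-data generator with recorded ground truth so that every stage can
be validated by calibration and parameter-recovery experiments rather than
by eyeballing.

## Exposure model

Applications are point events (chemical code, year, pounds, acres, planar
x/y). For each participant-year we sum pounds-per-acre over all
applications of a chemical within a **500 m Euclidean buffer** (boundary
inclusive) of every address active that year; residential and workplace
buffers add. Annual values are averaged over calendar years
**1974 through the blood-draw year**, counting zero years in the
denominator. Per chemical, the window average is dichotomized at the
**median among controls** (midpoint convention), with *strictly greater*
scoring 1 — with many unexposed controls the median is typically zero and
"above the median" reads naturally as strict. The copper count is the sum
over the 15 copper chemicals, the organophosphate (OP) count over the 40
OP chemicals; both use the CADPR chemical codes.

Design choices worth knowing:

* Applications are points (field centroids); no polygon intersection, no
  geodesy. The buffer logic is scale-local, so planar meters on a flat
  square region carry all the statistical structure.
* Exposure is lbs/acre per event summed within the buffer (a raw-pounds
  mode exists behind `value = "pounds"`).
* A chemical with no variation anywhere yields indicator 0 for everyone,
  with a logged message.

## Synthetic study generator

The generator's defaults emulate a two-wave population-based
case–control study in an agricultural region: 569 cases, 237 controls,
cases a few years older (means 70.5 vs 67.4) and more often male,
smoking ~50% ever, ~86% European ancestry, six blood cell fractions from
a Dirichlet with realistic means, blood draws in two recruitment windows.
Application intensity concentrates at persistent spatial *hotspots*; OP
intensity at a hotspot is a noisy linear function of its copper
intensity, and each chemical is in use at only a subset of hotspots
(crop specificity). Participants live partly near hotspots (cases
slightly more so). These three ingredients give copper/OP count
correlations around 0.76–0.80, copper counts averaging ≈4 with SD ≈3.5,
and OP counts averaging ≈13 — the qualitative structure such agricultural
study populations exhibit, including the central confounding of copper by
OP exposure.

Methylation is generated on the **logit (M-value) scale**: probe baseline
(mean −0.8, SD 1.6, so mean beta ≈ 0.3) + per-probe covariate effects
(slopes drawn per probe with configurable SDs) + planted exposure effects
+ heteroskedastic noise (per-probe SDs from a scaled inverse chi-square
with 20 df around `noise_sd` = 0.35), then mapped through the inverse
logit so every beta value is strictly inside (0, 1). Additive effects on
the logit scale keep the EWAS's linearity assumptions honest while
guaranteeing a valid beta range.

**Effect calibration.** A planted probe receives slope
\(b = c \cdot \frac{r}{\sqrt{1-r^2}} \cdot \frac{\sigma_p}{\mathrm{sd}(x_\perp)}\)
where \(x_\perp\) is the copper count residualized on the full covariate
design and \(c = 1.06\) is a fixed attenuation constant compensating the
logit curvature and the 5/95 winsorization, measured once on an
independent calibration run. With `effect_size_r = 0.3` the realized mean
|bicor| at planted probes is 0.30 ± 0.01 at n = 300. Planted probes and
region probes get mid-range baselines (SD 0.8 around 0) — differential
signal at intermediate methylation — which also keeps the logit curvature
mild. Planted regions are blocks of consecutive probes (100 bp apart, so
they co-cluster at the default 1 kb gap) at the requested start position,
sharing one signed shift.

The array layout spreads probes over 22 autosomes plus X/Y with an
exponential inter-probe gap (median 500 bp, floored at 2 bp), assigns
genes in blocks (negative-binomial sizes, mean ≈ 9, 15% intergenic), and
flags ~28% of probes (all X/Y probes as sex-chromosome; cross-reactive,
SNP-overlapping and non-CpG flags on autosomes) — matching the fraction
removed by standard 450k QC. Planted probes are never flagged, so ground
truth survives filtering by construction.

What the generator does **not** emulate: Type I/II probe chemistry (one
logit-normal family serves for all probes), detection p-values and
normalization artifacts, bimodal probe classes, spatial correlation of
methylation beyond planted regions, and real LD-like correlation between
neighboring probes. Passing recovery tests therefore demonstrates the
pipeline's statistical behavior under its own assumptions, not robustness
to every artifact of real arrays.

## Preprocessing

`filter_probes()` drops every probe with a non-empty flag set and reports
per-category counts. `winsorize()` clamps each probe to its 5th/95th
percentile, with quantiles by linear interpolation of order statistics
(the k-th of n order statistics sits at quantile (k−1)/(n−1)). One subtle
consequence, worth documenting: with that interpolation rule a second
winsorization pass can clip again by a sliver (the interpolated quantile
of the clamped vector falls slightly below the original cutoff unless
(n−1)·q is an integer); the drift is bounded by the interpolation
fraction times the local order-statistic gap and is negligible against
the winsorization effect itself.

`residualize()` removes covariates once, producing a residual matrix
reused by the correlation, regression and region stages. The design is
intercept + age + sex + ancestry + smoking (2 dummies) + wave + five of
the six cell fractions (one dropped for the simplex constraint;
configurable) + OP count. Disease status is deliberately **not** in the
design: methylation can be a mediator between exposure and disease, so
conditioning on case status would open a collider path; stratified
analyses subset samples before residualizing instead. `mode = "ols"`
(default) gives exact least-squares residuals; `mode = "eb"` shrinks each
probe's coefficients toward the across-probe mean with per-covariate
weights inverse to sampling variances (ridge-toward-prior; intercept
never shrunk; prior variances floored at 1e-8). OLS is the calibration
reference; the EB mode is property-tested (shrinkage direction) because
no exact reference form exists for it.

## Probe-level association

For each probe the package reports both a **biweight midcorrelation**
(robust effect scale; raw MAD, tuning constant 9, weights
\((1-u^2)^2 1[|u|<1]\), per-vector Pearson fallback at zero MAD) and a
**moderated-t regression p-value**. Variance moderation fits a scaled-F
prior to the per-probe residual variances by matching the first two
moments of \(\log s_g^2\) (digamma/trigamma inversion; prior df capped at
1e7 when the variances are under-dispersed), and the moderated statistic
\(t_g = \hat\beta_g / (\tilde s_g/\sqrt{S_{xx}})\) has \(d + d_0\)
degrees of freedom. Probes with unadjusted p < 1e-7 are flagged
significant — the operational rule this kind of exposure EWAS applies —
with BH adjusted p-values emitted alongside.

**Calibration requires adjusting the exposure too.** The residual matrix
is orthogonal to the covariate design, but the raw copper count is not —
it is strongly correlated with the OP count inside the design. Regressing
design-orthogonal residuals on a raw exposure is provably deflationary
(the t-statistics' null variance shrinks by the squared ratio of partial
to total exposure SD; in stratified controls the same construction can
drive λ to essentially zero). `run_ewas()` therefore projects the
exposure onto the design's orthogonal complement first (the
Frisch–Waugh–Lovell partial regression) and uses n − k − 1 residual df.
Under the null synthetic study this yields λ within a few percent of 1
and a 5% false-positive rate inside its binomial band.

## Inflation and the empirical null

λ = median(z²)/qchisq(0.5, 1) with z from the moderated-t p-values
(signed by slope). The empirical-null correction re-estimates the null's
mean (bias) and SD (inflation) from the bulk of the statistics by a
three-component Gaussian mixture EM: one dominant null and two signal
components constrained to opposite sides of the null mean, at least
`delta` = 2.5 null-SDs away — the separation is what prevents the signal
components from eating the tails of a genuinely calibrated null (at
delta ≤ 1.5 a pure N(0,1) input collapses to σ̂₀ ≈ 0.85). Initialization
is seeded k-means; convergence on relative log-likelihood (1e-8) or
parameter change (1e-9).

Two corrected inflation factors are reported, deliberately:

* `lambda_corrected` — standard λ of all corrected statistics. With
  genuine signal present this stays above 1 (signal mass shifts the
  median chi-square: with 5% signal at |z| ≈ 4 the floor is
  qchisq(0.5/0.95, 1)/qchisq(0.5, 1) ≈ 1.13 even at perfect recovery),
  which is also why corrected λ on real data remains above 1.
* `lambda_corrected_null` — the posterior-null-weighted median of the
  corrected z², i.e. the residual miscalibration of the null component
  itself. This is the quantity that returns to ≈1 when the null
  parameters are recovered correctly.

## Region detection

Bump hunting proceeds in four steps. (1) Greedy clustering of probes at
max gap 1 kb within a chromosome. (2) Per-probe slopes of the residuals
on the (adjusted) exposure — unmoderated, since smoothing pools
information across neighbors anyway — smoothed within clusters by a
truncated running mean (window 3; a loess-like local-linear alternative
exists). (3) Candidate regions are maximal same-sign runs above the
genome-wide 99th percentile of |smoothed slopes|, keeping runs of ≥5
probes, with area = Σ(|value| − cutoff). (4) Permutation p-values: for
each of B permutations of the exposure, slopes are recomputed, smoothed,
and **all** exceedance runs (no length filter) contribute their areas to
one pooled null; p = (1 + #{null areas ≥ observed}) / (1 + total nulls).
Pooling unfiltered null runs keeps the denominator large at feasible B
(the +1 smoothing means p is never exactly zero); filtering nulls by
length would leave a handful of null areas and a degenerate p-value
resolution.

## Gene-set overrepresentation

Probes map to genes through the annotation's gene column only (intergenic
probes are dropped with a message); the universe is every gene with ≥1
surviving probe. Genes with more probes have more chances to contain a
significant probe, so enrichment must de-bias by probe count: a
probability-weighting function bins genes by CpG count (equal-frequency
bins, isotonic-regression smoothed), floors the per-bin selection
probability at 1e-3 (keeping odds finite), and normalizes to mean 1. The
test is **Wallenius' noncentral hypergeometric** upper tail with odds =
mean weight of set genes / mean weight of non-set genes, evaluated by the
exact sequential-draw forward recursion (with two weight classes the
remaining urn composition depends only on draws and successes — an O(n·m₁)
dynamic program that is numerically stable at study sizes). With uniform
weights the engine reduces to Fisher's exact test to machine precision.
BH is applied within each category label (BP/CC/MF/pathway).

The validation experiments show why the correction exists: when selection
probability is purely a function of CpG count and gene sets are
*count-coherent* (as real functional classes are), uncorrected Fisher's
false-positive rate at p < 0.05 reaches 0.3–0.4 while the weighted engine
stays inside the 99% binomial band. Note that the anticonservatism only
appears for count-coherent sets; uniformly random sets mostly average the
bias away.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → exposure → preprocess → ewas (total
and per-stratum) → dmr → enrich against one configuration, writing every
artifact as plain CSV/TSV/JSON/GMT/BED into one directory; each stage
reads its inputs back from that directory, so every file is round-tripped
by construction. All randomness flows from a single root seed through
per-stage derived seeds; identical configuration and seed give
byte-identical outputs (the run report records a hash of the scientific
configuration, excluding volatile paths). The package's interface is R
functions; the orchestration layer is `run_pipeline()` plus the exported
stage functions rather than a shell executable.

## Problem sizes used in validation

The shipped experiments use 20,000 probes × 300 samples for pipeline
calibration/recovery (with ~14,300 probes surviving QC), 50,000 z-scores
for empirical-null recovery, 3,000–4,000-gene universes with 100–1,000
sets for enrichment, and B = 100 permutations for region p-values; unit
tests run smaller. These sizes give stable Monte-Carlo estimates for
every check while keeping the whole suite fast on a single CPU; all of
them are configuration parameters, and paper-scale runs (≈350k probes,
800 samples) only change `n_probes`/`n_cases`/`n_controls`.

## Known limitations

* The copper-count score's historical range ("0 to 17" with 15 chemicals
  in the catalogue) is not reproducible from the published description;
  the package counts over the configured chemical list (0–15 by default)
  and leaves the discrepancy documented rather than guessed at.
* The EB residualization mode is a reasonable ridge-toward-prior form,
  not a reconstruction of any specific package's estimator; only its
  qualitative shrinkage behavior is guaranteed.
* Permutation p-values share one pooled null across regions, so they are
  not independent across regions; treat them as region-level evidence,
  not as a family-wise error control.
* Enrichment's probe-to-gene map uses the annotation field only; nearest
  -gene assignment for intergenic CpGs is out of scope.
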