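---
title: "Models and methods behind radresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radresp)
library(dplyr)
```

radresp analyses the radioresponse of tumour cell-line panels across
radiation qualities: it fits clonogenic survival curves, derives
radiosensitivity metrics, turns paired photon/ion fits into endpoint-wise
relative biological effectiveness (RBE) values, clusters panels into
radiosensitivity cohorts, classifies those cohorts from gene expression, and
propagates fitted survival into tumour control probability (TCP) under
fractionated schedules. This vignette explains the models, the tunable
parameters, the numerical choices, and what the simulators do and do not
emulate.

## The RCR survival model

Clonogenic survival is modelled with the repairable conditionally repairable
(RCR) form

$$S(d) = e^{-ad} + b\,d\,e^{-cd},$$

with dose $d$ in Gy. The first term is the fraction of cells that escape
lethal damage (rate $a$ per Gy); the second is the fraction that sustains
potentially lethal damage but is conditionally repaired (amplitude $b$,
decay $c$, both per Gy). $S(0) = 1$ identically, and the model reproduces
both the low-dose shoulder of photon curves and the nearly log-linear
high-LET curves (where $b \to 0$).

Constraints $a \ge 0$, $b \ge 0$, $c > 0$ are imposed during fitting: they
keep $S$ positive and the high-dose tail decaying, which the data cannot
always enforce on their own at only five or six dose levels.

### Fitting

`fit_rcr()` minimises $\sum_i (\ln SF_i - \ln S(d_i))^2$ — least squares on
log survival, the radiobiology convention, which weights each decade of
survival equally instead of letting the near-1 low-dose points dominate. A
linear-space alternative (relative least squares) is available for data
containing zero counts. Replicate flasks enter jointly rather than as
per-dose means, so better-replicated doses carry proportionally more weight.

The objective is multimodal in $(b, c)$: a shallow shoulder can be explained
either by a small $b$ or by a large $b$ with fast decay. The optimiser
(bounded L-BFGS-B) therefore runs from a 16-point start grid — $a_0$ from
the log-slope of the two lowest-dose points, $b_0 \in \{0, 0.5, 1, 2\}$,
$c_0 \in \{0.5, 1, 2, 4\}\,a_0$ — and keeps the best optimum, breaking
near-ties toward the smaller $b$ (the more parsimonious shoulder). On
noise-free model data the fit recovers the generating triple to better than
$10^{-4}$ relative error; on Poisson-simulated assays with $10^5$ cells
seeded it recovers parameters to a few percent, with $b$ the least
identified of the three.

Surviving fractions of exactly zero cannot enter a log fit; they are dropped
with a warning rather than pseudo-counted, because any pseudo-count choice
would silently tilt the tail.

### Derived metrics

`survival_metrics()` computes, per curve:

* **SF2 / SF3.5** — fitted survival at 2 and 3.5 Gy. SF3.5 is the
  clustering feature: at larger doses per fraction (stereotactic or ion
  schedules) it separates resistant lines better than SF2.
* **D10** — the dose at 10% survival, solved by bracketing (the bracket
  grows geometrically until survival falls below target), a coarse scan for
  the first crossing, then root polishing to $|S - 0.1| < 10^{-10}$. The
  scan step matters only for pathological parameter sets where the repair
  bump makes $S$ non-monotone near 1; taking the *first* crossing keeps the
  solution well-defined there.
* **Mean inactivation dose** $\bar D$, twice: the closed form
  $\bar D = 1/a + b/c^2$ (the survival integral in closed form; it diverges
  for $a = 0$, which is rejected), and a trapezoidal area under the fitted
  curve on a uniform grid — default step 0.01 Gy, upper limit where
  $S < 10^{-8}$ — which agrees with the closed form to about $10^{-3}$ Gy.
  The AUC variant exists because both appear in practice; their near
  equality on fitted curves is itself a useful diagnostic. The leading
  trapezoid error is $(h^2/12)(a - b)$, so the finite-grid value can sit on
  either side of the closed form depending on the sign of $a - b$.
* **D0** — the limiting slope: $-1/\text{slope}$ of an OLS line through
  $\ln S$ sampled densely on a distal dose window, defaulting to the distal
  40% of the data's dose range. "Distal end" is a judgement call; the window
  is exposed as an argument. Note that when the repair term dominates the
  tail, $\ln S \approx \ln(bd) - cd$ carries a $1/d$ correction to the
  slope, so D0 approaches its asymptote $1/\min(a, c)$ only on windows with
  $d \gtrsim 200/\min(a,c)$; on data-scale windows D0 is a descriptive
  tail-steepness metric, not the asymptote.

## Endpoint-wise RBE

For a reference (photon) and test (ion) curve of the same cell line, each
dose-like metric $M$ gives an RBE $= M_\text{ref}/M_\text{test}$
(`rbe_table()` computes all four: D10, parametric $\bar D$, AUC $\bar D$,
D0). RBE is invariant to a common rescaling of both dose axes and exceeds 1
wherever the test quality is uniformly more effective.

Per-endpoint summaries use the sample (n−1) standard deviation and
$CV = SD/\text{mean}$; with a single cell line the SD is reported missing,
not zero. Everything is carried at full precision — rounding is left to
display, because chaining rounded intermediates visibly corrupts one-decimal
dose arithmetic (see the underdosing discussion below).

## Radiosensitivity cohorts from SF3.5

`cluster_sf35()` runs agglomerative hierarchical clustering with Euclidean
distance and average (UPGMA) linkage — `stats::hclust` — on the raw 1-D
SF3.5 values and cuts the tree at $k = 4$. No standardisation is applied:
the feature is univariate, so scaling would only multiply every distance.
Cohort labels S, MS, MR, R are assigned by ascending cluster-mean SF3.5,
which makes the labelling independent of dendrogram leaf order;
`resistant_vs_rest()` collapses the grouping to a binary resistant/other
factor. For 1-D inputs the resulting clusters are contiguous intervals of
the sorted values, and the partition is invariant to input row order — both
are asserted in the test suite.

On the packaged 38-line HNSCC panel (`hnscc_panel()`, fitted SF2/SF3.5,
plating efficiency, anatomical site), the $k=4$ cut isolates exactly three
lines in the resistant cohort (SCC61, SCC9, HN5 — SF3.5 of 0.465, 0.44,
0.414) and places HN31 (0.265) as the maximum of the moderately sensitive
cohort.

## Gene-signature classification

`rank_genes()` scores every gene with a one-way ANOVA F statistic across
the cohorts (vectorised over genes; p-values from $F_{g-1,\,n-g}$), sorting
by ascending p, ties by descending F, then gene id. Genes with no variance
anywhere have an undefined F and are flagged and ranked last rather than
silently dropped. An optional moderated variant shrinks the per-gene
residual variance toward the grand mean of the gene-wise variances with a
fixed prior of 4 df — useful at small n, but the plain statistic is the
default because its behaviour is exactly reproducible from first principles.

`evaluate_panels()` grows panels from the top of the ranking (e.g. sizes
4–500) and evaluates a linear SVM (cost 1, unscaled inputs — expression is
already on a common log-intensity scale) by repeated stratified 10-fold
cross-validation, defaulting to 10 repeats. Two selection modes exist:

* `inside_cv` (default): genes are re-ranked within every training fold, so
  the held-out samples never influence feature selection. On label-permuted
  data this scores at chance — the standard guard against selection leakage.
* `outside_cv`: one ranking on all samples, the optimistic shortcut common
  in practice; it is provided for comparability, not recommended.

Accuracy is the fraction of correct pooled-over-folds predictions, averaged
over repeats; balanced accuracy (mean per-class recall) is reported
alongside because a 3-vs-35 resistant-vs-rest null already achieves ~92%
plain accuracy by always predicting the majority class.
`select_signature()` picks the best panel, breaking accuracy ties toward
the smaller panel.

## Tumour control probability

The Poisson TCP model: a tumour controlled only if no clonogen survives,

$$\mathrm{TCP} = \exp\!\Big(-\sum_i N_i\, S(d)^n\Big),$$

over voxels $i$ holding $N_i$ cells. The default tumour is a sphere of
radius 0.6203 cm — volume $\tfrac43\pi r^3 = 1.000$ cm³ — containing
$10^8$ cells. Dose is uniform and the tumour fully oxygenated, so the voxel
sum collapses to $\exp(-N\,S(d)^n)$ for any voxel count (asserted to
$10^{-12}$); the voxel machinery is retained for heterogeneous extensions
but is deliberately untested surface beyond that invariance.

Fraction number $n$ is continuous: `dose_for_tcp()` inverts the TCP
analytically, $n^* = \ln(-\ln T / N)/\ln S(d)$, and returns the total
physical dose $n^* d$ (and GyE total where an RBE is attached). Published
GyE-per-fraction prescriptions divide cleanly into non-integer fraction
counts, so continuous $n$ matches how such comparisons are actually made.
Survival powers are computed as $\exp(n \ln S)$ to stay finite at large
$n$.

One modelling note: in the fractionated form the single-fraction survival is
taken from the RCR expression with *negative* first exponent,
$S(d) = e^{-ad} + bde^{-cd}$, raised to the power $n$ — the per-fraction
survival must equal the single-dose model, so a sign slip sometimes seen in
fractionated restatements of the formula is not propagated.

### Underdosing under a generic RBE

`underdose_report()` quantifies what happens when a clinic converts a GyE
prescription to physical ion dose with a generic RBE (default 3) while the
cell line's actual RBE is lower: physical dose $= \mathrm{GyE}_\text{fixed}
/ \mathrm{RBE}_\text{fixed}$, delivered biological dose $=$ physical
$\times \mathrm{RBE}_\text{actual}$, and the difference is the underdose.
All three identities hold exactly at full precision in the report; rounding
to one decimal happens only at display. (Chained rounding — subtracting an
already-rounded delivered dose — shifts some published one-decimal
differences by 0.1 GyE; carrying full precision reproduces the internally
consistent rows and is the defensible convention.)

`schedule_comparison()` applies `dose_for_tcp()` per cell line across
schedules such as 2 Gy/fraction photons, 8 Gy/fraction stereotactic, or
3 GyE/fraction carbon (converted to physical dose per fraction through the
attached RBE), at a common target TCP (default 70%).

## What the simulators emulate

`simulate_clonogenic()` draws per-flask colony counts from a Poisson law
with mean $\text{cells} \times \mathrm{PE} \times S(d)$ — colony formation
is a count process, and Poisson is the standard assumption in the absence
of a stated noise model. Defaults are the photon dose grid 0/1/2/4/6/8 Gy,
triplicate flasks, and seeding that escalates geometrically from 100 cells
at 0 Gy to $10^4$ at the top dose so expected colony counts stay in a
countable range. Dose-0 flasks estimate plating efficiency downstream
(`clonogenic_sf()` pools their colonies per cell line and quality).

What it does **not** emulate: overdispersion from pipetting and counting
error, colony merging at high density, the ~50-cell colony threshold, or
dose-rate and LET effects within a quality. Parameter-recovery results on
these simulations therefore certify the estimation machinery, not the lab
assay.

`simulate_expression()` produces a genes × samples Gaussian log-intensity
matrix: a chosen number of informative genes receive per-cohort mean
offsets (default `c(0, 2, 4, 6)` noise-SD units across S/MS/MR/R), all
other genes are pure noise. The default design mimics a 38-sample panel
with 13/12/10/3 samples per cohort — the resistant cohort deliberately
tiny. Not emulated: probe-level noise, correlated gene modules,
batch/normalisation artefacts, and any relation between expression and the
survival parameters beyond the labels. Classifier results on this generator
demonstrate pipeline correctness (chance-level nulls, recoverable strong
signal at panel-like n), not expected accuracy on real transcriptomes.

## Problem sizes and determinism

Every stochastic component accepts a seed (designs carry one; CV takes
one), and equal seeds give bitwise-equal output. The test suite and the
acceptance script run at deliberately modest sizes — $10^5$–$10^6$ cells
seeded, 200–1000 genes, 10–20 cross-validation or permutation repeats —
chosen so the statistical assertions have comfortable margins while the
whole suite completes in well under a minute.

## Known limitations

* No linear-quadratic fitting and no confidence intervals on RCR
  parameters; the fit reports residuals, not uncertainty.
* RBE here is a ratio of fitted dose metrics; no microdosimetric or
  LET-dependent RBE models.
* TCP assumes full oxygenation, uniform dose, constant LET, and ignores
  repopulation and normal-tissue constraints; it supports relative
  comparisons between cell lines and schedules, not absolute outcome
  prediction.
* The cohort boundaries from 1-D clustering are sensitive to the panel
  composition: adding lines near a boundary can move it.
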