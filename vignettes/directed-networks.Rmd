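---
title: "Directed EEG networks from partial directed coherence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG networks from partial directed coherence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcnet)
```

## The analysis in one paragraph

pdcnet estimates *effective* (directed) connectivity between EEG sensors in
resting state. Each subject's multichannel record is modelled as a vector
autoregression (MVAR): every channel at time $n$ is a linear combination of
the recent past of *all* channels plus innovation noise,

$$Y(n) = \sum_{r=1}^{p} A_r\, Y(n-r) + E(n).$$

The Fourier transform of the coefficient series,
$\bar A(f) = I - \sum_r A_r e^{-i 2\pi (f/f_s) r}$, yields partial directed
coherence from channel $j$ to channel $i$,

$$\mathrm{PDC}_{j \to i}(f) =
  \frac{|\bar A_{ij}(f)|}{\sqrt{\sum_k |\bar A_{kj}(f)|^2}},$$

a number in $[0,1]$ that measures which fraction of channel $j$'s outflow at
frequency $f$ is directed at channel $i$. Averaging PDC over a frequency
band (alpha 8–13 Hz by default) and zeroing the diagonal gives a weighted
directed network on the 30-channel 10–20 montage, which is then summarized
three ways: directed-weighted graph metrics (clustering coefficient $C$,
characteristic path length $L$, global efficiency $G_e$, strengths, local
efficiency), block sums over hemispheric/midline and lobe partitions (LL,
LR, RL, RR, MM, LM, ML, RM, MR; FC, PC, OC, TC, ...), and group statistics
(pooled two-sample $t$ with Benjamini–Hochberg FDR per family, Pearson
correlation of network metrics with HDRS symptom scores).

## The MVAR estimator

`fit_mvar()` uses multivariate ordinary least squares on the mean-removed
record. With `order = "auto"` (the default in `default_config()`), the
order is selected by Schwarz's Bayesian criterion over $1 \ldots p_{max}$;
every candidate is fitted on the common sample range (starting at
$p_{max}+1$) so criterion values are comparable, and the winner is refitted
on its own maximal range. The criterion trace is stored on the model so the
selection can always be audited. A fixed order is available in the
configuration for reproducibility and speed, and is what the packaged
benchmark runs use: order selection costs $p_{max}$ extra fits per subject
and the synthetic generative processes have a known small order.

Two genuinely open choices were fixed as follows:

* **One model per condition block.** Resting segments of a condition are
  concatenated and a single model fitted, maximizing the sample count per
  coefficient (a 30-channel order-3 model has 2 700 coefficients).
  Segment boundaries are preserved by `split_conditions()` so per-segment
  fitting remains possible, but concatenation is the default.
* **Original (non-generalized) PDC.** The formula above, applied to raw
  coefficient magnitudes with no noise-covariance weighting, and
  band-averaged on the magnitude scale (not squared). The column
  normalization $\sum_i \mathrm{PDC}_{j\to i}^2(f) = 1$ is asserted in the
  test suite at $10^{-9}$ at every frequency.

The frequency grid defaults to 0.5 Hz steps, which resolves the alpha band
with 11 points; band edges are inclusive.

## Graph metrics

All metrics treat the band-averaged matrix as a dense weighted digraph with
`weights[i, j]` the edge $j \to i$.

* **Strengths** are row sums (inflow) and column sums (outflow).
* **Clustering** uses the directed-weighted triangle form with cube roots
  of weights: $C_i = \tfrac12 [(P^{1/3} + (P^T)^{1/3})^3]_{ii} /
  [k_i(k_i-1) - 2\sum_j a_{ij}a_{ji}]$, where $a$ is the binarized
  adjacency ($a_{ij}=1$ iff $w_{ij}>0$) and $k_i$ the total binary degree.
  Because PDC matrices are dense, $k_i = 2(K-1)$ in practice; the
  binarization rule is stated explicitly for that reason. Nodes whose
  denominator vanishes contribute $C_i = 0$.
* **Distances** map weight to length as $1/w$ — the convention of the
  standard brain-connectivity toolboxes — and respect edge direction.
  $L$ is the mean distance over ordered pairs; on disconnected graphs it is
  reported as `Inf` with a flag rather than silently dropping pairs, and
  **global efficiency** (mean of $1/d$, with $1/\infty = 0$) is the
  recommended robust statistic.
* **Local efficiency** of node $i$ is the global efficiency of the subgraph
  induced by $i$'s neighbours (any in- *or* out-edge), excluding $i$;
  fewer than two neighbours gives 0. The directed-weighted form follows the
  same toolbox convention; the verbal textbook definition is
  undirected-flavoured, so the choice is pinned down by brute-force oracle
  tests (exhaustive triple enumeration for clustering, min-plus relaxation
  for distances) on random digraphs of up to 8 nodes.

On raw dense PDC networks ($w \approx 0.1$) these conventions put $L$ above
1 by construction. Absolute magnitudes of $L$ therefore depend on the
weight-to-length convention; group *contrasts*, which are what the
statistics operate on, do not.

## Block connectivity

`summarize_blocks()` sums directed weights from a source channel set to a
target channel set ("XY" = X-to-Y). Hemisphere membership follows the
10–20 odd/even/z rule with the midline kept out of the lateral sets, so the
four lateral blocks (LL, LR, RL, RR) and five midline blocks (MM, LM, ML,
RM, MR) partition the ordered channel pairs exactly — as do the 25 lobe
region pairs — and each partition reconstructs the total off-diagonal
weight to machine precision (a property test at $10^{-12}$). The block
statistic is the **sum**, matching the scale on which such quantities are
conventionally reported; `normalize_blocks()` divides by the ordered-pair
count when a per-edge mean is needed, e.g. for symptom correlations.

## Statistics

Group comparisons use the classical pooled-variance two-sample $t$
($df = n_1+n_2-2$), computed from raw samples or from printed summary
statistics; recomputing published group means/SDs reproduces published $t$
values only under pooling, which is why Welch's variant is not used.
The sign convention is control minus patient. Each analysis family — 3
bands, 4 hemisphere blocks, 5 midline blocks, the region pairs, per-node
metrics, the correlations — is BH-FDR-corrected separately, with the family
identifier carried in every output row. Normality screening uses the
one-sample Kolmogorov–Smirnov distance with parameters estimated from the
sample; this is conservative without the Lilliefors correction, and the
result carries that caveat rather than a guess. Correlations are Pearson
$r$ with the least-squares line, two-sided $p$ via the $t$ transform.

## The synthetic cohort generator

`simulate_cohort()` is the known-answer test bed: nothing downstream is
validated against real EEG (none is distributed with the package), so the
generator defines exactly what "correct recovery" means.

* **Base process.** Every channel of the 30-channel montage carries a
  damped-oscillator AR(2) self term with pole modulus $\rho = 0.9$ at
  10 Hz, putting the spectral peak mid-alpha. Directed cross-edges at lag 1
  link nearest neighbours: anterior-to-posterior chains in each lateral
  strip and along the midline, homologous right-to-left edges, a smaller
  left-to-right set, and midline-to-hemisphere links.
* **Stability across sampling rates.** The AR(2) DC stability margin
  $1 - a_1 - a_2$ shrinks toward zero as $f_s$ grows (the pole pair
  approaches $z = 1$), so any fixed cross-coefficient destabilizes the
  coupled network at high rates. The default cross-coefficient is therefore
  *half the margin at the requested rate*, which keeps the companion
  spectral radius near 0.90 at every rate (asserted for 100–500 Hz).
  Stationarity (companion spectral radius $< 1$) is asserted at
  construction and again before simulation, with the radius reported in the
  error message.
* **Patient effect.** Patients' generating coefficients on the configured
  blocks — right-to-left plus left-to-left cross-edges by default — are
  multiplied by the attenuation factor exactly; controls use the base spec.
* **HDRS scores** are `baseline − slope × (ground-truth coupling sum in
  the attenuated blocks) + Gaussian noise`, clipped at ≥ 17 for patients
  (the usual inclusion threshold) and ≥ 0 for controls. With the default
  `hdrs_model = NULL` the slope self-calibrates so an unattenuated coupling
  sum maps to a healthy score of about 4 and baseline 30 with noise SD 2.5;
  no effect-size estimates exist for this, so these are calibration
  choices, fixed once, not population estimates. Because the attenuation is
  identical for every patient, ground-truth coupling varies *between*
  groups, not within; HDRS–connectivity correlations are therefore
  evaluated across the full cohort by default (`cor_scope = "all"`), where
  the generator guarantees a negative relationship. A `"patients"` scope is
  available for data with within-group variation.
* **Determinism.** Per-subject seeds derive arithmetically from the cohort
  seed; simulation saves and restores the caller's RNG state, and repeated
  runs are bit-identical.
* Burn-in of $10 \times p \times K$ samples is discarded; innovations are
  independent Gaussian, matching the linear framework PDC assumes.

What the generator does *not* emulate: volume conduction (no head model, so
no instantaneous mixing — real sensor-space PDC is biased by it),
nonstationarity, artifacts, and 1/f broadband structure. Passing the
recovery tests shows the estimator chain is correct for linear VAR data; it
does not certify performance on real EEG.

One non-obvious behaviour worth knowing: because PDC normalizes by total
outflow per source, attenuating a source's right-to-left edges *increases*
its remaining relative outflow, so LR/RR blocks can rise in patients while
LL/RL fall. The recovery claims are therefore about the attenuated blocks
and the direction of their change, not about every block.

## Benchmark problem sizes

The packaged recovery runs use 15 + 15 subjects, 120 s per subject at
120 Hz, fixed order 3, and a 1–45 Hz grid — a scale at which the full
pipeline runs in seconds per cohort while leaving the estimator ample
samples per coefficient (14 400 samples for 90 regressors per equation).
20 independent cohort seeds give the sign-recovery rates; 20 more, with
attenuation 1.0 (patients and controls statistically identical), give the
null calibration. Under the global null, BH acts per family as a Simes
test, so *each* family fires with probability about $\alpha$; the reported
null rate is the pooled detection frequency over the three block families
and all seeds, which estimates that per-family rate with 60 draws instead
of 20.

## Degenerate inputs and numerical guards

* Constant channels make the regressor matrix rank-deficient;
  `fit_mvar()` names the offending channel instead of failing inside the
  solver.
* A numerically zero PDC denominator column cannot occur for finite
  coefficients (the diagonal of $\bar A$ is $1 - \sum_r a_{jj,r}e^{-i\theta}$);
  it is still guarded at $10^{-12}$ and raises an error.
* Band/grid mismatches, Nyquist violations, schedules past the end of a
  record, unknown channel labels, and non-stationary specs all error before
  any computation.
* A subject failing anywhere in the per-subject analysis is skipped with
  the reason recorded in the run log — never silently dropped — and group
  statistics are computed only when both groups retain at least two
  subjects.

## Known limitations

* Sensor-space analysis only; no source reconstruction, no leakage
  correction.
* The original PDC variant is scale-sensitive between channels (no noise
  covariance weighting); channels are assumed comparably scaled, which
  holds for the generator and for conventionally preprocessed EEG.
* ICA-based artifact removal is out of scope; inputs are assumed
  artifact-free.
* EDF ingestion is not implemented; recordings enter as delimited
  label-headed matrices (`read_recording()`), and the JSON configuration
  drives everything else.
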