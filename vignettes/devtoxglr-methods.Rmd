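---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devtoxglr)
library(dplyr)
```

This vignette is the package's account of its own science: the statistical
models each stage implements, the assumptions they rest on, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The assay and its analysis chain

The screen differentiates a germ-layer reporter human embryonic stem cell
line toward definitive endoderm for 48 hours in 384-well plates. Three
fluorescent fusion reporters mark lineage commitment: SOX17 (endoderm),
SOX2 (ectoderm/pluripotency) and BRA (mesoderm). The developmental-toxicity
signal is a concentration-dependent loss of SOX17-positive cells; a parallel
cell-count endpoint separates specific differentiation effects from plain
cytotoxicity. The analysis chain is:

1. **Gating** — per-cell intensities to per-well percent responders;
2. **Normalization and curve fitting** — percent change from solvent
   control, three-model fits, AIC selection, hit calls and potencies;
3. **Plate QC** — robust control-separation metrics;
4. **Scorecard** — qPCR delta-delta-Ct gene-set scores verifying the
   differentiation model itself;
5. **Benchmarking** — confusion metrics over curated chemical truth sets.

## Gating model

A cell is biomarker-positive when its mean channel intensity strictly
exceeds `median + 5 * MAD` of a plate-local baseline population: pluripotent
control cells for SOX17 and BRA (markers absent there), endoderm-control
cells for SOX2 (marker lost after induction). Choices worth stating:

* **MAD convention.** `stats::mad()` with the 1.4826 consistency constant by
  default, for parity with the robust-statistics convention used in the
  downstream concentration-response stage; every gating and cutoff function
  accepts `mad_constant = 1` for the raw MAD.
* **Ties go negative.** Positivity is a strict inequality; a cell exactly at
  the threshold is not a responder. With continuous intensities this is
  measure-zero; it matters only for degenerate constant-intensity inputs.
* **Cell-level baselines.** Thresholds are computed on the pooled per-cell
  intensities of a plate's baseline control wells (not on well medians), and
  never pooled across plates, so plate-to-plate staining drift is absorbed.
* **Empty wells.** A zero-cell well keeps `cell_count = 0` and missing
  percentages rather than being dropped, so cytotoxic wipe-outs stay visible
  to the cell-count endpoint.

## Concentration-response model

Raw well values (`rval`: percent responders or cell count) are normalized
per plate against the solvent-control median `bval`:
`resp = 100 (rval - bval) / bval`, and loss-direction endpoints are
multiplied by -1 so losses read as positive activity. The endpoint catalogue
marks the two loss-direction series (SOX17 down, cell count down) as
inverted; SOX2 and BRA series stay on the raw percent-responder scale since
directed endoderm induction leaves them near zero.

The efficacy cutoff is `coff = 3 * bmad`, with `bmad` the MAD of
solvent-control responses pooled across all plates of the screen for that
endpoint. Pooling across plates (rather than per experimental block) is the
default reading; `baseline_cutoff()` can be applied per block by grouping
beforehand.

Each series is fit with three candidate mean models in
`x = log10(conc uM)` — constant 0, Hill
`tp / (1 + 10^((ga - x) gw))`, and gain-loss
`tp [1 + 10^((ga - x) gw)]^-1 [1 + 10^((x - la) lw)]^-1` — by maximum
likelihood under a Student-t error model with 4 degrees of freedom
(Gaussian selectable). The heavy-tailed error model keeps single outlying
wells from steering the fit, which matters at 4 replicates per
concentration. Numerical choices:

* **Bounds.** `tp` in `[0, 1.2 * max|resp|]`, `ga` within the tested
  log-concentration range ±1, Hill coefficients in `(0.3, 8]`, the loss
  midpoint allowed up to 2 decades above the top tested concentration, and
  `log(sigma)` in `[log 1e-4, log 1e4]` (the floor keeps noiseless series
  finite).
* **Starts.** Three deterministic starts per model with `ga` at the 25/50/75%
  quantiles of the tested log-concentrations; L-BFGS-B, tight convergence
  (`factr = 1e4`). Deterministic starts make fits exactly reproducible
  without consuming random-number state.
* **Selection.** Winner = minimal AIC among converged models, counting the
  error scale as a parameter (constant 1, Hill 4, gain-loss 6); exact ties
  go to the simpler model. On pure-noise series a Hill-family model
  out-scores the constant at roughly the boundary chi-square rate (~6%),
  which is why model selection alone is not the hit rule.
* **Hit rule.** `hitc = 1` iff the maximum per-concentration median response
  reaches `coff` *and* the winner is non-constant. The extra winner
  condition prevents large-`coff` noise exceedances from hitting.
* **Potency.** `AC50 = 10^ga`. The activity concentration at cutoff (ACC) is
  the lowest concentration where the winning curve crosses `coff`:
  closed-form inversion for Hill, first-crossing root finding on a fine grid
  for gain-loss. A hit whose fitted top never reaches the cutoff keeps its
  call but gets `acc_uM = NA` and a flag; two further cautionary booleans
  mark borderline hits (`|max_med - coff| < 0.1 coff`) and ACC values below
  the lowest tested concentration (extrapolated).
* **Combined call.** The sensitivity-raising rule is a logical OR of the
  SOX17-loss and cell-count-loss hits.

## Plate QC

From %SOX17+ of control wells: `S/B = xPos / xNeg`,
`rCV = 100 madPos / xPos` (inter-plate rCV = median of per-plate values),
`rZ' = 1 - 3 (madPos + madNeg) / |xPos - xNeg|`. The positive control is
configurable between the solvent-exposed endoderm wells (default — they are
the population treatments are normalized against) and the plain endoderm
wells; the negative control is the pluripotent population. Degenerate cases
(zero or equal medians) return `NA` with a warning rather than infinities.

## Scorecard model

Per replicate, `dCt = Ct(gene) - mean(Ct of the five housekeeping genes)`;
per gene, `ddCt = mean(sample dCt) - reference-panel mean dCt` and
`log2FC = -ddCt`. Per-gene evidence for increased expression is a
one-sample, one-sided t-test of the sample dCt replicates against the
reference mean (alternative: dCt decreased), with p-values clipped to
`[1e-12, 1 - 1e-12]` so their normal quantiles stay finite; zero-variance
samples degenerate to the clip value on the side of the observed mean.
Set-level scores use the correlation-adjusted Stouffer combination
`Z = sum(Z_k) / sqrt(N + 2 sum_{k<j} r_kj)`. The combined `Z` is reported
as the differentiation-state score — higher scores mean more genes with
significantly increased expression than the average pluripotent state — with
the tail probability `1 - pnorm(Z)` alongside, since either could back a
heatmap display. Reference correlations default to 0 (independence): the
published panel's gene-gene correlations are not reproduced here, and with
`r = 0` the null calibration of the combined tail probability is exact
(verified by simulation in the tests).

## What the generator emulates, and what it does not

`simulate_plate()` produces the object-level table an imaging platform
would export, with this structure:

* **Intensities**: two-component lognormal mixtures per channel
  (`meanlog log(100)` negative, `log(2000)` positive, `sdlog 0.4`). The
  separation is wide enough that the 5*MAD gate sits cleanly between the
  components, reproducing the thresholdable bimodality of reporter
  intensity histograms; gated percentages then agree with the latent states
  to within binomial noise, which is what makes the generator usable as a
  gating oracle.
* **Counts**: negative binomial (mean 2000 counted nuclei/well, size 30) —
  overdispersed relative to Poisson, as seeded-and-grown well counts are.
  The assay seeds 2.8e3 cells/well; 2000 counted nuclei reflects
  post-processing attrition and keeps per-well binomial noise realistic.
* **Biology**: endoderm controls at 70.2% SOX17-positive, 0.45%
  BRA-positive background; solvent exposure multiplies the SOX17-positive
  probability by (1 - 0.195) without touching counts; treatment wells start
  from the solvent-suppressed baseline and apply a Hill-shaped fractional
  suppression, with an independent Hill term scaling expected cell count.
* **Well-to-well variability**: a logit-scale normal random effect
  (sd 0.14) on each well's positive probability, i.e. ~3.5 percentage
  points at the solvent operating point — consistent with the control
  spread and robust-CV levels a well-behaved screen reports, and the main
  driver of the simulated efficacy cutoff landing near 20%.
* **Layout**: 12 technical replicate wells per control role per plate
  (pluripotent, endoderm, solvent, TGF-beta-inhibitor positive control),
  treatments in the interior; the default 8-point series spans 1e-6 to
  200 uM, half-log dense at the top. Replicate-plate structure (plates x
  biological replicates) is left as free parameters of the layout
  builders.

Not emulated: pixel-level images and segmentation (the generator emits
per-cell statistics, not fields of view), spatial plate effects (edge
gradients, dispensing streaks), channel crosstalk, and time-course
dynamics. Passing tests on synthetic data therefore demonstrate that the
analysis chain is correct and well calibrated for data with this
statistical structure — not that the assay's imaging and wet-lab steps are
robust to artifacts the generator does not model.

The Ct-panel generator plays the analogous role for the scorecard: a
deterministic per-gene baseline dCt profile (pluripotency genes expressed,
lineage genes silent), a synthetic 10-line reference panel around it
(between-line sd 0.5 cycles), replicate noise of 0.25 cycles, and
log2 shifts injected under the directed-endoderm state (SOX17 +5.5,
EOMES +9.2, GATA6 +8.9, NODAL +6.9, SOX2 -5.3, BRA -3.1, and companions).
The reference panel is a labelled synthetic stand-in, not the published
multi-line dataset, so cross-line scores are exercised structurally, not
reproduced numerically.

## Benchmark tables and conventions

The packaged CSVs transcribe the published chemical tables verbatim,
including censored potencies. Conventions: `">200"` entries are stored as
censored-above bounds and count as exceeding any threshold at or below the
bound; `"<x"` entries pass a threshold when their bound does; `NA` means
the potency was never reached and always fails an activity requirement.
Effect bands are half-open at the lower edge — weak `[0, 20)`, moderate
`[20, 80)`, high `[80, 100]` — resolving the overlapping printed ranges.
Confusion metrics are compared to printed values at the printed precision.

## Problem sizes used in the tests

Unit tests run reduced wells (300 cells/well) because every statistic under
test is a per-well fraction, insensitive to the absolute count; calibration
and recovery checks use the full default configuration: 12 plates x 12
control replicates for QC and cutoff calibration, 50 seeded end-to-end
screens for AC50 recovery, 100 for the null hit rate, and 1000 simulated
panels for scorecard null calibration. These sizes give stable estimates of
each property while keeping the suite quick to run.

## Known limitations

* The raw-screen summary numbers of the original study (control S/B, rCV,
  rZ', the 20.3% cutoff, per-chemical IC50s) are not exactly reproducible
  without the underlying well-level data; the simulator is calibrated to
  the same operating conditions and the tests check the corresponding
  properties and ranges instead.
* The gain-loss ACC uses grid-assisted root finding; curves that touch the
  cutoff tangentially (no sign change at grid resolution) would be missed,
  though fitted screening curves do not produce this in practice.
* The hit rule is deliberately binary with two cautionary flags; the full
  cautionary-flag taxonomy of pipeline-grade database exports is out of
  scope.
* Scorecard set scores assume gene-level independence unless a correlation
  matrix is supplied.
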