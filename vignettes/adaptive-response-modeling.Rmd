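---
title: "Modeling adaptive drug response from perturbation signaling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adaptive drug response from perturbation signaling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptsig)
```

## The problem and the modeling strategy

BRAF-mutant melanoma cells exposed to RAF/MEK inhibitors remodel their
signaling within hours to days. Some of that remodeling is adaptive — it
protects cells from the drug — and some is incidental. `adaptsig`
formalizes the question "which signaling changes predict survival?" as a
regression problem per cell line: a conditions × variables matrix **X**
of z-scored log2 fold changes (drug × dose rows; signal × time columns)
against a single response *y*, the non-apoptotic viability of the same
conditions. The default design mirrors a multiplexed perturbation study:
5 drugs × 7 doses (a 1:3.16 dilution series from 3.2 µM down to 3.2 nM),
21 antibody readouts at 1, 5, 10, 24 and 48 h, and phenotype counts at
24, 48 and 72 h, giving a 35 × 105 predictor block and a 35 × 1 response.

Partial least squares regression is the right tool for this shape of
problem (many correlated predictors, few observations): it projects
**X** and *y* onto a small number of latent components chosen to explain
response covariance, and it comes with a per-variable importance score
(VIP) whose scale is self-calibrating (mean squared VIP = 1). The
package's modeling layer is written from scratch as single-response
NIPALS with deflation of both blocks, because the VIP formula consumes
per-component weight vectors `w_n`, and NIPALS defines them directly and
unambiguously with unit norm. For a single response, NIPALS and SIMPLS
predictions coincide up to sign; a test cross-checks predictions against
an independent PLS implementation (mixOmics) and against ordinary least
squares at full rank.

Assumptions worth stating explicitly: the signal–phenotype link is
modeled as linear on the z-scored scale; responses are summarized by one
number per condition (averaging 48 h and 72 h viability deliberately
absorbs differences in response *timing* between cell lines); and all
conditions are treated as exchangeable rows (no dose–time smoothness is
imposed).

## Preprocessing rules

* **Replicate outliers** — per condition, the 4 biological × 2 technical
  replicates are pooled and values outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`
  are removed. Quartiles use linear interpolation of order statistics
  (`stats::quantile` type 7), the most widespread convention; the filter
  is applied once (it is not mathematically idempotent — refiltering can
  shrink the fences — and a single pass is the documented contract).
* **Antibody QC** — antibodies whose biological-replicate condition
  profiles correlate below Pearson 0.5 (mean over replicate pairs,
  technical replicates averaged first) are dropped per cell line.
  Antibodies with fewer than two complete profiles are retained with a
  warning rather than silently judged.
* **Collapse and normalization** — the median of the retained replicates,
  log2-normalized to the median vehicle control of the same antibody and
  time point. Time-matched controls are used because cultures grow over
  the assay, so a 72-h treated well is only comparable to a 72-h control.
* **Autoscaling** — each design column is mean-centered and scaled to
  unit variance across the 35 conditions. The alternative (one global
  scaling) would leave columns with unequal variance and let
  high-variance signals dominate the projection, defeating the purpose of
  per-variable importance; per-column scaling is therefore used. Columns
  with zero variance are flagged and set to zero, never divided.
  Missing design cells are a hard error by default; column-mean
  imputation exists behind an explicit flag.

## Model fit, validation, importance

Cross-validation is tenfold with a seeded random partition; centering and
scaling are re-estimated inside every training split so no information
leaks from held-out rows. Reported metrics are R² (in-sample), Q² = 1 −
PRESS/TSS (TSS about the overall mean), and MSPE expressed as a percent
of response variance (100·PRESS/TSS), which makes Q² and MSPE two views
of the same quantity. Component count selection takes the smallest N
whose Q² is within 0.01 (configurable) of the best over 1..N_max —
additional components must earn their keep beyond noise.

VIP scores are computed exactly as
`VIP_k = sqrt(K · Σ_n w_nk²·SS_n / Σ_n SS_n)`; because weight columns
have unit norm, `Σ_k VIP_k² = K` is an identity and is asserted to 1e-6
on every fitted model. Signs come from the Pearson correlation of each
predictor column with the response (a zero correlation maps to +1 by
convention); the sign of the PLSR coefficient is available as an
alternative behind a flag, but raw correlation is the default because it
does not depend on component rotation. Scores in (0, 1] are zeroed — the
boundary value 1.0 is treated as insignificant, consistent with a strict
|VIP| > 1 significance reading. When two independent scanner/analysis
passes of the same arrays exist, variables whose condition-mean fold
changes disagree in sign between passes are removed, remaining signed
scores are averaged, and any residual sign conflicts are dropped and
counted.

Cell lines are clustered on their signed, thresholded VIP vectors with
Euclidean distance. The linkage is not dictated by the method description,
so average linkage was chosen: it is robust for the zero-inflated vectors
thresholding produces. Direct drug-target readouts (e.g. pMEK, pERK) can
be excluded by name before distances are computed, since their importance
is a trivial consequence of drug action. A brute-force O(n³)
agglomeration oracle in the test suite verifies the cophenetic distances.

## Phenotypes, dose response, synergy, gating

Non-apoptotic viability is `(total − apoptotic)` cells averaged over
replicates, divided by the time-matched vehicle value; the PLSR response
averages 48 h and 72 h (falling back to 48 h alone when late time points
cannot be scored). Dose–response curves are four-parameter Hill fits on
the log10-dose axis via multi-start Levenberg–Marquardt; a single start
stalls in local minima for shallow or right-shifted curves, so a small
grid of starting values is tried and the best deviance kept. IC50 is the
*absolute* 50%-viability crossing (reported absent when no crossing
occurs within 100× the tested range), distinct from the half-effect EC50,
because the sensitivity cutoff (log10 IC50 [M] < −6.5, strict) is an
absolute-concentration rule. Emax is the fractional effect at the top
*tested* dose. AUC is the trapezoidal area over log10 dose normalized by
the log-dose span, so a fully unresponsive line scores exactly 1 and
scores are comparable between 7- and 9-point designs. Parameter-recovery
tests draw EC50 from [10⁻³, 10] µM and therefore use a 12-point grid from
100 µM that spans that range: a curve saturated over the tested doses is
not identifiable from any fit (at double precision the residual can reach
~10⁻¹⁶ with E_inf off by 0.02), which is a property of the data, not the
optimizer.

Combination effects are scored against Bliss independence,
`I_XY = I_X + I_Y − I_X·I_Y`, with activity defined as the apoptotic
fraction by default (1 − relative viability available via the grid
construction); the excess over the prediction (EOBI) per dose pair is the
synergy readout.

Single-cell gating replaces manual quadrant drawing with a reproducible
rule: a two-component Gaussian mixture on log2 intensities of
vehicle-control cells, threshold at the posterior crossover between the
components, one-component-preferred fits flagged degenerate (gate +∞, all
cells Low). Gates are fitted on vehicle cells and *then* applied to all
conditions of the same cell line, so drug-induced shifts are measured
against a fixed reference; refitting per condition would confound the
shift being measured. A manual threshold override exists for parity
checks. Quadrant membership uses strict `>` so the rule is invariant
under monotone transforms applied jointly to intensities and thresholds.

Biomarker screens use Spearman correlation (average ranks, t
approximation for p-values; exact permutation available for n ≤ 10) and
first-order partial Spearman
`ρ_xy·z = (ρ_xy − ρ_xz·ρ_yz) / sqrt((1−ρ_xz²)(1−ρ_yz²))` to separate,
e.g., the predictive value of pS6 inhibition from the extent of target
(pERK) inhibition.

## What the synthetic generator emulates — and what it does not

The generator plants a low-rank latent structure: `n_latent` "pathway
activities", each following a per-drug Hill dose response multiplied by a
time profile that either ramps up or flips sign after a switch time (the
early-down/late-up pattern characteristic of adaptive rebound). A chosen
fraction of signals loads on these latents; viability is 1 minus a
time-ramped positive combination of the latent activities, clipped to
[0.02, 1]. Phenotype counts are Poisson totals with binomial apoptotic
subsets whose means follow that link, so expected non-apoptotic viability
equals the ground truth exactly. Single-cell intensities are
two-component log-normal mixtures whose High weight shifts with latent
activity; combination grids are Bliss predictions plus a planted excess.

Defaults are the study conditions: 10 cell lines, 5 drugs, 7 doses
(1:3.16 from 3.2 µM), 21 signals at 1/5/10/24/48 h, phenotypes at
24/48/72 h, 4 × 2 replicates, 2 scanner passes. Where the design left a
magnitude open, one realistic value was fixed: replicate noise 0.15 on
the log2 scale, a condition-level biological effect of sd 0.3 shared
across replicates (without it, viability-unrelated antibodies would have
pure-noise replicate profiles and the antibody QC would — correctly —
remove all of them, which real arrays do not show), scanner gain sd 0.2
per antibody with 0.05 readout noise, and ~2000 cells per phenotype well.
Each generator draws from its own stream split deterministically from the
master seed, so stages can be re-run independently and all outputs are
byte-identical under the same configuration.

Passing tests on this generator demonstrate that the pipeline recovers
*planted* structure under *its* noise model: Gaussian log2 noise,
linear latent→signal maps, independent markers within cells, and no
spatial/plate artifacts, segmentation errors, antibody cross-reactivity,
or cell-line-specific growth confounds. Results on real arrays depend on
those unmodeled effects, and the fit statistics obtained here (R²/Q²
near 1 at the default noise levels) characterize the simulation, not any
real dataset.

## Numerical choices and degenerate inputs

* Weight sign convention: the largest-magnitude element of each weight
  column is made positive, so serialized models are platform-stable.
* Component extraction stops (with a warning) when residual covariance or
  score norm falls below 1e-12; requesting more components than the rank
  truncates with a warning; a constant response is an error.
* Q² ties are broken toward fewer components; tolerance 0 reproduces the
  Q² argmax.
* The sensitivity boundary uses a 1e-9 tolerance on log10 units so an
  IC50 exactly at the cutoff classifies deterministically (resistant).
* Gate fitting with < 100 cells warns; < 2 distinct values is an error;
  mixtures whose posteriors do not cross between the component means are
  flagged degenerate rather than silently gated.
* Spearman on constant input is flagged undefined, not NA-propagated.

## Problem sizes used by the test suite

Unit tests run the full single-cell-line design (35 × 105 with all
replicates); property tests use 200 random PLSR instances (12 × 6), 200
null-response cross-validations (35 × 10), 100 noiseless Hill curves, 20
seeded end-to-end runs for planted-variable recovery, and 50,000-cell
samples for gate recovery; the pipeline tests run two cell lines end to
end twice to compare content digests. These sizes keep the suite
comfortably under a minute while exercising every code path.

## Known limitations

* Single-response PLSR only; a multi-phenotype Y-block is out of scope.
* The consistency rule compares the sign of the condition-*mean* fold
  change per variable — the simplest faithful reading of "consistent up-
  or down-regulation"; per-variable agreement fractions are reported so
  stricter rules can be compared.
* Whether the IQR filter should pool all 8 replicates or act within
  biological replicate is ambiguous in the source protocol; pooling is
  implemented, matching the "total 4 × 2 replicates" phrasing.
* The generator does not attempt to match any real cell line's parameter
  values, and intensities are drawn directly (no image-level synthesis).
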