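---
title: "Methods: quantitative lung aeration from thoracic MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lung aeration from thoracic MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungaerate)
```

## The problem

Lung aeration — how much of the lung is gas — is the central quantity in
imaging of atelectasis and the acute respiratory distress syndrome. CT
measures it directly because Hounsfield units are calibrated to density;
MRI grey units (GU) are arbitrary, scanner- and session-dependent. This
package implements a calibration chain that makes conventional magnitude
MRI quantitative: normalize the signal to a reference tissue, calibrate
signal against gravimetric density on ex vivo lung samples, convert the
calibration into intensity thresholds for aeration compartments, and
carry those thresholds to in vivo scans through an atelectasis reference.

## Models

### Density–signal calibration

Each ex vivo lung sample of mass $M$ (weighed after airway removal) is
scanned at airway pressures 0, 40, 10, 2 cmH2O; segmentation gives its
volume $V$ (mL) and mean signal $S$ (GU), so density is
$\rho = M/V$ (g/mL). Two fixed-effect forms are fitted by maximum
likelihood with a random intercept per lung (the four pressure levels are
repeated measures) and a fixed additive indicator for injured (fluid-
instilled) samples:

$$\rho = a\,s + b \qquad \text{and} \qquad \rho = a\,s^2 + b,$$

where $s$ is the mean lung signal, raw or divided by the water- or
muscle-tube signal. The quadratic form is exactly $a s^2 + b$ — no linear
term — because that is the candidate the calibration compares against the
linear form; adding the full polynomial would change the question being
asked. Models are ranked by AICc with
$k$ = fixed effects + variance components; ML (not REML) is used
throughout so that likelihoods are comparable across fixed-effect
structures. The injury-effect p-value is a likelihood-ratio test against
the same model without the indicator (the alternative, a Wald test, is
asymptotically equivalent but the LRT is exact under the ML machinery
already in place). If the between-lung variance collapses to zero or the
mixed fit fails, the fit falls back to fixed-effects-only least squares
with a warning; $k$ then counts one variance component.

### Attenuation line and thresholds

For translation, absolute calibration is replaced by a relative one. With
the deflated (0 cmH2O) scan of each sample as its own reference,

$$\mathrm{MRI_{ATT}} = S_{\mathrm{CPAP}}/S_0, \qquad
  \mathrm{GAS_F} = (V_{\mathrm{CPAP}} - V_0)/V_{\mathrm{CPAP}},$$

and the line $\mathrm{MRI_{ATT}} = \beta_1\,\mathrm{GAS_F} + \beta_0$ is
fitted with a per-lung random intercept. The deflated rows sit at
$(0, 1)$ *by construction* — the ratio definition pins them — so they are
excluded from the regression by default (`include_reference = TRUE`
restores them); including points that carry no information about the
relation would drag the intercept toward 1. Aeration thresholds are read
off the line at the CT-convention gas-fraction cut-offs:
$t = \beta_0 + \beta_1 c$ for $c = 0.1$ (non-aerated below) and $c = 0.5$
(poorly aerated below). If the signal were strictly proportional to
density, $\mathrm{MRI_{ATT}} = 1 - \mathrm{GAS_F}$ exactly, giving the
analytic check slope $-1$, intercept $1$, thresholds $0.9$ and $0.5$ —
the test suite verifies this limit to $10^{-9}$.

Confidence intervals come from a nonparametric cluster bootstrap: lungs
(not observations) are resampled with replacement, the line is refit on
the pooled resampled observations, and percentile intervals are taken
over 1000 seeded replicates. The bootstrap refits use ordinary least
squares rather than the mixed model: the threshold is a fixed-effect
quantity and resampling whole lungs already propagates the between-lung
variability, at a fraction of the cost of one thousand mixed fits.

### Translation to in vivo scans

In vivo, lungs are surrounded by chest wall and cannot be deflated, so
the absolute density–signal law does not carry over, but the *relative*
attenuation relation does. Fully non-aerated tissue (atelectasis) is the
in vivo analogue of the deflated sample: its mean muscle-normalized
intensity $\mathrm{MRI_{ATEL}}$ (2.03 cm³ cubic ROI in the middle of the
collapse; the ex vivo references use a 2.03 cm³ *sphere* — both shapes
are honoured as specified) rescales the attenuation thresholds,

$$t_{\mathrm{invivo}} = \mathrm{MRI_{ATEL}} \times t_{\mathrm{att}}.$$

With $\mathrm{MRI_{ATEL}} = 0.92$ and attenuation thresholds 0.70 / 0.28
this yields 0.644 and 0.2576, i.e. 0.64 and 0.26 at the two-decimal
precision used in practice. Thresholds are applied at full precision by
default; `rounded = TRUE` applies the two-decimal values for strict
reproduction of reported analyses.

### Classification and regional analysis

Voxel classification uses half-open bands — non-aerated at
$s \ge t_{non}$, poorly aerated at $t_{poor} \le s < t_{non}$, else
normally/hyper-aerated (one merged class: hyperaerated tissue has too
little signal to subdivide at clinical SNR). The boundary inclusivity is
a pure convention — ties are measure-zero in real data — but tests need
determinism. Multi-breath-hold acquisitions arrive as 2–3 axial blocks
with independent gain; each block is divided by its own muscle reference
(0.46 cm² disc in the block's middle slice) *before* concatenation,
which is the only order that makes merged intensities comparable. The
ventro-dorsal split halves the lung mask at the geometric midpoint of its
anterior–posterior bounding box (equal extent, not equal voxel count),
reading "equally spaced" geometrically.

### Paired statistics

Pre/post comparisons use the Wilcoxon signed-rank test in its normal
approximation without continuity correction (zero differences dropped,
tie-corrected variance). This specific variant is deliberate: for six
uniformly signed differences it gives $p = 0.0277$, which reproduces the
conventionally reported 0.028, whereas the exact permutation test gives
0.03125. The regional analysis is a classical within-subject 2×2 ANOVA
(ROI × time, subject as block) with Sidak-adjusted
($1-(1-p)^m$) paired post hocs, in two families of $m = 2$; inputs with
zero variance return $p = 1$ with a warning instead of failing. The
design sample size for detecting a correlation uses the standard
two-sided Fisher-z formula
$n = \lceil ((z_{\alpha/2}+z_\beta)/\operatorname{atanh} r)^2 + 3 \rceil$,
which gives $n = 12$ for $r = 0.8$, $\alpha = 0.05$, power 0.9 (the
one-sided variant gives 11; smaller figures sometimes quoted for this
design are not reproducible from either form).

## The synthetic-data generators

No public scan archive accompanies this method, so validation rests on
digital phantoms with exact ground truth.

**Ex vivo** (`exvivo_config()`, `simulate_exvivo_samples()`,
`generate_exvivo_dataset()`): 8 healthy + 3 injured samples, masses
drawn at 131.4 ± 34.6 g, deflated specific volume 0.96 mL/g (deflated
lung tissue is slightly denser than water), inflation factors
{1, 3.57, 2.22, 1.54} at {0, 40, 10, 2} cmH2O chosen to span gas
fractions 0–0.72. The generator paints the normalized signal as the
*exact inverse* of the analysis-direction quadratic
($\rho = 1.22 s^2 + 0.05$), so fitting is a closed loop: with all noise
set to zero the fitted $(a, b)$ equal the generating values to $10^{-6}$
(table route) and to better than 1% through the full image route, where
the residual error is ellipsoid rasterization (≤ 2% in volume on the
coarse test grids — voxel-centre rasterization errs with the surface
area, not by a single voxel). A proportional mode ($s \propto \rho$)
provides the analytic attenuation limit above. Default measurement
noise — signal SD 0.015 (normalized units), 1% volume noise, 0.5%
reference jitter, 0.02 g/mL between-sample offsets, session gains
{1, 1.15, 0.9} — was chosen once as plausible bench-study precision; it
is calibrated only to summary-level targets, since no per-sample scan
values are published.

Two attenuation-level configurations are frozen in the tests: a pure
estimator testbed (line slope −1.05, intercept 0.805, single residual SD
0.03, 11 lungs × 4 pressure levels all drawn from the line) used for
bias and bootstrap-coverage studies, and a "study-matched" physical
configuration (pinned deflated reference, between-lung SD 0.02, residual
SD 0.042, fit on the three inflated levels) whose noise was tuned once so
the fit statistic lands at $R^2 \approx 0.93$, and then frozen.

**In vivo** (`invivo_config()`, `generate_invivo_scan()`): a 72×60×36
grid at 2.5×2.5×4 mm (three 48 mm blocks) holding an elliptical body
with posterior muscle band and two lung ellipsoids (~654 mL total). The
most dorsal 10% of left-lung voxels are painted at the atelectasis
intensity 0.92; the next most dorsal 16% of lung voxels span the poorly
aerated band and the rest the normally aerated band, each band ending
0.10 normalized units clear of the classification thresholds. This
yields exact painted compartment fractions, a monotone ventro-dorsal
gradient, and a histogram with no mass near the thresholds — so the
noiseless phantom classifies exactly, the ±5% sensitivity deltas vanish
by construction, and under Rician noise of SD 0.05 the leakage across
thresholds stays within a few tenths of a percent of TLV. Per-block
gains {1, 1.12, 0.95} cancel after muscle normalization.

Rician noise is applied as
$v \mapsto \sqrt{(v+n_1)^2 + n_2^2}$, $n_i \sim N(0, \sigma^2)$ —
magnitude images are non-negative and their air background averages to
$\sigma\sqrt{\pi/2}$, which is what makes the SNR definition
$S_{lung}/S_{air}$ finite.

**What the phantoms do not emulate**: anatomy (ellipsoids, no airways or
vessels), perfusion, chest-wall signal attenuation (named as the reason
the absolute density law cannot be translated), B1/bias fields,
respiratory motion, T1/T2 contrast physics (sequence parameters are
metadata only), and partial-volume mixing at lobe boundaries. Passing
phantom tests therefore demonstrates the correctness of the computational
chain — volumetry, normalization, merging, fitting, thresholding,
reporting — not the clinical accuracy of the thresholds themselves.

## Numerical and interface choices

* ROI membership is by voxel-centre inclusion, no partial-volume
  weighting: deterministic and testable. Sphere radius $(3V/4\pi)^{1/3}$
  (7.85 mm at 2.03 cm³), cube side $V^{1/3}$ (12.66 mm), disc radius
  $\sqrt{A/\pi}$ (3.83 mm at 0.46 cm²).
* Volumes are magnitude images: negative intensities on load are clamped
  to 0 with a warning.
* DICOM slices are ordered by the projection of ImagePositionPatient onto
  the slice normal — robust to renumbered exports; inter-slice spacing
  inconsistent beyond 1% is a hard error naming the offending slices. The
  reader/writer covers uncompressed Explicit-VR little-endian magnitude
  series (16-bit with rescale slope), the form scanners export for this
  analysis.
* Masks store no independent geometry; they inherit spacing/origin from
  their paired volume, making volume/mask mismatch unrepresentable.
  Whether reference-tube ROIs are re-placed per pressure level is left to
  the ROI config; the simulators re-measure them per scan.
* Gas fractions slightly below zero (volumetry noise at low pressures)
  are kept as-is for fitting and clamped only below −0.05 (warning);
  classification never sees them since it operates on intensities.
* Descriptive summaries of the sample table use the population SD
  (divisor $n$): that is the convention under which the tabulated
   34.6 g and 0.02 g/g figures are reproduced, and it is stated in the
  function documentation.
* Whole-lung normalized signal is the mean of per-block-normalized
  voxels (consistent with per-block muscle sampling), not a whole-scan
  mean divided by a single muscle value; with equal block gains the two
  coincide.
* Every JSON output embeds the package version, the RNG seed and a
  config hash, so reruns with identical inputs are byte-identical except
  for file timestamps.

## Problem sizes

The test suite runs the full bench-study scale where it matters
(11 lungs × 4 pressures; 200 replicate datasets with 1000-rep bootstraps
for coverage; 100 replicates for model selection and covariate power;
20 noisy phantom seeds) and scales the image-level closed loops down to
three light samples on a coarse 3×3×4 mm grid — the rasterization
arithmetic is identical, only the voxel counts differ. The thorax
phantom runs at full configured size (~155k voxels) in under a second.

## Limitations

The calibration is only as portable as its reference: muscle signal
varies with age, hydration and nutrition, and chest-wall attenuation
differs between subjects — neither is corrected for. No hyperaeration
threshold is provided (insufficient SNR at very low density). No image
registration is performed; pre/post comparisons are on summary
statistics. The DICOM support is deliberately minimal (no compressed
transfer syntaxes, no multi-frame objects). The bootstrap CIs are
percentile intervals over 11 lungs; with so few clusters their coverage
is near, not exactly at, the nominal level (measured ≥ 90% in the
package's acceptance tests).
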