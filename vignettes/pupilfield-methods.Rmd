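---
title: "Methods: light-adapted pupil analysis with pupilfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light-adapted pupil analysis with pupilfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilfield)
```

`pupilfield` analyses steady-state (light-adapted) pupil size measured in the
field with a wearable eye tracker synchronized to a near-corneal
spectroradiometer. This vignette is the package's own account of its methods:
the models, the numerical choices, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable implementation existed.

## Alpha-opic photometry

Each 10 s spectral irradiance sample (irregular wavelength grid within
350--800 nm, W m⁻² nm⁻¹) is reduced to the light metrics that drive the
analyses: photopic illuminance $E_V$, the five alpha-opic irradiances, and
the five alpha-opic equivalent daylight illuminances (EDIs). The melanopic
EDI (mEDI) is the illuminance of standard daylight producing the same
melanopic irradiance as the test spectrum; the melanopic daylight efficacy
ratio (DER) is mEDI divided by illuminance (≈1 for daylight, <1 for warm
LEDs, >1 for blue-rich light).

**Regridding.** "Energy-preserving interpolation" admits several readings; we
implement conservative (flux-preserving) rebinning. The raw samples define a
piecewise-linear spectral density; negative readings (instrument noise) are
clamped to zero and counted; data outside 380--780 nm are discarded; each
destination value on the canonical 380, 381, ..., 780 nm grid is the mean
density over its 1 nm bin, with half bins at the two grid edges. This
conserves band energy exactly (to floating-point rounding) over every
bin-edge-aligned band and hence over the full visible band — a point-sampling
interpolation does not. Energy over an *arbitrary* sub-interval is conserved
only up to the within-bin variation of the source spectrum: a 401-value
representation cannot reproduce every integral of a richer function, so the
package's tests assert exact conservation at bin granularity and
percent-level agreement for arbitrary wide bands.

**Action spectra.** The official alpha-opic tabulations are not shipped with
the package. Instead the six weighting functions are deterministic
reconstructions: the Govardovskii (2000) A1 opsin nomogram at the standard
peak wavelengths (S 419, M 530.3, L 558.9 nm, rhodopsin 496.3 nm, melanopsin
480 nm), multiplied by a young-adult ocular-media transmittance (exponential
lens density, 0.8 at 400 nm with a 30 nm decay scale), converted from quantal
to energy units and peak-normalized. The photopic curve is the luminous
efficiency reconstruction $1.55\,\bar l(\lambda) + \bar m(\lambda)$
(normalized), which places its peak within 2 nm of 555 nm and gives
$V(555) > 0.995$. Illuminance uses $K_m = 683.002$ lm W⁻¹ (the SI value; the
source protocol does not state one). The daylight normalization reference is
a 6504 K Planckian radiator; the five normalization constants (alpha-opic
irradiance per lux of the reference) are computed once from the embedded
curves, so by construction every EDI of the reference equals its illuminance
— the identity every downstream analysis relies on. Reconstructed curves can
differ from specific standards tabulations at the few-percent level;
because normalization is self-consistent, this shifts absolute EDI values
slightly but none of the package's comparative statistics.

## Quality control

An observation is retained iff the pupil estimate is present, detection
confidence ≥ 0.6, the diameter lies in the physiological 1--9 mm range
(inclusive bounds: the stated rules exclude "less than 0.6" and values
"outside" the range), and the spectrum did not saturate. Because one frame
can violate several rules, per-rule counts use a fixed precedence —
confidence (a missing pupil counts as confidence 0), then range, then
saturation — so the counts partition the sample exactly.

Participants are excluded when their per-participant loss fraction exceeds a
threshold, *strictly*: a participant at exactly the threshold is retained.
The threshold can be fixed (0.75 by default) or chosen by the scree rule:
over candidate thresholds 0.50, 0.55, ..., 0.95, find the first step beyond
0.50 at which raising the threshold excludes the fewest additional
participants, i.e. the start of the flattest step of the exclusion curve.
Ties resolve to the smallest qualifying threshold so the rule is
deterministic; the full count curve is returned for plotting.

## Mixed models and Bayes factors

All hypothesis tests are random-intercept linear mixed models fitted by
maximum likelihood with `lme4`:

```
pupil ~ log10(mEDI) + age + (1 | participant) + (1 | sex)
```

against the null model lacking the term under test (for the
melanopic-vs-photopic comparison, the null swaps the light metric; this pair
is non-nested, which the criterion below handles without modification). The
`(1 | sex)` term has only two levels; such fits routinely end on the
zero-variance boundary, which is flagged (`singular`) but accepted —
fidelity to the registered model formulas is preferred over reparameterizing
them. Age enters in raw years. Light metrics are floored at 0.01 lx before
log10; dark frames are excluded from the confirmatory fits anyway (field
condition only). A zero-variance fixed predictor (e.g. an all-zero caffeine
column) is dropped with a record rather than treated as an error, whereas a
genuinely collinear design aborts naming the offending terms.

Evidence is summarized by the BIC approximation to the Bayes factor,

$$\log_{10}\mathrm{BF}_{10} \approx \frac{\mathrm{BIC}_0 -
\mathrm{BIC}_1}{2\ln 10},$$

rather than Monte-Carlo integration under JZS priors. The approximation is
deterministic, fast and model-agnostic, and the analyses consume Bayes
factors *categorically* (anecdotal < moderate < strong < very strong <
decisive, with thresholds at BF = 3, 10, 30, 100); exact magnitudes under a
particular prior are not reproduced, and every result carries a `method`
tag saying so. Boundary values fall into the weaker category (BF exactly 10
is "moderate"), negative values mirror the scale with a `null-` prefix, and
BIC-based matrices of pairwise comparisons are exactly antisymmetric.

Model diagnostics follow the checks that motivated the log10 transform:
residual-vs-fitted trend, a heteroscedasticity slope (|residual| on fitted),
and collinearity via pairwise correlations and variance inflation factors.
Serial dependence is quantified by a per-participant sample ACF on the 10 s
grid, with lagged pairs spanning gaps dropped and constant series flagged as
undefined.

## Age analyses

Field observations are grouped into half-open mEDI clusters [1, 10), [10,
100), [100, 1000) and [1000, ∞) lx; the boundary rule is a package decision
(the source text says "between 1 and 10 lx"). The dark-adaptation condition
is its own cluster regardless of residual mEDI; field frames below 1 lx and
all lab/transition frames are unassigned. Per participant and cluster we
report the median and IQR with linear-interpolation (type 7) quartiles —
again a convention choice, applied consistently and cross-checked against a
brute-force quantile oracle in the tests.

Cluster age effects are plain OLS of per-participant medians on age (the
source analyses use OLS on medians, not mixed models), with t-based 95% CIs;
slopes are also reported per decade (×10). Per-individual dose--response
fits regress pupil on log10 mEDI pooling field and dark data, dark frames
entering at the 0.01 lx floor (configurable — the floor's exact value is not
stated by the protocol, and a different floor shifts individual intercepts
slightly). The pupil-range regression uses max − min diameter per
participant (≥ 20 valid frames including dark adaptation) on age.

As a literature reference predictor the package includes the Watson--Yellott
unified formula: effective corneal flux = luminance × field area × 0.1 if
monocular, passed through the Stanley--Davies dose--response
$D = 7.75 - 5.75\,q/(q+2)$ with $q = (F/846)^{0.41}$, plus the linear age
correction $(y - 28.58)(0.02132 - 0.009562\,D)$.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without the
study's wearable recordings. Its defaults *are* the study conditions:

* **Cohort.** Ages uniform on 18--87 (uniform rather than the study's
  young-skewed histogram, to maximize regression power), balanced sexes,
  iris colours at frequencies 0.30/0.20/0.49, log-normal caffeine intake,
  Gaussian participant intercepts (default SD 0.3 mm — a repo choice; the
  source reports no quantitative noise magnitudes).
* **Pupil model, log-linear mode.** Intercept and slope interpolate linearly
  in age between the printed case regressions (age 18: 6.28 mm, −0.998 mm
  per log10-unit mEDI; age 87: 3.83 mm, −0.463 mm), plus the participant
  intercept, clipped to 1--9 mm.
* **Pupil model, cluster mode.** Per-cluster age regressions (dark: 8.13 mm,
  −0.408 mm/decade; 1--10 lx: 6.16, −0.374; 10--100 lx: 4.32, −0.198;
  100--1000 lx: 3.55, −0.141; >1000 lx: 2.57, −0.080). Two modes exist
  because the continuous and clustered parameterizations are not mutually
  consistent on real data. Sub-1 lx field frames borrow the 1--10 lx
  parameters; they are excluded from cluster analyses regardless.
* **Spectra.** Illuminance log-uniform over 0.5--100,000 lx; daylight above
  1000 lx, a daylight/LED/fluorescent mixture below. LEDs are Gaussian
  primaries (467/527/630 nm, 25 nm FWHM) plus a two-Gaussian phosphor white;
  fluorescents a narrow line comb. Daylight is a Planckian radiator at a
  *mired-compressed* effective temperature, $1/T_\mathrm{eff} = 1/6504 +
  0.7\,(1/T - 1/6504)$: a raw blackbody at 5000 K has melanopic DER 0.87
  against the 6504 K reference, below the realistic daylight band, while the
  0.7 compression reproduces published daylight-series DERs (≈0.91 at
  5000 K, ≈1.04 at 7500 K). The factor was fixed once against those
  published values. Every generated spectrum is rescaled to its target
  illuminance exactly.
* **Noise and artifacts.** Pupil noise SD falls linearly from 0.5 mm at
  1 lx mEDI to 0.15 mm at 10⁴ lx (the observed shrinking of variability
  with light level; exact taps are repo choices), and the QC artifact rates
  default to the observed ones: 43.37% sub-0.6 confidence, 0.16%
  out-of-range, 1.41% saturated.
* **Lab protocol.** Four 3 min colour phases in seeded random order, 20 s
  dark intervals before/after each, three ascending 1 min levels (10, 100,
  colour maximum 480/250/1000/1000 lx) — 13 min 40 s, 82 frames. The
  narrow-band primaries dissociate illuminance from mEDI, which is what
  makes the melanopic-vs-photopic comparison decisive there.

What the generator does **not** emulate: serial carry-over (frames are
exchangeable given the light level, so the strong real-world
autocorrelation of pupil size and mEDI is absent), gaze geometry and task
structure, weather/seasonal light-availability structure, and any spectral
diet beyond the three illuminant families. Passing tests therefore
demonstrate that the pipeline recovers what the generator encodes — they do
not certify behaviour on recordings whose artifact structure differs.

## Problem sizes and tolerances

The package's tests run cohorts of 40--83 participants with 100--460 frames
each (raw spectra are simulated in full, ≈30k spectra for the largest
cohort), 20 seeded replicates for the evidence-direction and
parameter-recovery properties, and a 5000-sample field run for the
lux--mEDI coupling. Regression recovery is asserted at absolute tolerances
derived from the design's standard errors (±0.05--0.06 mm/decade for
cluster slopes, ±0.1--0.3 mm for intercepts at 3--4 SE); energy
conservation at 10⁻⁹ relative; the daylight EDI identity at 0.1%. Evidence
checks are categorical (sign and the decisive threshold), mirroring how the
source analyses are consumed.

## Known limitations

* Absolute EDIs depend on the reconstructed action spectra and daylight
  reference (few-percent scale); comparisons and categorical inferences do
  not.
* BIC-approximated Bayes factors penalize parameters more harshly than JZS
  priors at these sample sizes; magnitudes are not comparable to
  Monte-Carlo values, categories and signs are.
* The scree rule assumes the loss distribution has a flat step; on
  pathological loss curves the smallest-threshold tie-break is arbitrary
  (but deterministic).
* `(1 | sex)` with two levels estimates its variance poorly; it is kept for
  formula fidelity and its boundary fits are flagged.
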