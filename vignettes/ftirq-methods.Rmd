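---
title: "Calibration models, synthetic spectra and design choices in ftirq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration models, synthetic spectra and design choices in ftirq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ftirq` quantifies the flavonoids quercetin (QE), quercitrin (QI) and
rutin (RUT) — and their sum (SUM) — in dried buckwheat flowers and leaves
from mid-infrared ATR absorbance spectra (500–4000 cm⁻¹). This vignette is
the package's account of its science: the calibration model and its
assumptions, the synthetic data generator, the numerical conventions, and
the places where the design was genuinely open.

## The calibration model

Each candidate model is a univariate partial least squares regression
(PLS1) from transformed spectral variables to one concentration, built by
NIPALS: predictors are mean-centered, the weight vector of each latent
factor is the normalized covariance $X^\top y$, and $X$ and $y$ are
deflated by the factor's scores. PLS1 has no random initialization, so
fitting is deterministic. Predictors are **never variance-scaled**:
absorbance variables share physical units, and autoscaling would inflate
noise-only variables. The number of latent factors is chosen by
leave-one-out cross-validation on the calibration set over 1–20
candidates, capped at $\min(20,\, n_{\mathrm{cal}}-2,\, p)$ so small
designs stay feasible; ties in RMSECV break toward fewer factors
(parsimony — the choice only affects the reported factor count, not
correctness).

The assumptions this inherits: absorbance is linear in concentration
(Beer–Lambert, reasonable for thin effective path lengths of ATR),
concentration information survives the pretreatment chain, and the
calibration samples span the validation range. The last assumption is
enforced by the split rule below.

### Calibration/validation split

Samples are ranked by the reported reference concentration of the target
flavonoid; every fourth rank starting at the second becomes validation,
and the extreme samples (minimum and maximum) always stay in calibration
so validation never extrapolates. All replicate spectra of a sample share
its assignment — replicates of one physical sample on both sides of the
split would leak. The rule is deterministic on purpose: reports are
reproducible without bookkeeping a split RNG, and the rank stratification
gives validation sets that cover the concentration range. A random
grouped split would be equally defensible; determinism was chosen.

### Verdicts

With $\sigma$ the standard deviation of the reference HPLC determinations
for that plant part and flavonoid: *useful* means
$\mathrm{RMSEC} \le 3\sigma$, $\mathrm{RMSEV} \le 3\sigma$, and both
calibration and validation correlations above 0.9; *HPLC-comparable* adds
$\mathrm{RMSEV} \le \sigma$. Two conventions are deliberate:

- the correlation rule is applied to **both** the calibration and the
  validation coefficient — the conservative reading of "R > 0.9";
- the RMSE comparisons are **non-strict** (`<=`). A model whose RMSEC
  prints exactly at $3\sigma$ (e.g. 0.30 against $\sigma = 0.1$) is
  accepted; a strict inequality would reclassify borderline models over
  sub-printing-precision differences.

The flower and leaf analyses use their part-specific $\sigma$; the
combined analysis uses the pooled row of `reference_sd_table()`. One
oddity of the shipped defaults: the pooled QI value (0.06 mg/g) is
*smaller* than the flowers-only value (0.8 mg/g), which no pooled SD can
arithmetically be. The values are kept verbatim as supplied defaults
rather than silently "fixed"; anyone with better reference statistics can
pass their own table to `run_config()`/`run_search()`.

## Pretreatment

Eight chains: base transform in {none, SNV, Haar approximation, Haar
detail}, optionally followed by a first difference. Conventions:

- **Derivative** = plain successive difference, no Savitzky–Golay
  smoothing. Smoothing windows discard exactly the fine structure that
  distinguishes overlapping bands of similar compounds, so none is
  introduced. The omitted $1/\Delta\nu$ factor is a constant within a
  resolution and is absorbed by centering.
- **Haar** = one decomposition level with the orthonormal $1/\sqrt2$
  normalization, so energy conservation is exact
  ($\|a\|^2 + \|d\|^2 = \|x\|^2$) and testable to 1e-10. Odd-length
  inputs (the 219-point 16 cm⁻¹ grid) are padded by replicating the last
  point before pairing — deterministic, and the padded transform remains
  orthogonal.
- **Order**: base transform first, then derivative ("derivative of the
  transformed data"), and replicate averaging (when configured) happens on
  **raw** spectra *before* any pretreatment: SNV does not commute with the
  mean, so the order must be fixed; averaging raw spectra matches how an
  instrument operator would co-add measurements.
- SNV of a constant spectrum is undefined and errors rather than
  returning zeros: a flat spectrum is an acquisition failure, not data.

## Variable reduction

All three schemes keep exactly $\lfloor p/4 \rfloor$ of the $p$
transformed variables. RS1 and RS2 rank by absolute Pearson correlation
with the response computed on **calibration rows only** — correlations on
all samples would leak validation information into model building.
Zero-variance columns get correlation 0, and all ties break toward the
lower column index, so degenerate inputs (e.g. a constant response) still
give a deterministic mask. RS2 first restricts to the regions where the
pure standards absorb, 500–1700 and 2950–3500 cm⁻¹ (closed intervals,
which together cover half the spectral span); wavenumber labels are
tracked through derivative midpoints and wavelet pair midpoints
(`wavenumber_lineage()`) so the region test survives index shifts.

RS3 uses only the pure-standard spectra: each standard is min–max
normalized to [0, 1] — on absolute values for chains that can go negative
(derivative, detail), since peak magnitude, not sign, marks absorption —
and a variable's score is the maximum over the three standards. The
selection keeps the top $\lfloor p/4 \rfloor$ scores rather than applying
a fixed 0.4 intensity cutoff: the count criterion is exact while an
absolute cutoff cannot guarantee the count; the implied threshold (score
of the last variable kept) is reported, and for raw 4 cm⁻¹ standards it
lands near the conventional 0.4. RS3 masks depend only on (chain,
resolution), never on samples or responses.

Auxiliary variables, when enabled, are one-hot dummies over all seven
species (PLS is indifferent to the dummy-sum collinearity, and one-hot
keeps the coding symmetric) plus a plant-part dummy in the combined
analysis; they are appended **after** reduction and scaled to the median
absolute magnitude of the kept spectral variables so they are neither
dominant nor negligible.

## The synthetic data generator

No public archive of the original spectra exists, so the package
generates data with the statistical structure the analysis assumes.

**Standards.** Band models on the 4 cm⁻¹ grid: a shared flavonol-core
band list (aromatic ring modes, conjugated C=O, phenolic C–O, broad OH
stretch) plus rhamnose bands for QI and rhamnose + glucose bands for RUT.
This encodes the real difficulty — the three spectra are strongly mutually
correlated (shared core) yet linearly independent (sugar bands), and at
least 90% of their integrated absorbance lies inside the RS2 regions.
Gaussian line shapes by default (Lorentzian available); the choice is
immaterial to the chemometrics. A seed adds 2% band-height jitter
emulating lot-to-lot variation.

**Samples.** For each sample, true concentrations are drawn uniformly
from the plant-part-specific ranges (flowers: QE 0.09–3, QI 4.1–32,
RUT 18–110 mg/g; leaves: QE 0–1.8, QI 0–22, RUT 11–112 mg/g); SUM is
always the component sum, never drawn. An optional `range_skew` exponent
reproduces uneven concentration distributions without hard-coding them.
Each of 3 replicate spectra is

$$A(\nu) = m\left[\textstyle\sum_i c_i\,\epsilon_i(\nu) + M_s(\nu)\right]
  + b_0 + b_1\nu + e(\nu)$$

with $\epsilon_i$ the standards scaled by `absorptivity_scale`
(0.005 AU per mg/g, putting a 110 mg/g rutin sample near 0.55 AU at the
strongest band — the right order for ATR of dried plant tissue), $M_s$ a
16-band smooth plant-matrix spectrum specific to (species, plant part)
that deliberately overlaps the analyte bands, $m$ a log-normal scatter
factor, $(b_0, b_1)$ a per-replicate baseline, and $e$ i.i.d. Gaussian
noise. Defaults, chosen once as instrument-realistic:

| parameter | default | rationale |
|---|---|---|
| `noise_sd` | 5e-4 AU | RMS noise of a 50-scan DTGS average (single-scan mAU-level noise / √50) |
| `scatter_sd` | 0.08 | contact-pressure variation of ATR replicates |
| `baseline_amplitude` | 0.01 AU | small drift; slope SD is this / 3500 cm⁻¹ |
| `replicate_heterogeneity_ground` | 0.02 | ground powder is nearly homogeneous |
| `replicate_heterogeneity_whole` | 0.15 | a whole-tissue spectrum probes ~1 mm², far from the bulk mean |
| `matrix_jitter_sd` | 0.05 | species-level matrix-composition differences |

Reported references are truth plus Gaussian error at the per-part HPLC
SDs, truncated at zero (concentrations cannot be negative, and the low
range ends reach zero); reported SUM is the sum of the three reported
components, as a real data sheet would compute it. Replicate
heterogeneity is the **only** mechanism distinguishing whole from ground
samples — it suffices to reproduce the qualitative finding that ground
samples calibrate better, without inventing unsupported optics.

**Resolutions.** Spectra are generated at 4 cm⁻¹ and degraded to 8 and
16 cm⁻¹ by Gaussian convolution (FWHM = target resolution,
edge-renormalized so constants stay constant) followed by linear
resampling to the canonical grid (500 + k·r up to 4000 cm⁻¹; point
spacing equals the nominal resolution — a fixed convention that makes
variable counts unambiguous, recorded in every CSV header). Degrading
smooths the 4 cm⁻¹ noise, so coarser spectra are less noisy per point, as
on a real interferometer where resolution trades against noise.

**What the generator does *not* emulate** — and hence what passing tests
do not show about real data: ATR penetration-depth dispersion (effective
path length falling with wavenumber), water-vapor and CO₂ artifact bands,
detector nonlinearity, wavelength calibration drift, and any real
chemical rank beyond three analytes plus one matrix per (species, part).
Real spectra are messier in all these ways; results on synthetic data
bound what the pipeline can do under its own assumptions, not what a
specific instrument will achieve.

**"Noise-free" includes the matrix jitter.** `synth_config_noise_free()`
zeroes every dispersion, *including* the per-species matrix perturbation.
This matters: with a species-specific matrix component, a validation
sample of a species absent from calibration carries a spectral direction
outside the calibration span, and exact recovery would fail for some
seeds even with zero noise. With all dispersions zero, the spectra live
exactly in the span of {three standards + one part matrix}, and any
configuration reaching rank 3 recovers concentrations to machine
precision — the identifiability property the exactness tests assert.

## Numerical conventions

- NIPALS stops a factor early when $\|X^\top y\|$ falls below 1e-10 of
  its initial value (effective rank reached); requesting more factors
  truncates with a warning.
- The regression vector is $W(P^\top W)^{-1}q$; its predictions agree
  with sequential score-deflation prediction to 1e-8, which is tested.
- Leave-one-out predictions for a fold whose effective rank $a$ is below
  the candidate $k$ reuse the rank-$a$ prediction (the model cannot
  improve past its rank).
- Correlation of a zero-variance vector is reported as `NA` with a
  warning, never silently 0, except in variable ranking where 0 is the
  documented tie-broken convention.
- CSVs are written at `%.17g` precision, so write/read round-trips are
  lossless at double precision.

## Problem sizes

The shipped tests and the acceptance script run: exactness checks on a
17-sample noise-free ground-flower dataset (the default ground-flower
inventory), and a realistic-noise search of the 384-configuration
flowers/ground slice at 4 cm⁻¹ on 40 samples (34 *F. esculentum* + 2
each of three minor species, proportional to the default inventory).
These sizes give stable statistics — a validation set of 10 for the
search — while a full 6912-configuration run on the complete 108-sample
inventory is simply `run_search(bundle, standards)` and scales linearly
in configurations.

## Known limitations

- PLS1 only: SUM is modeled as its own response, not constrained to the
  component predictions; no PLS2, kernel or sparse variants.
- No MSC or detrending pretreatments, no higher derivatives, no
  multi-level wavelet decompositions, and no CARS/VIP/UVE-style selection
  schemes — the three shipped schemes are the point of comparison.
- The JCAMP-DX reader supports AFFN `(X++(Y..Y))` blocks only (no
  compressed DIF/DUP forms, no binary vendor formats) and resamples
  immediately to the canonical grid.
- Latent-factor robustness is not analyzed: the factor count is whatever
  leave-one-out selects per configuration.
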