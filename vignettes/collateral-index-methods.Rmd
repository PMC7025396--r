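---
title: "Signal variance-based collateral assessment in DSC perfusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal variance-based collateral assessment in DSC perfusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvipwi)
```

## The problem and the model

In acute stroke from a proximal large-artery occlusion (internal carotid or
M1), the leptomeningeal collaterals — pial anastomoses over the convexity —
determine how fast the penumbra collapses into infarct. `cvipwi` quantifies
this collateral supply directly from the *raw* dynamic susceptibility
contrast (DSC) perfusion time series, with no deconvolution and no arterial
input function.

The physical idea: during bolus passage the gadolinium chelate drops the
T2\*-weighted signal in proportion to local blood content and flow. Large
pial vessels show a deep, sharp drop at a low mean signal; parenchyma shows
a shallow drop at higher mean signal. The per-voxel temporal coefficient of
variation

$$\mathrm{CV}(v) \;=\; \frac{\sigma(v)}{\mu(v)},$$

with $\sigma$ and $\mu$ the standard deviation and mean of $S(v,t)$ across
the acquisition, therefore separates the vessel compartment from tissue.
The vessel map is obtained by thresholding CV at the upper half of its
robust range (2nd–98th percentile of positive in-brain CV), removing
ventricular CSF with a ventricle mask, and stripping the 5% of high-CV
voxels with the lowest signal at the bolus peak (outer CSF and cortex
adjacent to vessels show high CV at low signal — partial volume). The
remaining high-CV voxels are intersected with a binarised vessel-density
atlas (minus venous sinuses), split at the median plane, and summarised as
the collateral vessel index

$$\mathrm{CVI} \;=\;
\frac{\text{highCV}_{\text{affected}}\ (\mathrm{mm}^3)}
     {\text{highCV}_{\text{unaffected}}\ (\mathrm{mm}^3)},$$

dichotomised at 0.963 (the cohort median in the validating population) into
good/moderate versus poor collaterals.

Alongside the index, the package computes the standard threshold-defined
stroke lesion metrics: the ischaemic core as $0 < \mathrm{ADC} <
600\times10^{-6}\,\mathrm{mm^2/s}$; non-deconvolved time-to-peak (TTP) maps;
TTP-delay relative to the contralesional hemispheric median; tissue at risk
(delay $\ge 4.5$ s, equivalent to $T_{max} \ge 6$ s) and severe
hypoperfusion (delay $\ge 9.5$ s); the PWI/DWI mismatch ratios; and the
hypoperfusion intensity ratio
$\mathrm{HIR} = V_{\ge 9.5\,\mathrm{s}} / V_{\ge 4.5\,\mathrm{s}}$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| CV robust range percentiles | 2 / 98 | – | standard "robust range" convention; insensitive to single-voxel outliers |
| CV threshold | rmin + 0.5 (rmax − rmin) | – | "upper 50% of the robust range"; inclusive (≥) comparison |
| low-intensity strip fraction | 0.05 | – | removes partial-volume CSF/cortex voxels at the bolus-peak volume |
| ADC core threshold | 600e-6 | mm²/s | established upper bound for irreversibly injured tissue |
| tissue-at-risk delay | 4.5 | s | TTP-delay equivalent of Tmax ≥ 6 s |
| severe-hypoperfusion delay | 9.5 | s | TTP-delay equivalent of Tmax ≥ 10 s |
| minimum lesion component | 300 | mm³ | artifact correction; see below |
| CVI cutoff | 0.963 | – | median dichotomization into good/moderate vs poor |

All of these live in `default_config()$thresholds` and are overridable per
case; the shipped values are asserted by the test suite so they cannot
drift silently.

## Numerical choices

* **σ normalisation.** σ uses the population (1/N) form. At N ≈ 67 volumes
  the difference from 1/(N−1) is &lt; 1%, but the choice must be fixed for
  the oracle tests to be exact.
* **Division guard.** CV is set to 0 where μ ≤ ε with
  ε = 1e-6 × median(positive μ), so background never enters the robust
  range. Zero-CV voxels are likewise excluded ("non-zero voxels").
* **Percentiles.** The robust range uses linear interpolation between order
  statistics (R's type 7). The low-intensity strip instead thresholds at
  the ⌊f·n⌋+1-th order statistic and removes voxels *strictly below* it:
  with distinct intensities exactly the f·n lowest are removed, ties are
  never broken arbitrarily, and the f → 0 limit leaves the mask unchanged.
* **Ties and comparisons.** Every threshold comparison is inclusive (≥),
  and frame ties (bolus peak, TTP) break to the earliest frame: the
  pipeline is fully deterministic.
* **TTP resolution.** TTP is frame-resolved (index of the temporal minimum
  × TR), matching scanner-generated non-deconvolved TTP maps; no
  sub-sample interpolation, so constructed cases have exact oracles.
* **Median plane.** Defined on the image grid: the midpoint of the
  left-right axis after reorientation to RAS voxel order. For an odd axis
  length the exact midplane slice belongs to neither hemisphere. No
  anatomical midsagittal estimation is attempted.
* **Contralesional reference.** The TTP median is computed over
  unaffected-hemisphere brain voxels *excluding ventricles*, since CSF has
  no bolus passage and its TTP is noise.
* **Perfusion-lesion territory.** The delay compartments are restricted to
  the affected hemisphere (config-switchable); restriction to a specific
  vascular territory would need a territory atlas, which is out of scope.

## Registration

The 6-DOF rigid registration (motion correction against the temporal mean
volume; ADC-to-PWI coregistration) is implemented in the package: trilinear
resampling in compiled code, correlation-ratio similarity (normalised
mutual information available), a 2×/1× multi-resolution schedule, and a
centre-of-mass translation initialisation so multi-voxel shifts are inside
the optimiser's capture range. Nelder–Mead keeps the best vertex, so
registering an image to itself returns the identity exactly. Transforms are
serialized as 4×4 row-major world-mm text matrices. Interpolation is
trilinear for scalar data (out-of-field = NaN) and nearest-neighbour for
masks (out-of-field = 0); the interpolation order of the original clinical
pipeline is not documented, and trilinear is assumed.

## Lesion-mask correction

The automatic artifact correction applied after ADC/TTP thresholding is
specified here as: restrict to brain, remove 26-connected components below
300 mm³, fill fully enclosed cavities (6-connected background flood). The
connectivity and minimum size are package decisions — the original
correction is described only as existing and visually verified — and both
are exposed as configuration keys. After cleaning, the severe mask is
intersected with the at-risk mask and that with the perfusion lesion, so
the nesting severe ⊆ at-risk ⊆ lesion holds for any input.

## The phantom: what it emulates, what it does not

`phantom_spec()` states the emulated world: a 64×64×19 grid of
1.8×1.8×5.2 mm voxels (half-matrix version of a 128×128, 19-slice
gradient-echo EPI protocol; 5.2 mm = 4 mm slice + 1.2 mm gap), 67 volumes
at TR = 1.5 s. An ellipsoidal brain contains periventricular CSF, a pial
vessel shell, a posterior midline venous-sinus strip, and parenchyma.
Signal is baseline minus a peak-normalised gamma-variate drop (arrival
12 s, shape α = 3, scale β = 6 s, peak at 30 s = volume 20): vessels drop
50% of a 200 a.u. baseline, parenchyma 15% of 300 a.u., CSF not at all —
the simplest kinetics reproducing the qualitative vessel/tissue/CSF
signal-time behaviour. Gaussian noise defaults to σ = 3 a.u. (SNR ≈ 100,
a realistic clinical DSC regime); the affected side's kinetics can be
delayed; the affected pial shell is deterministically subsampled (or the
unaffected one, for ratios > 1) so the true vessel-volume ratio equals
`asymmetry_ratio` to within one voxel; an optional block of ADC
450×10⁻⁶ mm²/s forms a core. Truth masks are independent of the noise
seed.

The phantom deliberately omits recirculation and leakage, EPI distortion,
partial-volume mixing at compartment borders, vessel geometry (it is a
shell, not a tree), and spatially correlated noise. A green test therefore
establishes algorithmic correctness — thresholds, bookkeeping, geometry,
invariances, parameter recovery under idealised kinetics — not clinical
performance, which in the validating cohort rests on 55 undeposited
patient datasets and is out of scope here.

## Design choices made where the method description was open

* *Robust range* was taken as the 2nd–98th percentile of positive in-mask
  values, the documented convention of the toolbox family the original
  processing used.
* *The 5% strip population*: the quantile is computed over the high-CV
  voxels themselves, since the operation is described as a subtraction
  from those maps; a config switch (`strip_scope = "brain"`) computes it
  over all brain voxels instead.
* *Leptomeningeal extent* ("lateral and cranial convexity") is delegated
  to the support of the supplied vessel-density atlas; the package bundles
  a synthetic atlas for phantoms and accepts any coregistered atlas for
  real data.
* *TR source of truth*: the NIfTI `pixdim[4]` when positive, else a
  mandatory config value; a >1% disagreement warns and the config wins
  (clinical exports often zero this field).
* *Cohort statistics* (correlations, ROC, regression) are intentionally
  not implemented; the cohort CSV is their interface.

## Known limitations

Arterial and venous high-CV voxels are not distinguished (venous outflow
tracks arterial inflow, but the index is a mixture). Oblique acquisitions
are reoriented by nearest axis only. The registration is rigid; nonlinear
distortion is untouched. The grid median plane assumes reasonably
AC-PC-aligned axial coverage. All empirical claims about recovery accuracy
in this document are exactly those computed by the test suite on the
phantom suite — no more.
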