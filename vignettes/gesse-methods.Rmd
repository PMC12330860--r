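---
title: "GESSE R2 mapping: models, phantom, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GESSE R2 mapping: models, phantom, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesse)
```

## The signal model and its assumptions

GESSE forms a single refocused spin echo at `sTE` and samples it with
gradient echoes on both sides of the echo top. The package models the
magnitude signal with exactly two mono-exponential rates,

$$S(TE) = M_0 \exp\!\big(-R_2\,TE - R_2'\,|TE - sTE|\big),$$

and the FID (before the refocusing pulse) with
$S(TE) = M_0 e^{-(R_2+R_2')TE}$. This is deliberately minimal: no Bloch
simulation, slice-profile, refocusing-efficiency, magnetization-transfer,
exchange, or diffusion physics. Consequences to keep in mind:

* **R2 is "apparent"**: real tissue decay is multi-compartmental and
  TE-dependent; the two-rate model is the operational definition the
  pair-ratio estimator inverts, not a biophysical claim.
* The FID convention $R_2^* = R_2 + R_2'$ is adopted because the reference
  processing chain computes R2\* from the FID section; the package never
  needs an independent R2* definition.
* Magnitude noise is **Rician** by default (modulus of complex Gaussian);
  a clipped-Gaussian model exists for analytic checks. No Rician bias
  correction is applied anywhere — the pair estimator is used "model-free",
  matching its intended processing style; its residual noise bias decays
  with SNR (tested empirically at SNR 10/30/100).

Units: rates are s⁻¹, echo times at all interfaces are ms, and every
exponent is evaluated after converting times to seconds. This is asserted
once here and applied everywhere.

### Echo-grid conventions

The default `echo_train_spec()` places the rephasing echoes at
`sTE − (11:1)·ΔTE` (25.7–38.7 ms) and dephasing echoes at
`sTE + (1:30)·ΔTE` (41.3–79.0 ms), with `sTE = 40` ms and `ΔTE = 1.30` ms.
Literal `sTE ± n·ΔTE` grids are the only layout under which symmetric
pairs exist exactly; published per-section endpoint listings of nominally
equivalent protocols are not mutually consistent with one uniform spacing,
and the package makes no attempt to reproduce such rounding. Pair indices
`n = 6–11` are averaged by default (unweighted — averaging weights are an
open choice; a count of valid pairs is the only statement the estimator
needs, and a CNR-weighted variant was considered and rejected as
under-specified).

### Estimators

* `r2_from_pair` / `r2_map_pair_average`: exact on noiseless two-rate
  signals for any $M_0$ and $R_2'$ (the $R_2'$ factor cancels in the
  symmetric ratio). Non-positive or non-finite magnitudes invalidate a
  voxel rather than being clipped; validity propagates downstream.
* `fit_loglinear`: OLS of $\ln S$ on $\{1, -TE, -|TE - sTE|\}$. Requires
  echoes on both sides of `sTE`, otherwise the two regressors are
  collinear and the fit is refused.
* `fit_exponential`: signal-domain least squares with analytic gradient,
  box constraints ($M_0 > 0$, rates $\ge 0$), started from the log-linear
  solution, solved by `nlminb` at 1e-10 relative tolerance. On noiseless
  data all three estimators agree to 1e-6 s⁻¹ (tested).

## The digital phantom: what it emulates, what it does not

`build_phantom()` produces a deterministic labelled ellipsoid "brain":
cortical ribbon, superficial and deep white matter, CSF cavity, four
bilateral nuclei with elevated R2 (emulating iron-rich deep gray matter),
a midsagittal corpus-callosum arch pre-divided into four sections with a
small anterior-to-posterior R2 gradient (high in the genu, low in the
isthmus, mirroring the inverse association with effective fiber
diameter), and rectangular tract bundles carved into deep white matter
with exactly the requested voxel counts. Gray/white R2 defaults sit in
the 22–28 s⁻¹ band typical of 7 T.

The voxel-table generator (`generate_voxel_table()`) is the stated world
for the regression analysis: 20 bilateral tracts × 2500 voxels, diameter
indices spanning 3–6.5 μm (interleaved between hemispheres so diameter
and orientation are not confounded), Watson-distributed per-voxel
orientations (κ = 8) around supine-pose modes — most tracts near parallel
or perpendicular to B0, a few oblique — Gaussian rate noise σ = 1.5 s⁻¹,
and in-tract FA above 0.4 and tract probability above 0.25 so the default
table passes the standard selection unchanged.

What a green test on this world does **not** establish: realistic
anatomy, registration error, partial-volume mixing, within-tract diameter
or orientation dispersion, multi-subject pooling, or any claim about real
tissue — it establishes that the estimators invert their own generating
models without bias and at the advertised precision. With equal voxel
counts per tract the realized voxel-weighted mean diameter is 4.75 μm; a
real dataset realizes whatever its voxel counts dictate, and `d̄` is
always recomputed from the analyzed table, never fixed.

The Watson law was chosen for orientations because fiber principal
eigenvectors are axial (sign-free) quantities; κ = 0 reduces to the
uniform axial law (verified against the closed-form sin⁴α distribution)
and κ = ∞ to a delta at the mode.

## The orientation/diameter regression

Pipeline: strict selection (`FA > 0.4`, `prob > 0.25` — "larger than"
taken literally, so boundary values are excluded), α = arccos|PEV·B0|,
per-tract binning of sin⁴α into `[0, 0.1), …, [0.9, 1.0]` (last bin
closed), then unweighted OLS of bin mean R2 on

$$R_2 = a_0 + a_1 (d-\bar d) + a_2 \sin^4\alpha + a_3 (d-\bar d)\sin^4\alpha.$$

Open choices, decided as follows:

* **Regressor = within-bin mean sin⁴α**, not the bin centre: unbiased when
  the within-bin distribution is non-uniform (it strongly is, near the
  supine-pose poles). Bin centres would shift the slope by a
  discretization bias.
* **Unweighted OLS on binned means**: the binning exists precisely to
  remove the heavy weighting of near-parallel/perpendicular fibers;
  re-weighting by counts would undo that. A `weighted` flag restores
  count weighting for sensitivity analysis.
* **HC3 robust standard errors by default**: bin means carry unequal
  sampling variance (SD/√n per bin), so classical OLS standard errors are
  anti-conservative — measured 95 % CI coverage for the orientation slope
  was ≈ 0.88 with classical SEs and ≈ 0.94 with HC3 on the generator's
  stated world (400 replicates, computed by the test suite's machinery).
  `robust_se = FALSE` restores classical SEs.
* **Model comparison** fits the four nested variants (orientation-only,
  diameter-only, both, full). R² is monotone under nesting by
  construction. When the true interaction is zero, the *exact* adjusted
  R² of the full model still exceeds the reduced model's whenever the
  interaction's F-statistic exceeds 1 — roughly a third of replicates —
  so ties/reversals of adjusted R² are meaningful only at reporting
  precision (3 decimals), which is how the acceptance test phrases it.
* Hemisphere tracts are kept separate (20 tracts, not 10 pairs).

## Corpus-callosum sectioning

"Tip to tip into four equal-length sections" is operationalized as equal
**arc length along the medial curve**: tips are the endpoints of the
geodesic diameter of the 8-connected mask graph (Euclidean edge weights),
each refined to the most interior voxel of its end region via a chamfer
distance transform so that tips land on the midline rather than corners;
every voxel gets the normalized geodesic coordinate
$t = d_A/(d_A + d_P)$ and is cut at t = 0.25/0.5/0.75. An
`equal_extent` alternative (quartering the anterior–posterior extent) is
provided since the operational definition in the field is not unique;
arc length is the default because it follows the curved body of the
structure. Degenerate (line-like) or disconnected masks are refused. The
effective diameter $d_\mathrm{eff} = \sum f_i d_i^3 / \sum f_i d_i^2$ is
computed from user-supplied histograms; the shipped histogram file is
synthetic (labelled as such) — measured electron-microscopy histograms
are not redistributed, and merging "anterior body"/"mid body" source
histograms is the caller's responsibility.

## Numerical choices and degenerate inputs

* Non-positive magnitudes: exception at scalar level, validity-mask at
  map level.
* `fit_exponential` non-convergence marks the voxel invalid with the
  solver message attached.
* sin⁴α = 1 falls in the closed top bin; singleton bins report `NA`
  standard error but are retained (n ≥ 1 contract).
* All stochastic operations require explicit seeds; identical seeds give
  bit-identical output (tested). The pipeline derives per-stage seeds from
  one master seed.
* NIfTI-1 I/O is a minimal built-in implementation (uncompressed,
  float32, identity-scaled sform) because no NIfTI package is available
  in the supported dependency set; it is not a general-purpose reader.

## Known limitations

* The signal model excludes everything a refocusing pulse does
  imperfectly; measured GESSE R2 in vivo will differ from CPMG/Hahn T2.
* The phantom's geometry is schematic (boxes and ellipsoids), adequate
  for estimator validation, unusable for registration or segmentation
  testing.
* The regression assumes one tract, one diameter, one orientation per
  voxel; real voxels mix fibers, which is precisely why the selection
  thresholds exist.
* QSM (field-to-susceptibility inversion), cortical surface sampling,
  atlas registration, and acquisition-side corrections are out of scope;
  the pipeline consumes pre-aligned attributes.
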