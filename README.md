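# gesse

Quantitative R2 (= 1/T2) mapping and white-matter microstructure analysis
for **G**radient **E**cho **S**ampling of **S**pin **E**cho (GESSE/GESFIDE)
acquisitions.

At ultra-high field (7 T), conventional multi-spin-echo T2 mapping is
limited by RF power deposition and B1 non-uniformity. GESSE sidesteps this
by forming a *single* refocused spin echo at time `sTE` and sampling it
with a train of gradient echoes on both sides of the echo top (plus the
free induction decay, FID, before the refocusing pulse). This package is
for quantitative-MRI researchers who want a tested, reproducible
implementation of the GESSE analysis chain — from the forward signal model
through R2/R2*/R2' estimation to the white-matter fiber diameter and
orientation regression — that runs end to end on a built-in digital
phantom, with no subject data required.

## The model

Transverse decay is modelled with two mono-exponential rates: the
irreversible rate R2 and the reversible rate R2' from static mesoscopic
field offsets (R2\* = R2 + R2'). Around the spin echo,

    S(TE) = M0 · exp(−R2·TE − R2′·|TE − sTE|)

while the FID decays at R2\*. For a gradient-echo **pair symmetric about
the spin echo** (TE = sTE ± n·ΔTE), the R2′ attenuation is identical on
both sides and cancels in the ratio, giving the model-free estimator

    R2(nΔTE) = ln[ S(sTE − nΔTE) / S(sTE + nΔTE) ] / (2 n ΔTE)

which is exact for any M0 and R2′. Maps for n = 6–11 are averaged by
default. Exponential (signal-domain) and log-linear fits of the same model
are provided for comparison, and R2′ = R2\* − R2 from the FID section.

In deep white matter, R2 depends on fiber microstructure. With α the angle
between a voxel's principal fiber direction and B0, and d the tract's
apparent axonal diameter index (μm), the package fits the multi-linear
model on per-tract sin⁴α bins of width 0.1:

    R2 = a0 + a1·(d − d̄) + a2·sin⁴α + a3·(d − d̄)·sin⁴α

where d̄ is the voxel-count-weighted mean diameter, plus the nested
reduced models (orientation-only, diameter-only, both, full) compared by
R² and adjusted R². Corpus-callosum analysis divides a midsagittal mask
tip-to-tip into four equal-arc-length sections (genu, anterior body,
isthmus, splenium) and relates section R2 to the effective fiber diameter
d_eff = Σfᵢdᵢ³ / Σfᵢdᵢ².

## Worked example

```r
library(gesse)

spec <- echo_train_spec()       # sTE 40 ms, dTE 1.30 ms, 6/11/30 echoes
ts   <- tissue_params(M0 = 1000, R2 = 25, R2prime = 5)
s    <- simulate_se_signal(ts, spec = spec)
noisy <- add_magnitude_noise(s, sigma = 5, model = "rician", seed = 7)
stk  <- echo_stack(matrix(noisy$values, 1), noisy$echo_TEs, noisy$section)
r2_map_pair_average(stk, spec, n_range = 6:11)$R2
#> [1] 24.63422        # one noisy voxel; truth 25 1/s

tab <- generate_voxel_table(seed = 1)   # 20 tracts x 2500 voxels, sigma 1.5
sel <- select_voxels(tab)               # FA > 0.4 and tract prob > 0.25
obs <- bin_by_sin4(sel)                 # 10 sin^4(alpha) bins per tract
fit_orientation_model(obs, compute_dbar(sel), terms = c("a1", "a2"))
#> Orientation/diameter model fit (binned OLS)
#>   a0 = 22.12 (SE 0.05596)
#>   a1 = -6.037 (SE 0.0329)
#>   a2 = 3.464 (SE 0.1142)
#>   R^2 = 0.997, adjusted R^2 = 0.997, n = 200, d_bar = 4.750 um
```

The generator's default coefficients are (22.08, −6.06, 3.49, 0) s⁻¹, so a
single run recovers the generating surface to within its standard errors:
the intercept is the R2 of a voxel of average diameter whose fiber is
parallel to B0, `a1` the diameter slope (s⁻¹ μm⁻¹), `a2` the
orientation-dependence amplitude.

Full pipeline (phantom → echoes → maps → regression → callosum) from one
config:

```r
run_all(system.file("extdata", "demo_config.yaml", package = "gesse"), "out/")
```

or from the shell: `Rscript inst/cli/gesse.R all --config demo.yaml --out out/`
(subcommands: `simulate`, `estimate`, `orient-fit`, `callosum`, `all`).

## Documentation

See the methods vignette (`vignettes/gesse-methods.Rmd`) for the model
assumptions, the synthetic-data generator's scope and limitations, and the
numerical/design choices.
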