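# nrbrt — non-reciprocal broken-ray tomography

Fluorescence tomography of weakly scattering samples (epithelial layers,
engineered tissue, small model organisms) usually reconstructs the contrast
agent on top of *separately measured* tissue optics, with ad hoc assumptions
about how absorption and scattering depend on wavelength. Non-reciprocal
broken-ray tomography (NRBRT) removes that assumption: it reconstructs, from
one angularly selective measurement set, all three of

* the total attenuation at the excitation wavelength, `mu_e = mu_a;e + mu_s;e + n*sigma`,
* the total attenuation at the fluorescence wavelength, `mu_f = mu_a;f + mu_s;f`,
* the fluorophore concentration `n` (up to a calibration constant).

Each measurement probes a **broken ray**: a straight excitation leg from a
collimated source to the fluorescence conversion vertex `R`, then a straight
emission leg to a collimated detector (acceptance half-angle `beta`, side
`delta_d`). Because the wavelength changes at the vertex, swapping source and
detector swaps which leg is attenuated by `mu_e` and which by `mu_f` — the
broken-ray transform is *non-reciprocal*, and that asymmetry is the extra
information. With three coplanar directions `u_1, u_2, u_3` (direction 1
normal to the surface) and weights solving `sum_l sigma_l u_l = 0`, the data
functions

```
phi_lk(R) = -ln[ deltaW_lk / (eta0 W f_bar / 2 pi sigma) ]
          = -ln n~(R) + ∫_leg_l mu_e + ∫_leg_k mu_f
```

combine into vector fields `Phi(+/-)` whose divergence is *local*:

```
mu(+/-)(R) = -div Phi(+/-)(R) / (sigma1 + sigma2 + sigma3),
mu_e,f = mu(+) ± mu(-)/2,
n~ = exp{ 2 I1(+) - phi12(+) + phi32(+) - phi13(+) }   (max-normalized)
```

The package provides the full validation pipeline: voxelized cuboid phantoms
with spherical inclusions (the thirteen tabulated study samples plus custom
specs), a noise-free single-scattering forward model with finite-detector
geometric factors, an analog Monte Carlo photon-transport engine with
fluorescence conversion and acceptance-cone scoring, scan assembly with
source-detector interchange, TV-regularized inversion, and RMSE/SSIM image
metrics.

## Worked example

Reconstruct a weakly scattering sample (background optical depth 0.7, one
spherical inclusion of contrast 2) from a noiseless analytic transmission
scan:

```r
library(nrbrt)

spec    <- mini_sample()                       # 4 x 12 x 3 mm, inclusion D = 1 mm
phantom <- build_phantom(spec)                 # 0.1 mm voxels
slice   <- central_slice(phantom)
scan    <- assemble_scan(slice, scan_directions("transmission"),
                         detector_spec(delta_d = 0.07, beta_deg = 0.5))
fit     <- nrbrt(scan)                         # the model fit
fit
#> Non-reciprocal broken-ray tomography fit
#>   transmission scan (analytic data), 30 x 60 vertex grid at 0.1 mm
#>   lambda = 0, median kernel = 1, weights = (1, 0.7071, 0.7071)
#>   mu(+) range: [0.03231, 1.065] per mm; mu(-) range: [0.02819, 0.9296]
#>   metrics vs model: mu_plus RMSE=0.0755, mu_minus RMSE=0.0659, mu_e RMSE=0.108,
#>   mu_f RMSE=0.0426, n_norm RMSE=0.0224

fit$metrics
#> Reconstruction quality vs model:
#>  quantity   rmse  ssim
#>   mu_plus 0.0755 0.745
#>  mu_minus 0.0659 0.745
#>      mu_e 0.1085 0.745
#>      mu_f 0.0426 0.745
#>    n_norm 0.0224 0.944
#>   settings: lambda=0, median_kernel=1, beta_deg=0.5, delta_d=0.07, engine=analytic, N=NA
```

The RMSE values are in attenuation units (per mm) over the whole region of
interest, including the edge rows and the sharp inclusion boundary where any
discrete method errs; away from those (5 or more pixels) the noiseless
recovery is exact to rounding, and the normalized concentration contrast
inside/outside the inclusion reproduces the true factor 2. `coef(fit)`
returns the maps, `residuals(fit)` the differences against the ground truth,
`plot(fit)` draws reconstruction/model panels with the standard display
clipping (0 to 1.5 times the model maximum).

Monte Carlo data instead of analytic data:

```r
scan_mc <- assemble_scan(slice, scan_directions("transmission"),
                         detector_spec(0.3, 2), engine = "mc",
                         phantom = phantom, N = 1e6, seed = 1, partial = TRUE)
fit_mc  <- nrbrt(scan_mc, lambda = 5)          # TV-regularized differentiation
```

`run_pipeline()` drives phantom → forward → projection → inversion →
evaluation from a configuration list or YAML/JSON file
(`inst/scripts/nrbrt-pipeline.R` is a command-line wrapper), and
`sample_library()` holds the thirteen tabulated study samples.

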