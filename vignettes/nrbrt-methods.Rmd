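---
title: "Non-reciprocal broken-ray tomography: model, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-reciprocal broken-ray tomography: model, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrbrt)
```

## The physical model

A weakly scattering sample (a few transport mean free paths across) carries a
fluorescent contrast agent of concentration $n(\mathbf r)$ with absorption
cross-section $\sigma$.  At the excitation wavelength the total attenuation is
$\mu_e = \mu_{a;e} + \mu_{s;e} + n\sigma$; at the emission wavelength the
agent does not reabsorb, so $\mu_f = \mu_{a;f} + \mu_{s;f}$.  A collimated
source illuminates a thin slice along one of three fixed in-plane directions;
angularly selective detectors (area $\Delta d^2$, acceptance half-angle
$\beta$) collect fluorescence leaving along the other directions.  Each
measurement probes a *broken ray*: a straight excitation leg from the source
to the conversion vertex $\mathbf R$, then a straight emission leg from
$\mathbf R$ to the detector.  Because the wavelength changes at the vertex,
interchanging source and detector swaps which leg carries $\mu_e$ and which
carries $\mu_f$ — the measurement set is non-reciprocal, and that asymmetry
carries enough information to reconstruct $\mu_e$, $\mu_f$ and $n$ jointly,
with no assumption about the spectral dependence of the tissue parameters.

In the single-scattering (vertex-ray) approximation the finite-detector
signal is
$$\delta W_{lk} \;=\; \frac{\eta_0 W}{2\pi\sigma}\,\bar f_{lk}\,
  \tilde n(\mathbf R)\,
  \exp\!\Big(-\int_0^{L_1}\!\mu_e \,\mathrm d\xi-\int_0^{L_2}\!\mu_f\,
  \mathrm d\xi\Big),
  \qquad \tilde n = \sigma^{3/2} n,$$
where $\bar f_{lk}$ is the finite-detector geometric factor: the integral of
$\Delta\theta_{lk}(\mathbf r)/(|\mathbf r-\mathbf r_s|\sin\theta_l)$ over the
projection of the detector on the sample surface, with
$\Delta\theta_{lk}(\mathbf r)$ the width of the angular window in which the
back-projected ray from a scoring point both meets the source ray and stays
inside the acceptance cone.  The package computes this window in closed form
by intersecting the admissible arc with the cone arc
(`theta_window()`), and certifies it against a brute-force angular scan in
the test suite and the acceptance script.

The data function
$$\varphi_{lk}(\mathbf R) = -\ln\frac{\delta W_{lk}}
  {\eta_0 W \bar f_{lk} / 2\pi\sigma}
  = -\ln\tilde n(\mathbf R) + \int_{\text{leg }l}\mu_e
  + \int_{\text{leg }k}\mu_f$$
is tabulated on the vertex grid for all six ordered direction pairs
(`assemble_scan()`).  All constant bundles ($W$, $\eta_0$, $\sigma$, the
geometric factor) shift $\varphi$ by constants and cancel in the
reconstruction, which is why they all default to 1.

## The inversion

Write $\mu^{(+)} = (\mu_e+\mu_f)/2$ and $\mu^{(-)} = \mu_e-\mu_f$, and let
$I_l^{(\pm)}(\mathbf R)$ be the integral of $\mu^{(\pm)}$ from the vertex to
the surface along the fixed unit vector $\hat u_l$ (pointing from the vertex
toward the source/detector).  Under source-detector interchange,
$$\varphi^{(+)}_{lk} = \tfrac12(\varphi_{lk}+\varphi_{kl})
  = -\ln\tilde n + I^{(+)}_l + I^{(+)}_k,\qquad
  \varphi^{(-)}_{lk} = \varphi_{lk}-\varphi_{kl} = I^{(-)}_l - I^{(-)}_k.$$
With weights $\sigma_{1,2,3}$ solving $\sum_l \sigma_l \hat u_l = 0$
(normalized $\sigma_1 = 1$; `direction_weights()`), the package assembles
$$\Phi^{(+)} = -\sigma_3\hat u_3\,\varphi^{(+)}_{12}
              -\sigma_2\hat u_2\,\varphi^{(+)}_{13}
              -\sigma_1\hat u_1\,\varphi^{(+)}_{23},\qquad
 \Phi^{(-)} = -\sigma_2\hat u_2\,\varphi^{(-)}_{12}
              -\sigma_3\hat u_3\,\varphi^{(-)}_{13}.$$
The three $\Phi^{(+)}$ coefficients sum to zero, so the $-\ln\tilde n$ terms
cancel pixelwise; each integral family $I_l$ ends up multiplied by
$\sigma_l \hat u_l$, and since the directional derivative of $I_l$ along its
own ray is $-\mu$ at the vertex,
$$\nabla\!\cdot\Phi^{(\pm)} = -(\sigma_1+\sigma_2+\sigma_3)\,\mu^{(\pm)}.$$
This construction was derived here from those two requirements (locality and
concentration cancellation); the overall sign convention is fixed by
noiseless homogeneous recovery, which the test suite checks to machine
precision.  The formula is *local*: only data functions at (and next to) a
pixel enter its reconstruction, so editing the sample outside the probed
legs leaves a sub-region's reconstruction bit-identical (also under test).

The concentration uses only quantities that never leave the scanned region:
$$\tilde n = \exp\{2 I^{(+)}_1 - \varphi^{(+)}_{12} + \varphi^{(+)}_{32}
 - \varphi^{(+)}_{13}\},$$
with $I^{(+)}_1$ integrated along the surface normal through the
reconstructed $\mu^{(+)}$.  This form follows by eliminating $I^{(+)}_2$ and
$I^{(+)}_3$ from the pairwise relation
$\tilde n = \exp\{I^{(+)}_l + I^{(+)}_k - \varphi^{(+)}_{lk}\}$; the two
agree to $10^{-6}$ on noiseless data in the tests.  Since the absolute scale
of $\tilde n$ depends on uncalibrated constants, the map is always
max-normalized to $[0,1]$.  When the agent is confined to an inclusion, the
background data functions are undefined ($\delta W = 0$) and the
concentration cannot be reconstructed anywhere — the fit then degrades
gracefully (attenuation maps only, with a warning).  A conventional
fluorescence-tomography mode (`reconstruct_n(mode = "eq12")`) reconstructs
$n$ alone from a single source-detector configuration when the attenuation
maps are known.

## Differentiation of noisy data

Monte Carlo data functions are noisy and non-smooth (sharp inclusions).
Plain finite differences amplify that noise, so the divergence is computed
with total-variation regularized differentiation: per line, minimize
$$\tfrac12\|A u - (f - f_1)\|^2 + \lambda \operatorname{TV}(u),$$
where $A$ is the running-sum antiderivative in the forward or backward base
scheme; the two base-scheme solutions are averaged (a second-order
combination).  The solver is a lagged-diffusivity fixed point (default 100
iterations, relative tolerance $10^{-6}$, smoothing $\varepsilon=10^{-8}$);
non-convergence raises a warning and returns the last iterate.  A $3\times3$
median filter is applied to the $\Phi$ fields first (it also fills vertices
masked for zero Monte Carlo counts), and 10 edge pixels are duplicated on
all sides before differentiation, then cropped, which moves the boundary
artefacts of the derivative outside the region of interest.

Two parameters matter in practice, both exposed in `inversion_config()`:

* `lambda` — the TV weight.  It is dimensionless in the discrete objective;
  useful values for Monte Carlo data range from ~5 (high photon budgets) to
  ~250 (noisy runs), and each catalog sample carries a preset.  For
  noise-free analytic data the package defaults to `lambda = 0`, i.e. plain
  second-order centred differences, and `median_kernel = 1`: the filter and
  the regularization exist to fight noise, and the unregularized limit is
  exact for piecewise-linear data.  With centred differences the discrete
  divergence of the exact construction above cancels the transverse
  (streak) derivatives identically, which is why noiseless interior
  recovery is exact to rounding.
* `median_kernel` — the prefilter window (3 for Monte Carlo data).

## The synthetic samples

`sample_library()` encodes the thirteen study samples by their dimensionless
characterization: background optical depths $L_z\bar\mu_{s;e}$ from 0.7 to
4, $\bar\mu_{a}/\bar\mu_{s}$ between 0.1 and 0.43, background agent levels
$\sigma\bar n/\bar\mu_{a;e}$ from 0 to 10, and spherical inclusions with
attenuation contrasts 2.2–3.8 (samples 11–13 confine the agent to the
inclusion).  The absolute cuboid dimensions are package choices — the
physics depends only on the products — and the lateral extent of the
backscattering samples is set generously so that a centred region of
interest is fully scannable at the $-70^\circ$ direction; every field can be
overridden by rebuilding the specification.  Voxels are 0.1 mm, membership
is by voxel-centre-in-sphere (a sharp, step-like boundary), and the
intrinsic absorption of an inclusion is derived from its tabulated total
attenuation contrast (construction fails loudly if a contrast would imply
negative absorption).  `mini_sample()` is a reduced (3 mm deep) variant of
the weakly scattering sample used for fast Monte Carlo validation.

What the generator emulates: homogeneous background, sharp spherical
inhomogeneities, two discrete wavelengths, isotropic scattering, unit
quantum yield, index-matched boundaries.  What it does not: anisotropic
phase functions, refraction, spectral bands, autofluorescence, detector
dark counts.  Passing tests therefore validate the reconstruction
mathematics and the transport physics under the stated idealizations, not
performance on experimental data.

## The Monte Carlo engine

`mc_propagate()` is an analog (unweighted) tracker: exponential free paths
sampled exactly against the piecewise-constant voxel grids; at an
interaction the channel is chosen proportionally to
$(\mu_a, \mu_s, n\sigma)$ at the excitation wavelength (absorb / isotropic
scatter / convert-and-re-emit isotropically) and $(\mu_{a;f}, \mu_{s;f})$
at the emission wavelength.  Photon conservation (`absorbed + exited = N`)
holds exactly.  Scoring (`mc_score()`) counts fluorescence hits in the
projection of the detector on the surface whose 3D exit direction lies
within $\beta$ of the collimation axis, weighted by the direction cosine.
Reproducibility comes from one seeded stream per source station.

One geometric subtlety: the analytic model confines broken rays to the
slice plane and collapses the out-of-plane extent of the scoring region to
a multiplicative length.  In 3D, a scoring point at out-of-plane offset $x$
accepts photons only while the out-of-plane arrival angle $x/\rho$ (with
$\rho$ the vertex-detector distance) stays within the cone, so the
effective x-extent saturates at $2\beta\rho$.  `geom_factor_bar(x_mode =
"cone")` models this with a closed-form circular-segment integral; the
Monte Carlo engine and the model-vs-simulation comparisons use it, while
the default stays the collapsed form (the two coincide in the far regime
$2\beta\rho \gg \Delta d$).  Near the scoring face ($\rho \lesssim$ a few
hundred micrometres) and on the voxel layers straddling an inclusion
boundary the vertex-ray model is expected to degrade — the approximation
is pointwise in $\tilde n$ — so validation profiles sample away from those
layers.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale, a
deliberate package choice so that a full validation cycle stays within
minutes: noiseless recovery on a $51\times101$ vertex grid; the
brute-force window certification at $10^3$ configurations $\times\,10^6$
scan angles; Monte Carlo consistency at $10^7$ photons per source over a
9-point profile with an enlarged detector ($\beta = 2^\circ$,
$\Delta d = 0.3$ mm) to collect adequate counts; noise scaling over
$N \in \{10^5, 10^6, 10^7\}$ with 10 independent replicates.  Full-budget
runs ($10^9$–$10^{11}$ photons per source across hundreds of stations) use
the same code paths — only `N`, the station set and the runtime grow.

Other numerical choices: vertex/voxel grids are co-located (pitch 0.1 mm);
analytic scans compute station positions exactly, Monte Carlo scans snap
them to the 0.1 mm station grid (exact for $0/\pm45^\circ$, sub-pixel
residual at $-70^\circ$); ray integrals use an exact voxel-walk with
midpoint voxel attribution (robust on gridlines); degenerate geometry
(parallel rays, observation points on the source ray) raises errors rather
than returning junk; nonpositive signals become masked vertices, never
$-\infty$, and masked vertices are median-filled before differentiation but
excluded from metrics.

## Evaluation conventions

`rmse()` works in raw attenuation units by default (normalize inputs first
for unit-free comparisons).  `ssim()` uses a $7\times7$ Gaussian window
($\sigma = 1.5$) with the standard stabilization constants and the model
maximum as the dynamic range; window and constants are recorded in every
`metrics_report()`.  Display clipping to $[0, 1.5\times\max(\text{model})]$
is cosmetic only — metrics are always computed before clipping.

## Known limitations

* The single-scattering model degrades beyond background optical depths of
  about 4, with nonzero acceptance angles admitting multiply scattered
  light; reconstructions there show streaks and bias, as the catalog's
  strongly scattering samples illustrate.
* Backscattering scans are intrinsically noisier (longer photon paths,
  weaker signals); at matched budgets their reconstructions are worse, and
  the $45^\circ/-70^\circ$ direction choice only partially mitigates this.
* The concentration formula requires agent along the probed legs; confined
  agents leave $n$ unreconstructable (only $\mu$ inside the support).
* Sharp inclusion boundaries make the data functions non-smooth; the TV
  derivative contains the damage but pixel-level accuracy at the boundary
  itself is not attainable at 0.1 mm pitch.
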