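---
title: "Evaluating emission-tomography reconstructions with standardized images"
author: "tomoBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating emission-tomography reconstructions with standardized images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoBench)
```

## The problem

Iterative SPECT reconstruction methods have become good enough that classical
global quality scores (SSIM, NMSE, CC, PSNR) saturate: two reconstructions
that differ in diagnostically relevant detail can score almost identically.
tomoBench implements an evaluation framework built around two ideas:

1. **Standardized reference images.** Comparing a reconstruction directly to
   the emissivity ground truth ("Source Image") conflates algorithmic error
   with physics no algorithm can undo (attenuation, scatter). The framework
   therefore generates a family of references — *Source*, *Detector*,
   *Ideal*, *Realistic* — that isolate source distribution, propagation
   physics, and acquisition statistics. The **Ideal Image**, reconstructed
   from a noise-free, ideal-collimator, attenuated projection, is the
   recommended benchmark: residuals against it are attributable to the
   reconstruction method, not to physics.
2. **Residual-sensitive diagnostics.** Beyond the global scores, the package
   provides difference and $\chi^2$ maps, the **Structure and Contrast
   Index** (SCI) of residual maps, intensity (gray-value) histogram
   comparison, RoI-localized metrics, and jackknife uncertainties — tools
   that keep discriminating after the global scores plateau.

## The phantom

The built-in phantom is a modified Shepp–Logan head phantom: nine constant
activity ellipses on a 256 mm field of view, rasterized by default at
256×256 (1 mm pixels). The outer ellipse SRC0 (semi-axes 75×100 mm) is both
the uniform water body — the only attenuating structure; the cranial bone
shell of the classical phantom is removed — and a background emitter. Inside
it sit two large side ellipses, a central ellipse, two mid-size circular
sources, and a cluster of three small hotspots near (0, −64) mm that probes
spatial resolution. Two background variants are provided: variant 1 with
background specific activity 5 (against 5 for the side ellipses and 10 for
the central structures), and variant 2 with a four-fold background (specific
activity 20, activity ratio background : side ellipses : central/hotspots of
20:5:10) — a deliberately low-contrast, harder scenario used by the
benchmarking study.

Rasterization uses *override* semantics: each pixel center takes the
specific activity of the **last** listed ellipse containing it. This is the
only reading consistent with the 20:5:10 ratio of variant 2 — the side
ellipses must *replace* the background value of 20 with 5, not add to it.

```{r phantom}
spec <- sheppLoganPhantom(variant = 1, gridN = 128)
img <- rasterize(spec)
img
```

## The forward model

The acquisition is an ideal-collimator parallel-beam geometry: equally
spaced angles over 360° (128 projections give a step of exactly 2.8125°),
one detector bin per image column. The projector computes the attenuated
Radon transform: emission at a point contributes
$\exp(-\int \mu \, dl)$ along the ray from that point to the detector. It is
a deliberate analytic stand-in for a Monte Carlo photon-transport
simulation; what it models and what it does not:

* modeled: attenuation (exactly, along rays), Poisson counting statistics,
  optional 1-D Gaussian detector blur along the bin axis ("Realistic" mode);
* not modeled: Compton scatter, collimator septal penetration, energy
  windows, dead time, detector electronics, 3-D effects.

Consequently, passing tests demonstrate correctness of the geometry,
attenuation weighting, statistics and diagnostics — not fidelity to scatter
physics. Residuals between Source and Ideal images here reflect attenuation
only, and agreement measures on real scanner data will be less favorable
than on data generated by this simulator.

**Discretization.** Rays are sampled at half-pixel steps with bilinear
interpolation of both emissivity and attenuation; the attenuation line
integral is accumulated from the detector side with mid-sample centering.
The projected mass per angle matches the image mass to a few parts in a
thousand at default settings. The system matrix used by the reconstructors
is the *same* discretization (the forward map reproduces the simulator
bit-for-bit up to float tolerance), and the back-projection is its exact
transpose — adjointness holds to machine precision, which the test suite
verifies against a densely materialized operator on small grids. Note that
using the same operator for simulation and reconstruction is an "inverse
crime" in the numerical-analysis sense: converged reconstructions can fit
the data to reduced $\chi^2$ below 1. This is intentional here — the
framework evaluates *reconstruction behavior*, and the diagnostics (SCI,
histograms, RoIs) are what carry the discrimination burden.

**Counting noise.** A noise-free sinogram is rescaled to an expected total
count and each bin replaced by an independent Poisson draw; per-bin variance
is recorded as the expected count floored at one count (the floor avoids
division by zero in $\chi^2$ for empty bins). The default level, 5×10⁶
detected counts, is typical of a planar SPECT study and was fixed once as
the package's study condition; μ defaults to 0.0146 mm⁻¹ (water at roughly
159 keV). Neither value is tuned per experiment.

## Reconstruction

Two reconstructors share a standardized stopping rule — stationarity of the
reduced $\chi^2$ between the measured sinogram and the re-projected
iterate (relative change below $10^{-3}$ over a trailing window of 3
iterations, both configurable; the criterion is standard but its constants
are a package choice).

**ART** (Kaczmarz row actions): for ray $i$,
$f_j \leftarrow f_j + \lambda \, \frac{S_i - R_i}{\sum_j P_{ij}^2} P_{ij}$,
with $R_i$ the current forward projection of that ray. The $\sum_j P_{ij}^2$
normalization makes the unrelaxed update project exactly onto the ray's
measurement hyperplane (the single-ray residual is annihilated, which the
tests verify). Rays are visited in an angle-interleaved (stride-permuted)
order to reduce streak buildup, the relaxation default is 0.5, and negative
pixels are clipped at the end of each full sweep rather than per ray, so
the within-sweep algebra stays exact.

**MLEM**: the multiplicative update
$f_j \leftarrow \frac{f_j}{\sum_i P_{ij}} \sum_i P_{ij} \frac{g_i}{(Pf)_i}$,
which preserves non-negativity and monotonically increases the Poisson
likelihood. The initial image is a uniform positive constant scaled so the
total forward counts match the total measured counts (scale-matched
initialization shortens the path to stationarity); zero-sensitivity pixels
are frozen at zero; forward-projection denominators are floored at
$10^{-12}$ of their maximum.

Whether the system matrix includes attenuation weighting is controlled by
the `mu` argument of `buildSystemMatrix()`; both reconstructors accept
either form, and all bundled studies use the attenuation-aware operator.

**The Ideal Image recipe.** The reference reconstruction of the noise-free
ideal sinogram is MLEM under the same stationarity rule (capped at
`maxIterations`). Any fixed, documented operator serves the benchmark role;
MLEM with the attenuation-aware matrix was chosen because it is the
package's own converged estimator of the attenuation-limited image. On
noise-free data the $\chi^2$ trace decays toward zero with slowly shrinking
relative steps, so the cap (default 200 iterations) usually binds before
formal stationarity; the resulting reference fits its sinogram to reduced
$\chi^2$ of order $10^{-3}$, far below any difference that matters to the
benchmarked methods.

## The diagnostic suite

All comparisons first **mean-normalize** both arrays (divide by the mean, so
both carry equal total luminosity).

**Difference and $\chi^2$ maps** (`residualMaps()`): signed residual,
absolute residual, and $(X_i - Y_i)^2/\sigma_i^2$ per pixel with the
counting variance; the reduced $\chi^2$ is the mean over valid pixels.

**SCI** (`sci()`): the SSIM decomposition evaluated *on the residual map*
$R = X_\mathrm{norm} - Y_\mathrm{norm}$, against the normalized reference:
luminance $2\mu_R\mu_Y/(\mu_R^2+\mu_Y^2+c_1)$ (identically 0 after mean
normalization, and therefore discarded), contrast
$2\sigma_R\sigma_Y/(\sigma_R^2+\sigma_Y^2+c_2)$, structure
$(|\mathrm{cov}(R,Y)|+c_3)/(\sigma_R\sigma_Y+c_3)$ — the covariance enters
by magnitude, because the index measures the *presence* of organized
residual structure and an anticorrelated organized residual (underestimated
hotspots against an overestimated background) is just as organized as a
correlated one — with
$c_1=(0.01L)^2$, $c_2=(0.03L)^2$, $c_3=c_2/2$ and $L$ the range of the
normalized reference. **SCI = contrast × structure.** A perfect
reconstruction gives 0; coherent residual structure (edges, halos) gives
elevated values. Two readings of "the components of the residual map" are
defensible — global moments or window-averaged local components; the global
form is the default because it makes the luminance exactly zero and drives
both components to zero at convergence, while the windowed alternative is
available via `sci(..., windowed = TRUE)`. Interpretation caveat: in
fluctuation-dominated regimes (e.g. very noisy ART output) strong pixel
noise masks coherent structure, and a *low* SCI then reflects masking, not
quality — the SCI must be read alongside the other metrics.

```{r sci}
set.seed(1)
Y <- matrix(runif(64 * 64, 1, 3), 64)
X <- Y + 0.05 * matrix(rnorm(64 * 64), 64)
sci(X, Y)
```

**Global metrics** (`globalMetrics()`): NMSE $\sum(X-Y)^2/\sum Y^2$; PSNR
$10\log_{10}(\max(Y)^2/\mathrm{MSE})$ (reference maximum, by convention);
Pearson CC; mean SSIM with the standard 11-pixel Gaussian window
($\sigma=1.5$, $K_1=0.01$, $K_2=0.03$, dynamic range from the reference);
CNR $(\mu_\mathrm{signal}-\mu_\mathrm{bg})/\sigma_\mathrm{bg}$ over the
hotspot and background RoIs; reduced $\chi^2$ when a variance is supplied.

**Intensity histograms** (`intensityHistogram()`, `histogramChi2Red()`):
equal-width bins spanning the joint range of the mean-normalized pair
(`sharedEdges()`), default NB = 256; the comparison statistic is
$\frac{1}{N_B}\sum_i (S_{X,i}-S_{Y,i})^2$ on **raw pixel counts** (the
statistic is printed unweighted and unitless; the scale choice is recorded
here so values are comparable across studies). Blurring broadens and
attenuates the high-intensity peaks, so this statistic is particularly
sensitive to resolution loss and intensity migration.

**RoI analysis** (`localizedMetrics()`, `defaultRois()`): three disjoint
rectangular masks — an edge region straddling the upper boundary of the
central ellipse (resolution/partial volume), a hotspot region around the
small-source cluster (intensity recovery), a uniform background patch
(noise stability). Their exact geometry is a package default (fully
configurable); pointwise metrics use exactly the masked pixels, while
windowed SSIM uses the mask's bounding box because windows need spatial
context — for the default rectangular masks the box *is* the mask, and for
non-rectangular masks the surrounding true pixel values inside the box
provide the context.

**Jackknife uncertainties** (`jackknife()`, `jackknifeMetric()`): delete-one
resampling, with the unit chosen by domain — one projection angle for
sinogram metrics, one block of 16 image rows for image metrics (pixels are
spatially correlated, so row blocks rather than single pixels; the unit
choice is the package's).

## The bundled studies

`runCaseA()` is the convergence study: variant-1 phantom, 128 projections,
Poisson noise, MLEM checkpointed at 3/9/24/48 iterations and run to
stationarity, every checkpoint evaluated against the Ideal references in
both domains. Its characteristic signatures, asserted by the acceptance
tests at the full 256² / 128-projection configuration: the reduced $\chi^2$
against the measured counts falls into the noise-limited regime ($\le 2$)
at stationarity and is strictly larger at 3 and 9 iterations; the
image-domain SCI decreases strictly across checkpoints while SSIM's
relative change between 24 and 48 iterations is already smaller than the
SCI's — the saturation phenomenon that motivates the index.

`runCaseB()` is the benchmarking study: variant-2 (high-background) phantom,
ART and MLEM plus any externally supplied reconstructions evaluated globally
and per-RoI. External images enter as opaque arrays, so proprietary methods
can be benchmarked from their output alone.

```{r caseA, eval = FALSE}
resA <- runCaseA(seed = 1)          # full-scale study, several minutes
resA$imageMetrics$`48`$sci          # SCI of the converged checkpoint
```

## Problem sizes and numerical choices

The unit tests exercise the pipeline at 32–128 pixel grids with 8–32
projections and 10⁵–10⁶ counts — sizes chosen so the whole suite runs in a
few minutes while every property (adjointness, mass conservation,
closed-form attenuation, likelihood monotonicity) is already sharp; the
acceptance tests additionally run the full 256²/128-projection study. Key
guards: ray sampling step = half pixel; variance floor 1 count; MLEM
denominator floor $10^{-12}\,\max$; SSIM/SCI stabilizers as above; ART
clipping at sweep end. Degenerate inputs (zero-sum sinograms, constant
references, empty masks, all-zero rays) raise errors or warnings naming the
offending quantity rather than propagating NaNs.

## Known limitations

* No scatter/septal physics — see the forward-model section; "Ideal" here
  means attenuation-limited.
* Shared simulator/reconstructor discretization (inverse crime) makes
  absolute $\chi^2$ levels optimistic; orderings and the diagnostics'
  relative behavior are the robust outputs.
* 2-D only; slice thickness has no analogue here.
* The SCI's absolute scale depends on the stabilizer constants and on the
  global-vs-windowed component choice; comparisons should fix both (the
  defaults are stable across the package).
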