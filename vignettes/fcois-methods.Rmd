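---
title: "Methods: from reflectance movies to functional parcellations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from reflectance movies to functional parcellations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcois)
```

`fcois` implements resting-state functional-connectivity analysis for
widefield optical intrinsic-signal (OIS) imaging of the mouse cortex. A
camera records reflected light through the intact skull while LEDs flash
sequentially at four wavelengths (478, 588, 610, 625 nm) at 120 Hz, giving
a 30 Hz multispectral movie on a 128 x 128 grid of roughly 80 um pixels.
Reflectance changes report hemoglobin concentration changes, and the slow
(below 0.1 Hz) covariation of hemoglobin between distant cortical sites is
the functional-connectivity signal familiar from fMRI. This vignette
explains each model and procedure, the defaults and their units, the
numerical choices, and what the synthetic phantom does and does not
establish about real data.

## Spectroscopy: Modified Beer-Lambert unmixing

Reflected intensity at wavelength $\lambda$ is modeled as
$\Phi_\lambda(t) = \Phi_{0\lambda}\exp(-\Delta\mu_{a,\lambda}(t)\,L_\lambda)$.
Resting-state data have no stimulus baseline, so the temporal mean
intensity is the reference:
$\Delta\mu_{a,\lambda}(t) = -\ln(\Phi_\lambda(t)/\langle\Phi_\lambda\rangle_t)/L_\lambda$.
This makes every concentration estimate a *differential* measure, defined
up to a per-pixel constant; round-trip accuracy is therefore assessed
after removing temporal means, where the inversion is exact to machine
precision (`intensity_to_dabs()`, `dabs_to_hemoglobin()`).

The species unmixing solves $E\,\Delta[\mathrm{Hb}] = \Delta\mu_a$ per
pixel and frame by least squares, where $E$ holds the extinction
coefficients of HbO2 and HbR at each wavelength. Coefficients are stored
in the natural-log convention with units mm^-1 uM^-1 (tabulated base-10
molar values in cm^-1 M^-1 are multiplied by $\ln 10 \times 10^{-7}$), so
absorption stays in mm^-1 with concentrations in uM. The bundled
`optical_model_demo.json` carries representative demonstration values;
every test uses arbitrary well-conditioned matrices so correctness never
depends on that file.

Pathlengths $L_\lambda$ (mm) come either from a user table (the default)
or from an analytic diffusion model: the mean photon pathlength is the
sensitivity of the modeled reflectance to absorption,
$L = -\partial \ln R/\partial \mu_a
   = \tfrac{3}{2}(2\mu_a + \mu_s')\rho^2 / (1 + \mu_{\mathrm{eff}}\rho)$
with $\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a+\mu_s')}$ and an effective
source-detector separation $\rho$ (default 1 mm) standing in for the
ring-illumination geometry. Table mode is the default because published
pathlengths depend on baseline optical properties that the user, not the
package, should assert.

Each contrast is smoothed with a normalized truncated Gaussian (5 x 5
support, sigma 1.3 px) after spectroscopy. Borders use reflect padding,
chosen so a constant image is exactly invariant.

## Preprocessing: band-pass, 1 Hz resampling, global regression

Functional connectivity lives in the infra-slow band; traces are filtered
to 0.009-0.08 Hz, decimated to 1 Hz, and the brain-average "global
signal" is regressed from every pixel, in that order
(`preprocess_traces()`).

The band-pass is the squared-magnitude response of an order-4 Butterworth
band-pass — exactly the zero-phase response of a forward-backward pass —
applied spectrally to the demeaned trace. We applied the response in the
frequency domain after finding that recursive implementations cannot meet
a 60 dB stopband contract on recordings of this length: the 0.009 Hz
corner has a ~47 s time constant, and the start-up transients of a
forward-backward recursive pass leave residuals near -23 dB however the
initial conditions are chosen. The spectral application is exact for
stationary signals; its cost is that the trace is treated as one period,
so slow drift across the recording leaks a small broadband term (mitigate
with `stats::lm` detrending upstream if drift is visible). Filter order
and band edges are arguments throughout.

Decimation after filtering is plain sample-taking (every 30th sample):
with no energy above 0.08 Hz, the 0.5 Hz Nyquist limit of the target rate
is respected by construction. Output length is the whole number of
seconds.

Global signal regression computes $g(t)$ as the unweighted mean over
brain pixels and removes $\beta_p g$ from each pixel with
$\beta_p = \langle y_p, g\rangle/\langle g,g\rangle$. Because the pixel
average of $\beta_p$ is identically 1, the brain-average residual is zero
to machine precision — an algebraic identity the tests assert at
`1e-10` of the input RMS. GSR inevitably induces some anticorrelation;
anticorrelated network pairs should be interpreted with that in mind.

## Connectivity: seed maps, correlation matrices, SVD

A seed is a 0.5 mm diameter disc (29 pixels at 80 um pitch — every pixel
whose center lies within the radius, ties included); its trace is the
unweighted member mean. Seed maps are Pearson correlations between that
trace and every brain pixel; values are clamped to [-1, 1] against
rounding, and constant pixels yield flagged `NaN`s rather than silent
zeros. The full pixel-by-pixel matrix is guarded by a configurable pixel
cap (default 6000) with a stride option, since an N x N double matrix
grows quadratically.

The singular value decomposition of the (symmetric) correlation matrix
orders orthonormal spatial patterns by the share of total variance they
carry; we define the variance fraction $f(K)$ as the sum of the first $K$
singular values over the sum of all. For trace input, `svd_patterns()`
computes the same decomposition through the T x T time-domain Gram matrix
of the standardized traces — the pixel matrix has rank at most T, so its
nonzero spectrum and leading spatial patterns are recovered without ever
materializing N x N.

## Iterative parcellation

Starting from an initial label map, two steps alternate: each parcel's
trace is the mean over its member pixels, then every pixel joins the
parcel it correlates with most strongly. Parcels that fall below
`min_size = 10` pixels are eliminated after each assignment (their pixels
are recaptured on the next pass); without this rule a single-pixel parcel
is an absorbing state, since a pixel correlates perfectly with itself.
The loop stops at a fixed point, on a repeated label configuration
(argmax iterations can oscillate between two states, so cycle detection
is cheap insurance the mathematics does not provide), or at `max_iter`.
Ties in the argmax go to the lowest parcel id, making reruns
deterministic. The minimum size is specified in pixels; at 80 um pitch
10 pixels is 0.064 mm^2.

Three initializations are provided: (i) the first ten singular vectors,
each pixel assigned to the vector with the largest absolute coefficient
and that group split by coefficient sign — twenty label slots; (ii) the
sixteen-seed catalogue, discs labeled and everything else captured by the
first pass; (iii) 25 x 25 pixel tiles intersected with the mask. The
first and third need no anatomical input.

Converged parcels are correlated into a parcel matrix and clustered
agglomeratively with distance $1-r$, so heights live in [0, 2]. Single
linkage is the default (the conventional default of the numerical
environments this method grew up in), with average and complete linkage
available; the clustering backend is `stats::hclust`, and the test suite
checks it against an exhaustive agglomeration oracle.

### An identifiability limit of the SVD initialization

On a *perfectly* bilaterally symmetric, noise-free phantom the SVD
initialization cannot recover all twelve regions, and this is structural
rather than a bug. Every spatial mode of such data is either symmetric or
antisymmetric under the left-right flip. Twelve regions plus a global
component span 13 dimensions; global regression removes one, leaving rank
11 — five symmetric and six antisymmetric modes, with every antisymmetric
(left-minus-right) eigenvalue suppressed by the factor $1-r_{homotopic}$.
The first ten modes therefore always omit one antisymmetric pattern, the
sign-split assigns that network's left and right regions to one parcel,
and the iteration can merge parcels but never split them. Measured: ARI
0.965 (11 parcels, one homotopic pair merged) versus 1.0 for the seed and
tiling initializations. Any pixel noise breaks the symmetry and the
practical ceiling disappears — which is why this shows up only in the
cleanest possible data.

### Border displacement

To compare two parcellations of the same brain we represent borders as
the midpoints between differently labeled 4-neighbor pixels. For each
border element of map A, the distance to the nearest border element of
map B is summarized (median, 95th percentile, per adjacent-label pair and
overall, in um). The midpoint ("crack") representation makes the measure
symmetric at the pixel scale: shifting a straight border by one pixel
moves every crack by exactly one pitch (80 um), whereas pixel-based
definitions average 0 and 1 pitch. This displacement statistic is this
package's own definition of border uncertainty.

## Atlas registration

A named-polygon atlas with two midline landmarks (the olfactory
bulb/cerebrum junction and lambda) is mapped onto the image by the unique
similarity transform through the two landmark pairs: rotation, uniform
scale and translation, solved in closed form via complex arithmetic. A
single stretch means the anterior-posterior scale is reused
medial-laterally, so circles stay circles; the rotation is included
because it is part of the unique two-point similarity. Pixels are
assigned by ray casting on pixel centers with on-edge points counting as
inside; overlap between transformed polygons is treated as an invalid
atlas, and gaps are legitimate (unassigned pixels). The bundled
`schematic_atlas()` is a synthetic rectangle sketch carrying the standard
region names for tests and demos — not a digitized histological atlas.

## The synthetic phantom

`phantom_config()` defaults encode the acquisition this package targets:
128 x 128 grid, 80 um pixels, 900 s at 30 Hz. Six bilateral networks
(frontal, motor, somatosensory, retrosplenial, visual, colliculus — 12
regions) partition an elliptical cortex as anterior-posterior bands split
at the midline. Each region's latent signal is white noise filtered to
0.009-0.08 Hz; the latent basis is empirically whitened and mixed by the
(eigen-based, PSD-tolerant) Cholesky factor of the target correlation
matrix, so the realized sample correlation over the full duration equals
the target *exactly* rather than approximately. Targets: homotopic pairs
0.8; frontal vs somatosensory and retrosplenial vs motor at -0.5
(anticorrelated network pairs); visual weakly coupled to colliculus at
+0.3; verified positive semidefinite at construction. Pixels add a shared
band-limited global component (weight 0.3), shared-phase sinusoids at 2.5
and 10 Hz (amplitudes 0.5 and 0.25 uM) emulating respiration- and
cardiac-band vascular signals — shared phase because such artifacts are
spatially global — and white sensor noise of sd 1 uM per 30 Hz frame,
i.e. noise comparable to the signal at frame rate, rescued by the 200-fold
bandwidth reduction of filtering. HbR is inversely coupled as
$\Delta\mathrm{HbR} = -0.3\,\Delta\mathrm{HbO_2}$; correlation analyses
are invariant to that ratio. Raw four-wavelength 120 Hz streams are
rendered through the forward Beer-Lambert model for end-to-end tests.

What the phantom does *not* emulate: spatial blur (no optical PSF),
vascular topology, region-internal gradients, non-stationarity, motion,
and photon noise statistics (Gaussian, not Poisson). Passing recovery
tests therefore demonstrates the correctness of the pipeline's
mathematics on band-limited block-structured signals, not field
performance on real mice.

### The finite-window ceiling on split-half reliability

Split-half seed-map correlation compares maps from consecutive halves of
a recording. Even at zero sensor noise this does not reach 1: a
band-limited process observed for $T$ seconds supports roughly
$2 \times \mathrm{bandwidth} \times T \approx 43$ effective degrees of
freedom per 300 s half, so each half's sample correlations fluctuate by
$\pm 0.15$ around the target, and the zero-noise split-half correlation
lands near 0.9-0.97 (five seeds measured). Sensor noise lowers it only
slightly because filtering removes most of it — monotonically, which the
tests check with common random numbers across noise levels. This ceiling
is a property of any finite resting-state recording, and the same
arithmetic applies to real 15-minute sessions.

## Problem sizes, determinism, degenerate inputs

The test suite and the acceptance script run the recovery analyses at the
full 128 x 128 / 900 s conditions and use a 64-grid, 600 s phantom for
the split-half sweep and a 32-grid, 150 s phantom for optical round
trips — sizes chosen so each check runs in seconds-to-minutes on one
core while leaving the contract unchanged. All stochastic steps flow from
a single integer seed; fixed seed means bit-identical phantoms and
pipeline outputs. Degenerate inputs fail loudly with classed conditions:
zero intensities inside the mask, rank-deficient extinction matrices,
constant seed traces, empty masks, all-parcels-pruned, coincident
landmarks, overlapping atlas polygons, non-PSD correlation targets.

Coordinates are 1-based (row, col) matrix indices throughout, with
physical positions at pixel centers — the native R convention.

## Known limitations

- Spectral filtering assumes approximate stationarity; recordings with
  strong drift should be detrended first.
- The full correlation matrix is dense double precision; beyond the
  pixel cap use the trace-based SVD or a stride.
- The iterative parcellation only merges; the number of recoverable
  regions is bounded by the initialization's resolution.
- Analytic pathlengths use a semi-infinite homogeneous diffusion model
  with a nominal geometry parameter; quantitative hemoglobin units
  require calibrated pathlengths and extinction tables.
- No multi-animal registration or group statistics; one brain at a time.
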