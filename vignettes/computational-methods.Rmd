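---
title: "Computational methods for pocket-scale microscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational methods for pocket-scale microscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pocketscope implements, in hardware-independent form, the computations that
low-cost microcontroller-based microscopes rely on: finite-conjugate optical
design arithmetic, compression- and DCT-based autofocus, exposure/focus
bracketing, inline holographic refocusing, grating-spectrometer calibration,
and long-timelapse analytics. This vignette explains each model, the
parameters that matter, the numerical choices made where the design was
open, and what the synthetic-data generators do and do not emulate.

## Optical design calculations

The `optics` functions use the Cartesian sign convention with light
travelling left to right: object distances `a` are negative, real image
distances `a'` positive. The Gaussian lens equation is then
`1/f' = 1/a' - 1/a` and the lateral magnification `M = -a'/a` is positive
for a real, inverted, magnified image. Under this convention the solved
magnification obeys the closed form `M = -f'/(f' + a)`; note the leading
minus sign, which some textbook statements of the identity (written for the
opposite sign convention) omit.

Derived quantities are small closed forms: numerical aperture
`NA = 1/(2 f#)`, diffraction-limited resolution `d = lambda/(2 NA)`,
object-side (effective) pixel `pitch/|M|`, Nyquist margin
`d/(2 * effective pixel)` (at least 1 means adequately sampled, ignoring
any colour mosaic), and the axial step of a PWM-driven focus actuator,
`travel / 2^bits`.

A deliberate design point: `opticsReport()` never cross-validates user
inputs against one another. Published descriptions of these devices quote
rounded values (`f' ~ 4 mm`, `a ~ -4 mm`, `a' ~ 18 mm`) that are mutually
inconsistent with the lens equation at face value (they would imply
`f' = 3.27 mm`), and a calculator that "corrected" one input from another
would silently pick a side. Each requested quantity is computed exactly
from the parameters that define it; with `a = -4, a' = 18` the reported
magnification is the exact `4.5`, not the commonly quoted rounded `4`.

## Sharpness metrics and autofocus

Two relative sharpness metrics are provided. `jpegSizeSharpness()` encodes
the luminance plane as a baseline JPEG at fixed settings (quality 85 by
default) and returns the byte count: JPEG's DCT-based entropy coding spends
more bits on high-spatial-frequency content, so within one encoder
configuration a larger file is a sharper frame. The metric is
*rank-meaningful only* — never compare scores across encoders or quality
settings. Encoding the luminance plane (rather than RGB) makes chroma
subsampling irrelevant, which matters because mainstream JPEG bindings do
not expose a subsampling switch.

`dctSharpness()` works on the DCT statistics directly: the image is split
into 8 x 8 blocks, each block gets an orthonormal 2-D DCT, and the score is
the fraction of per-block energy outside the top-left 2 x 2 coefficient
corner, averaged over blocks. A constant frame scores exactly 0; blur
drains the score monotonically. The exact statistic (energy fraction,
2 x 2 low corner excluded) is this package's choice; the idea of scoring
focus from DCT coefficient distributions is standard.

`bestFocus()` takes the argmax of a `sharpnessCurve()`. Ties are broken by
proximity to the median z of the sweep — a drifted focus is more likely
near the centre of a deliberately centred bracket — then by the smaller z.
Autofocus is an exhaustive sweep over a recorded stack (the focus-bracketing
workflow); closed-loop hill climbing against live hardware is out of scope.

`edofComposite()` builds an extended-depth-of-field image by pure per-pixel
selection: each output pixel comes from the layer with the highest local
luminance variance in a 9 x 9 window. No blending: every output value
exists in some input layer at the same coordinates, which keeps the
composite quantitatively interpretable.

## Exposure bracketing

`defaultBracketPlan()` encodes the autonomous-deployment schedule: every 60
seconds, sweep the near-geometric exposure ladder 1/2/5/10/20/50/100/200/500
ms, then deep-sleep. The wide ladder is what lets a device ride out battery
discharge over multi-week deployments without trusting auto-exposure. The
focus-bracket offsets default to ±2 actuator steps (±8 um, with the ~4 um
voice-coil step) around the nominal focus; published descriptions of the
bracketing workflow do not enumerate offsets, so these are configurable
defaults.

`selectBestExposure()` scores frames by the fraction of pixels in the
[0.1, 0.9] band of full scale and disqualifies frames with more than 1%
of pixels at or above 0.99 of full scale (saturation destroys information
irrecoverably, under-exposure merely loses SNR). If everything is
saturated, the least-saturated frame wins; ties go to the shorter exposure.
The 0.1–0.9 band and the 1% cap are this package's choices — the source
workflows say only "best illumination conditions".

## Inline holography

`simulateInline()` implements the standard inline (Gabor) forward model: a
unit illumination wave crosses a plane of absorbing discs, propagates the
sample-to-sensor distance, and the sensor records the squared modulus —
the interference of scattered and unscattered light — with Gaussian read
noise and quantization. Spherical illumination from a point source at
distance `L` is mapped to the equivalent plane-wave problem at the
effective distance `z_eff = z L/(L + z)` with lateral magnification
`(L + z)/L`; with `z` of a few mm and `L ~ 80 mm` the correction is ~2%,
and plane-wave mode is the default (samples sit essentially on the sensor
window).

Propagation uses the band-limited angular spectrum method: multiply the
field's spectrum by `exp(i 2 pi d sqrt(1/lambda^2 - fx^2 - fy^2))` and zero
the evanescent band. This is exact scalar diffraction; it agrees with the
single-FFT Fresnel transform in the paraxial regime (a `method = "fresnel"`
mode is provided for cross-checking) but remains accurate at mm distances
with 2.2 um sampling. The raw propagator is kept mathematically pure — on
the periodic FFT grid it is unitary, so zero-distance identity, +z/-z
round-trips, Parseval energy conservation and linearity all hold to machine
precision and are tested at that tolerance. Boundary handling lives one
level up, in the hologram pipeline: before refocusing, the normalized
hologram is embedded in a next-power-of-two grid filled with the unit
background, with a 16-px raised-cosine taper blending the frame edge into
the background to suppress wraparound ghosts; the result is cropped back
after propagation.

`normalizeHologram()` divides by the background frame when available
(flooring background pixels at 1e-6 of full scale, with a warning count),
otherwise by the frame mean, and takes the square root as the amplitude
estimate with zero phase. No twin-image suppression is attempted: plain
backpropagation leaves the conjugate image superimposed, as is inherent to
single-shot inline holograms without phase retrieval.

### Depth scanning

`zScan()` refocuses on a uniform depth grid and scores each plane. The
choice of focus criterion was genuinely open and was settled empirically on
seeded random scenes:

* normalized intensity variance `var(I)/mean(I)^2` — the textbook default —
  fails on multi-particle scenes: the defocused fringe system can carry
  *more* variance than the focused dips, locking the scan to the range
  boundary;
* dark-deviation energy `mean(pmax(1 - I/mean(I), 0)^2)` fails the same way
  on a minority of scenes;
* the adopted default is the normalized gradient energy of the
  reconstructed *amplitude*, `mean(|grad sqrt(I)|^2)/mean(sqrt(I))^2`,
  computed after a 3 x 3 box smoothing. Amplitude edges of absorbing
  particles are sharpest exactly at focus; using the amplitude keeps
  fringe oscillations from dominating, and the light smoothing suppresses
  the white read/quantization-noise gradient floor that otherwise drowns
  the signal of a single small particle in a large field.

All three criteria remain selectable. Ties go to the smaller z, which also
fixes the degenerate case of a structureless hologram (flat curve).

Particle localization in a refocused frame uses `refineDipCenters()`: the
dip of an absorbing disc is flat-bottomed, so the argmin wanders by pixels
while the depth-weighted centroid (pixels below half dip depth, Voronoi
masking between nearby seeds) is stable to ~0.2 px.

Sampling note: with 2.2 um pixels the lateral resolution floor of the
lensless geometry is about twice the pixel pitch; recovered particle
separability is only claimed for centre separations of at least 3 pitches.

## Grating spectrometry

`extractSpectrum()` samples the frame by bilinear interpolation at 1-px
steps along a user-chosen segment (the first diffraction order), averaging
over an odd-width perpendicular band with an unweighted mean. Saturated
pixels (>= 0.99 full scale) are excluded from the band mean and counted;
band samples falling outside the frame are clamped and reported in a
warning. Per-channel (R, G, B) and Rec. 709 luminance traces are returned —
whether a browser-based line-plot tool averages channels or plots them
separately varies, so both are available.

`fitCalibration()` is ordinary least squares of wavelength on pixel
position, linear by default. A transmission grating at a 35-degree tilt
would justify mild nonlinearity, but without a geometry calibration a
linear map is the standard and honest choice for visible-range slit
spectrometers; a quadratic option sits behind `degree = 2`. The physical
layout parameters (1000 lines/mm grating, 35-degree tilt, 0.1 mm nozzle
slit, ~40 mm slit-grating distance) are documentation, not inputs: they
never enter the computation. `absorbance()` applies Beer-Lambert
`-log10(I/I0)` with a 1e-6 floor; the source devices demonstrate emission
only, so this is provided as standard spectrophotometry plumbing.

## Timelapse analytics

`flatFieldCorrect()` applies `(frame - dark) / ((flat - dark)/mean(flat -
dark))`. Normalizing the gain map to unit mean makes the correction
brightness-preserving; a flat whose shading field has unit mean is restored
exactly.

`pairShift()` uses phase correlation — the inverse transform of the
spectrally whitened cross-power spectrum — rather than raw
cross-correlation: whitening makes the peak a delta for pure translation
and is the robust standard for shift-only registration (a `method =
"cross"` mode exists for comparison). Frames are mean-subtracted and
Hann-windowed before the FFT to suppress edge effects, and the integer peak
is refined per axis by a three-point parabolic fit (offsets clamped to
±0.5 px). The sign convention: `f2` looks like `f1` shifted by `(+dx
columns, +dy rows)`. The reported quality is the ratio of the peak to the
best competitor outside its 5 x 5 neighbourhood.

`driftTrack()` registers successive pairs and prefix-sums them, matching
how long-series drift is usually reported. Successive-pair tracking follows
slow drift and survives scene evolution, at the cost of random-walk error
accumulation over very long series — registering to a fixed reference would
trade those properties. A failed pair (e.g. a constant frame) is recorded
as missing with quality 0 and contributes zero drift. Both integer and
subpixel modes are exposed, since reported drift figures rarely state
which was used.

`varianceProjection()` is the per-pixel temporal variance of luminance,
min-max rescaled; moving organisms leave bright trajectory traces, and the
projection is invariant to frame order. `intensitySeries()` reports mean
luminance against time per exposure group, the diagnostic used to monitor
illumination decay as a deployment battery discharges.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of its parameters and seed (identical
inputs give bit-identical output) and was written to emulate the imaging
physics the analysis code must survive:

* `makeBarTarget()` — three-bar resolution groups at chosen line widths,
  rendered with fractional pixel coverage, Gaussian optical blur,
  optional Poisson/Gaussian noise. `resolvedLinewidth()` reads the bar/gap
  line profiles recorded in the metadata and reports the smallest width
  with floored Michelson contrast at or above the threshold (default 0.26,
  the Rayleigh-like convention) in both orientations; `NA` means
  unresolved.
* `makeDefocusStack()` — defocus as a Gaussian blur with
  `sigma(z) = sigma0 + rate |z - z0|`. A real defocus PSF is not Gaussian,
  but the focus metrics only require blur monotone in defocus, which this
  guarantees by construction. Default read noise is 1% of full scale, a
  realistic magnitude for a small consumer CMOS sensor.
* `makeDriftingTimelapse()` — a band-limited random scene cyclically
  Fourier-shifted by per-frame ground-truth offsets, with optional radial
  vignetting, per-frame multiplicative dimming (battery-discharge model), a
  moving bright particle, and Gaussian noise. Cyclic shifts mean no content
  enters or leaves the frame — real drift also changes content at the
  borders, which the Hann window mitigates but tests do not exercise.
* `makeSpectrumFrame()` — Gaussian emission lines along a (possibly tilted)
  dispersion axis, coloured by a fixed piecewise-linear wavelength-to-RGB
  approximation (documented, not radiometrically calibrated).
  `whiteLedLines()` provides the classic phosphor-LED shape: narrow blue
  pump plus broad phosphor band with the tell-tale green dip between them.
* `simulateInline()` / `randomParticleScene()` — see the holography section.

Passing tests on these fixtures therefore demonstrates correctness of the
algorithms under controlled physics (known blur laws, cyclic shifts, exact
line positions, shot-noise-free backgrounds), not performance on real
devices, where aberrations, Bayer demosaicing artefacts, rolling-shutter
effects and content change are all present and unmodelled.

## Numerical choices and degenerate inputs

* All FFTs are plain base-R transforms; propagation transfer functions are
  built on the exact FFT frequency grid, so identity/unitarity tests can
  assert at 1e-6 RMS or tighter.
* Gaussian and box filters use edge replication; kernels truncate at
  3 sigma.
* Bilinear sampling clamps out-of-frame coordinates and counts them.
* Tie-breaks are deterministic everywhere: best focus (median proximity,
  then lower z), z-scan (lower z), exposure selection (shorter exposure,
  then earlier frame).
* Degenerate inputs fail loudly: constant frames cannot be registered,
  zero-mean flats cannot correct, all-NaN sharpness curves cannot be
  argmax'd; an empty hologram yields a flat z-scan curve resolved to the
  range minimum.
* Parabolic subpixel refinement offsets are clamped to ±0.5 px; a
  degenerate three-point fit returns 0.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
holography closure on ten 512 x 512 scenes with a 26-step depth scan;
autofocus on twenty 11-layer 128 x 128 stacks; drift recovery on twenty
8-frame 128 x 128 series with shifts up to ±8 px and 2% noise; calibration
recovery over 50 seeded replicates. These sizes were chosen to exercise the
full pipelines with comfortable statistical margins while keeping a
complete run in tens of seconds.

## Known limitations

* No phase retrieval: twin-image artefacts remain in all reconstructions,
  and very low-SNR holograms (e.g. weakly scattering bacteria) are not
  reconstructable by plain backpropagation.
* The linear wavelength calibration ignores grating-equation nonlinearity;
  with strong tilts, calibrate with more points and `degree = 2`.
* Successive-pair drift tracking accumulates error on very long series.
* Aberrations (beyond defocus blur) and Bayer-pattern sampling are not
  modelled anywhere; inputs are assumed demosaiced or grayscale.
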