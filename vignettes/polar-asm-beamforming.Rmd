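---
title: "Wavefield extrapolation and shot-profile migration on curvilinear arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefield extrapolation and shot-profile migration on curvilinear arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(polarasm)
```

## The problem

Fourier-domain beamformers for medical ultrasound have mostly been limited
to linear (flat) arrays, because the angular spectrum method — propagating a
wavefield between parallel planes by multiplying its plane-wave
decomposition with a per-component transfer function — presumes Cartesian
geometry. Curvilinear (convex) probes, the workhorse of abdominal imaging,
put their elements on a circular arc of radius $r_0$ and produce sector
images in polar coordinates $(\theta, r)$.

`polarasm` implements the angular spectrum method directly in polar
coordinates and builds a shot-profile migration beamformer on it. The
conformal log-polar substitution $x = e^{\rho}\sin\theta$,
$z = e^{\rho}\cos\theta$ (with $\rho = \ln r$) turns the 2-D wave equation
into a form whose angular Fourier transform
$\hat p(k_\theta, \rho, f)$ satisfies a one-dimensional ODE in $\rho$ with
the closed-form phase-integral solution

$$
H_\pm(k_\theta, r_1, r_2, f) = \exp\!\Big(\pm 2\pi i\,|k_\theta|\,
\big[\Phi(r_2) - \Phi(r_1)\big]\Big),\qquad
\Phi(r) = \sqrt{u^2 - 1} - \arctan\sqrt{u^2 - 1},\quad
u = \frac{f\,r}{c\,|k_\theta|}.
$$

One extrapolation step from the shell $r_1$ to $r_2$ is
$W(\theta)\,\mathcal F^{-1}\{H_\pm\,\mathcal F\{p\}\}$, where $W$ is an
angular window suppressing wrap-around of the circular convolution. The
$k_\theta = 0$ bin is always evaluated by its closed-form limit
$\exp(\pm 2\pi i f (r_2 - r_1)/c)$, never by the generic formula.

## What the propagator is — and what it is not

Three properties of $H_\pm$ carry the whole numerical design:

* **Unit modulus** for propagating components ($u > 1$ at both radii): the
  exponent is purely imaginary, so a march conserves angular spectral
  amplitude exactly.
* **Exact composition**: $\Phi$ differences telescope, so marching in many
  small steps equals one long step for a constant sound speed. The step
  size therefore does not control accuracy of the propagation itself; it
  controls how often the window is applied and the radial sampling of the
  image. The package default is half a wavelength (0.22 mm at 3.5 MHz in
  1540 m/s tissue).
* **Pure phase**: the closed form is the WKB (phase-integral) solution of
  the exact Bessel-type radial ODE. The true radial solutions carry an
  additional slowly varying amplitude $\propto ((f r/c)^2 -
  k_\theta^2)^{-1/4}$; omitting it means a marched field does not reproduce
  the physical $\sim 1/\sqrt{r}$ cylindrical decay across shells. For
  imaging this is immaterial (each shell's gain is common to transmit and
  receive and cancels in relative envelope metrics), but any comparison of
  absolute pressure across depths must align amplitude per shell. The
  validation study below does exactly that.

**Evanescent components** ($u \le 1$) are where the published formula is
silent. The default policy accumulates phase only over the propagating
portion of the radial path and hard-zeros components that are evanescent at
the destination shell; an alternative `decay` policy analytically continues
the phase integral with the branch for which $|H| \le 1$. Half a wavelength
from the aperture the difference is negligible; zeroing is the safer
default because the wrong continuation branch amplifies.

**Sign conventions.** Temporal spectra use the analysis kernel
$e^{-2\pi i f t}$, so a delay multiplies a spectrum by $e^{-2\pi i f T}$.
With that convention branch `-` advances an outgoing (transmit) field
outward in $r$, and branch `+` marches receive data outward while unwinding
their travel time. The angular transforms use $e^{\mp 2\pi i k_\theta
\theta}$ with spacing-scaled discrete forms, so the round trip is the
identity and Parseval's relation holds; $k_\theta$ is in cycles per radian.

**The angular window** is a Tukey taper (`make_window`), flat over the
interior and rolling to zero over 12.5% of the aperture on each side
(`taper_fraction = 0.25`), applied at every step. Its shape is not
prescribed by the method — any smooth edge taper serves — and the flat
interior guarantees it never touches energy in the imaging sector provided
the grid margin exceeds the taper width. Reconstruction grids therefore
carry an angular margin beyond the probe aperture.

## Shot-profile migration

For each focused transmit event $i$ the beamformer builds two shell fields
at $r = r_0$:

* transmit: $\hat p_{tx}(\theta, r_0, f) = A(\theta) P(f)
  e^{-2\pi i f \tau(\theta)}$ from the event's apodization, focal delays
  and pulse spectrum;
* receive: the one-sided band spectra of the recorded element traces,
  phase-referenced to the firing of the earliest element.

Both are marched outward shell by shell (branches `-` and `+`), and at
every shell the frequency-domain imaging condition accumulates
$I_i(\theta, r) = \sum_f w(f)\, p_{tx}^*\, p_{rx}$. Events are compounded
coherently, $I = \sum_i I_i$, and the envelope $|I|$ is taken only after
summation (the imaging condition sums complex per-shot images directly, so
coherent compounding is the natural reading). Only the current shell of
each field is kept in memory; a snapshot mode stores selected shells for
time-domain demonstrations.

Two reconstruction weights matter in practice:

* **Band weights** (`band_weights`): a flat passband over the pulse's
  support down to −40 dB by default. Hard truncation of a much narrower
  band causes axial ringing; a Tukey `taper` mode trades axial resolution
  for smoothness. A property test confirms that narrowing the band
  stretches the axial extent of a point image.
* **k-space f-number weights** (`fnumber_weights`): depth-dependent receive
  apodization is structurally impossible in this framework, but an
  f-number acceptance cone can be imposed in the angular-spectrum domain:
  pass $|k_\theta| \le (f r/c)\sin(\arctan(1/2F))$, cosine-tapered over the
  outer 10%. The mapping of f-number to acceptance angle is this package's
  documented choice (treating $1/2F$ as the tangent of the half-aperture
  angle, the usual aperture-growth rule); the published method does not fix
  one.

**Element-to-grid mapping.** Apodization and delays are defined per
element; on the reconstruction grid every $\theta$ sample lying inside an
element's arc footprint takes that element's values, so an element occupies
its physical width regardless of grid density (the grid must sample at or
above element density, enforced). The time-domain reference subdivides each
element into sub-sources across the same footprint, so both models share
one aperture geometry.

## The time-domain reference simulator

`simulate_transmit_field` and `simulate_channel_data` are direct-summation
point-source simulators, the package's independent oracle: no Fourier
marching, just delayed, spread, superposed pulses (and Born single
scattering with $1/(d_{tx} d_{rx})$ spreading for channel data). Design
choices:

* The waveform is a Gaussian-modulated cosine whose −6 dB spectral full
  width equals the stated fractional bandwidth — one pulse definition
  shared with the Fourier side.
* `spreading = "spherical"` gives textbook 3-D point sources
  ($s(t-d/c)/d$); `spreading = "cylindrical"` gives the far-field 2-D
  line-source response ($1/\sqrt d$ with a half-integral −45° filter),
  which is the physically consistent reference for a 2-D solver.
* `derivative = TRUE` radiates the time derivative of the source waveform:
  a field prescribed as pressure on the source surface (which is exactly
  what the transmit initialization does) radiates the derivative of that
  waveform, the familiar piston-source relation. The validation study uses
  cylindrical spreading with the derivative on.
* No obliquity factor by default (soft-source approximation); a cosine
  obliquity option exists for exploration but the validation agrees better
  without it at these apertures and angles.
* Channel data use a factorized two-stage sum: the per-scatterer transmit
  waveform is accumulated on a local time grid at twice the trace rate and
  then spread to the receive elements with Catmull-Rom resampling. This is
  an exact reordering of the pair sum up to the resampling, which carries
  about 1% RMS error for a 50%-bandwidth pulse — identical for every
  consumer of the data. An `exact` per-pair mode is kept both as the
  reciprocity-exact reference and as the cross-check of the fast route.
* The record starts just before the earliest possible echo (`t0` is stored
  in the container and honoured by both beamformers), which shortens
  traces without touching any arrival.

**Phantoms** (`make_phantom`) place bright point targets, uniform diffuse
scatterers with i.i.d. standard-normal amplitudes at a stated density per
resolution cell, and anechoic lesion discs whose interior scatterers are
removed; the diffuse draw is deterministic under its seed. Fully developed
speckle conventionally needs on the order of 10 scatterers per cell.

## The virtual-source DAS baseline

`das_virtual_source` is the comparison method: each focused transmit is
modelled as a virtual point source at its focus, with the two-sided
hyperbolic time model $t_{tx} = t_{focus} \pm |p - v|/c$ (valid before and
beyond the focus), linear-interpolated sampling of each element's
analytic-signal trace at the round-trip time, f-number receive aperture
growth (ray-to-element-normal angle test with a cosine edge taper), a ±15°
validity cone about each beam axis with a cosine edge roll-off plus a 4 mm
cosine-blended acceptance around the focus itself (the bare two-sided cone
excludes the focal neighbourhood, where every direction is far off-axis),
and coherent compounding. These defaults are deliberately conventional — the
baseline is tuned reasonably, not adversarially; its cone and f-number are
configurable.

## The two studies

`replicate_validation()` (deterministic, seconds): 128-element probe,
49.57 mm radius, 0.508 mm pitch; 3.5 MHz, 50% bandwidth; 20-element
subaperture focused at 20 mm; 0.22 mm steps; c = 1540 m/s. The ASM march
and the time-domain reference are evaluated at the same grid nodes
(|θ| ≤ 0.12 rad at 10, 20 and 30 mm depth) on one time axis, and the NRMSE
(reference-normalized RMS error after least-squares amplitude scaling) is
pooled energy-weighted over depths with the scale aligned **per depth** —
the pure-phase propagator carries an arbitrary per-shell gain against a
physical reference (see above), and the published per-depth waveform
comparison is insensitive to it. Both the pooled per-depth figure (≈ 0.9%)
and the single-global-scale figure (≈ 6%, floored by the WKB amplitude
term, not by waveform error) are returned.

`replicate_comparison(seed)` (stochastic, minutes): 5C1 geometry
(180 elements, 46.03 mm radius, 0.3212 mm pitch), walking-aperture focused
transmits at 97 mm focal depth spanning ±36.103°. Desk-scale choices, made
once and stated here: 31 beams (the clinical sequence's 121 thinned over
the same span — compounding density, not geometry), a 96-element transmit
subaperture (f/3.1 at the focus; the acquisition's subaperture is not
published), diffuse density 2 per resolution cell (sufficient for
mean-envelope statistics; fully developed speckle texture would need ~10),
14 MHz sampling with two sub-sources per element,
a 512 × 0.44 mm polar grid to 128 mm depth, a Tukey-tapered 2–5 MHz band,
and f-number 2 on both beamformers. Nine bright point
targets at 40–125 mm (all ≥ 10 mm from the focus) give the mean lateral
−6 dB width for each beamformer; two anechoic discs (6 and 7 mm radius at
55 and 115 mm) with flanking same-depth background sectors give the
contrast difference. The phantom (and nothing else) consumes the seed.

What passing these studies does and does not show: the synthetic phantom
has idealized point scatterers, a constant sound speed, no attenuation,
absorption, elevation geometry, element directivity or electronic noise, so
agreement here demonstrates correctness of the wavefield mathematics and
the expected relative behaviour of the two beamformers under Born
scattering — not in vivo image quality.

## Numerical choices and degenerate inputs

* Zero-length steps are the identity by construction (no evanescent
  masking is applied when $r_2 = r_1$).
* The $k_\theta = 0$ bin and the $u \to 1$ turning point are handled by
  limits ($\Phi \to 0$ continuously at $u = 1$).
* `lateral_fwhm` refines the envelope peak by parabolic interpolation and
  the −6 dB crossings linearly; it errors rather than extrapolate when the
  peak sits on the image boundary or the width is not bracketed.
* `nrmse` rejects an identically zero reference; regions passed to
  `contrast_db` must be non-empty and disjoint on the grid.
* Containers are versioned single-file R serializations with a validated
  schema; readers name the first missing dataset and reject newer versions.
* All randomness (phantom, noise) flows through explicit seeds and
  restores the caller's RNG state.

## Known limitations

Radially varying sound speed only (piecewise-constant per step) — angular
variation would need a split-step phase-screen extension. 2-D geometry (no
elevation). No attenuation or nonlinearity. The DAS baseline is one
reasonable parameterization of a family of methods; conclusions about
*margins* over DAS depend on its tuning, while the direction of the
comparison is robust in our experiments.
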