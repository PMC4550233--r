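---
title: "Modelling spinning-spot shadowless TIRF: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spinning-spot shadowless TIRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spintirf)
```

## The problem and the model

Objective-type TIRF illumination focuses a laser spot near the periphery of
the objective back focal plane (BFP). The Abbe sine condition ties the
spot's radial position to the incidence angle at the coverslip,
$r = f\,n_1\sin\theta$, and once $\theta$ exceeds the critical angle
$\theta_c = \arcsin(n_2/n_1)$ the transmitted field becomes evanescent,

$$ I(z) = I_0\, e^{-z/d}, \qquad
   d = \frac{\lambda}{4\pi\sqrt{n_1^2\sin^2\theta - n_2^2}}, $$

confining excitation to a sheet of order 100 nm. With the default optics
(60×, $f = 3$ mm, NA 1.45, $n_1 = 1.515$, $n_2 = 1.33$, 488 nm) the TIR
annulus at the BFP runs from $f n_2 = 3.99$ mm to $f\,\mathrm{NA} =
4.35$ mm, and the depth ranges from divergent at the inner edge down to
about 67 nm at the aperture edge. The package adopts this standard
closed form for $d$; the geometry functions (`critical_angle()`,
`bfp_radius_to_angle()`, `penetration_depth()`) are exact inverses of each
other over the aperture.

A stationary spot illuminates from a single azimuth, and two
direction-locked artifacts follow: interference fringes from coherent
scattering along the beam path, and shadows cast behind refractile
structures, both oriented by the illumination azimuth. Spinning the spot
around the BFP circle during one camera exposure replaces the field by its
azimuthal mean, in which these artifacts cancel. That averaging — not any
new physics — is the entire mechanism, and the package represents it
literally: `spinning_field(n)` is the elementwise mean of
`single_azimuth_field()` over $n$ equally spaced azimuths (a test asserts
exact equality with the brute-force mean).

## Phenomenological choices

The paper-level description gives no optical-path detail from which
fringes or shadows could be derived, so both are modelled
phenomenologically, with parameters chosen once:

* **Speckle**: a sum of `n_components = 8` cosine fringes whose wavevector
  tracks the illumination azimuth (±15° jitter), period 1.5 μm (×0.7–1.3
  jitter), random phases, overall contrast 0.3. Contrast 0.3 puts the
  stationary-spot spatial CV near 7%, qualitatively matching the strongly
  modulated stationary-spot films the method was designed to fix, while
  remaining a modulation (the field never goes negative).
* **Shadows**: each occluder disk attenuates by its `attenuation`, and
  casts a downstream wedge (half-angle 5°) whose attenuation recovers
  exponentially over 5 μm. Only the *directionality* matters for the
  conclusions (spinning symmetrizes it); the lengths are plausible rather
  than derived.
* **Beam envelope**: Gaussian with 1/e² radius `beam_waist`, default
  infinite — a well-expanded beam is flat over the ~50 μm field. Every
  lateral field is normalized to mean 1, so switching modes never changes
  the expected total signal from a uniform specimen at the interface.
* **Axial models**: spinning/stationary TIRF use $e^{-z/d}$ with $d$ set by
  the scan radius; pseudo-widefield excites uniformly through a 5 μm cell
  thickness; skimming-plane (radius just below the TIR threshold, beam
  skimming the coverslip) is given an exponential profile with
  $d_\mathrm{eff} = 1$ μm. The paper describes skimming geometrically but
  not axially; an exponential with micron-scale depth interpolates sensibly
  between TIRF and widefield and is configurable.

## Scan control

Waveform tables are one full period of quadrature sine/cosine at the stated
sample rate (1 MHz default), in normalized drive units where 1.0 is the
aperture radius; conversion to mm lives in the optics module because the
instrument's own units are arbitrary volts. Handedness (y leads x;
counterclockwise seen from the objective) is a convention — nothing
downstream depends on it. Interleave schedules cycle up to three presets
ABCABC…; each spinning frame must span a whole number of revolutions so the
exposure averages all azimuths, so `build_schedule()` rounds
`exposure_time × frequency` to the nearest integer ≥ 1 and adjusts the
frequency, recording the adjustment. At the canonical 5 ms exposure this
gives the 200 Hz scan rate. Frame interval is taken equal to exposure time
(contiguous exposures); where source material is ambiguous about interval
versus exposure semantics, both are simply parameters here.

## Specimen and camera

Brightnesses are quoted in photons/pixel per 5 ms reference exposure under
unit excitation; rendering scales linearly with exposure (a test checks the
doubling). The film (100 photons/pixel) sits at $z = 0$. Puffs have a
linear rise (10 ms) and exponential decay (100 ms), a 2-D Gaussian
footprint (σ = 0.8 μm), and — the key simplification — no diffusion: a
puff's widefield-visible amplitude is its full amplitude and its
TIRF-visible amplitude is attenuated by $e^{-z/d}$ at the release depth.

The **cytosolic indicator** component is what makes the two modes'
normalizations differ. Volume-distributed dye contributes its full
brightness to the widefield resting fluorescence $F_0^{WF}$ but only the
thin slice $\sim d/L$ of it to $F_0^{TIRF}$. Since ΔF/F₀ divides each
mode's signal by its own baseline, the event-ratio forward model becomes

$$ \mathrm{ratio}(z) \;=\; k\, e^{-z/d}, \qquad
   k = F_0^{WF} / F_0^{TIRF} > 1 , $$

so superficial events ($z < d\ln k$) genuinely show *larger* ΔF/F₀ in TIRF
than widefield — the observed hallmark of interleaved recordings. A
baseline confined to $z=0$ would force $k = 1$ and cap every ratio at 1,
which is why the volume term is part of the model rather than an optional
extra. Conveniently $k$ need not be configured: it is measurable from the
data as the ratio of the two resting maps over the ROI
(`estimate_calibration()`), and `analyze_puffs()` does this per site by
default. The defaults (film 100, cytosol 300 photons/pixel, 5 μm
thickness) give $k \approx 3.5$, i.e. a widefield baseline ~4× the TIRF
baseline — typical of a cytosolically loaded indicator — and place the
unity crossing of the ratio near 280 nm.

The EMCCD model draws Poisson photons at
`qe × expected signal × exposure`, multiplies by a gamma-distributed EM
register (mean `em_gain`, excess noise factor √2; a deterministic
`"mean"` gain mode exists for exact-value tests), adds Gaussian read noise
and the black level, and quantizes to 16-bit counts. Defaults (qe 0.9,
gain 50, read noise 10, black level 100) put the film near 4500 counts —
noise-limited but far from saturation, so the ±1% stability benchmark is a
real measurement rather than trivially zero. Each frame draws from a
counter-derived substream of the run seed, so renders are byte-identical
for a given seed regardless of evaluation order.

## Processing and analysis conventions

* ΔF/F₀ uses the per-pixel mean over a stated resting-frame range as F₀;
  pixels with F₀ below 1 count are masked (`NA`) rather than producing
  unbounded ratios — a division-stability policy recorded in the stack
  metadata.
* ROIs are 0-based half-open pixel rectangles; "3×3" site ROIs are centred
  on the site's integer pixel, and linked ROIs on de-interleaved substacks
  share identical pixel coordinates.
* Event amplitude is the in-window maximum minus the median of the trace
  outside all event windows; the median is robust to the events themselves.
  Taking a maximum of a noisy trace biases both modes' amplitudes upward;
  the bias largely cancels in the ratio but residually compresses deep-site
  depth estimates by a few tens of nm — visible in the recovery tests and
  accepted as part of the estimator.
* Adjacent-region variation is the maximum symmetric percent difference
  $100\,|m_i - m_j|/(m_i + m_j)$ over neighbouring tiles, a definition
  fixed here because "variation between adjacent regions" admits several.
* Sites are classified by mean event ratio (> 1.1 superficial, < 0.9 deep)
  with at least 4 events required, and depth estimates invert the forward
  model with the site's measured $k$.

## Scenario conditions and problem sizes

The packaged scenarios fix the study conditions: `film_beads` renders 600
frames of 5 ms spinning-spot TIRF at ~100 photons/pixel for the stability
and uniformity measurements; `shadow_cells` alternates stationary and
spinning frames over occluders; `puff_depths` places sites on a jittered
grid with depths uniform over 0–600 nm, ≥ 4 events per site, alternating
5 ms TIRF/widefield frames; `triple_interleave` cycles 488 nm TIRF, 532 nm
TIRF and skimming presets. The `puff_depths` TIRF preset scans at
normalized radius 0.925, just above the TIR threshold, giving
$d \approx 224$ nm: depth ranges of hundreds of nm are only resolvable when
$d$ is commensurate with them (at the aperture edge, $d \approx 67$ nm,
sites beyond ~300 nm are invisible in TIRF), and varying penetration depth
via scan radius is precisely the flexibility the scanned-spot design
provides. Test and benchmark renders use 96–128 px frames and tens to
hundreds of frames — small enough to run in seconds, large enough that
shot-noise-limited statistics (e.g. the ±1% frame-mean stability over a
100×100 px region) are meaningful.

## What the synthetic data do and do not show

The generator reproduces the *mechanisms* the method addresses —
azimuth-locked fringes and shadows, their cancellation under azimuthal
averaging, evanescent depth attenuation, per-mode ΔF/F₀ normalization, and
EMCCD counting statistics. It omits wave-optical speckle formation, Fresnel
transmission factors and polarization, the optical PSF (beads land in a
single pixel; puffs carry their own Gaussian footprint), Ca²⁺ diffusion and
buffering, photobleaching, and drift. Passing tests therefore demonstrate
that the pipeline is correct *given* the forward model — e.g. that depths
are recovered to < 50 nm RMSE when ratios truly follow $k e^{-z/d}$ — not
that real cells obey that model; in real recordings diffusion blurs the
depth readout and the widefield baseline varies with cell geometry.

## Known limitations

* The depth estimator treats widefield visibility as depth-independent;
  events deeper than the cell-thickness scale would violate this.
* Stationary-spot TIRF keeps the full speckle model but no galvo dynamics
  (phase lag, finite bandwidth) are simulated; the instrument compensates
  these empirically and they do not affect the averaged field.
* Multi-level stepwise puff kinetics and automated event detection beyond a
  simple threshold-crossing helper are out of scope; event windows are
  expected from ground truth or the user.
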