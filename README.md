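# spintirf

Simulation and analysis of **spinning-spot shadowless TIRF microscopy**.

Through-the-objective total internal reflection fluorescence (TIRF)
microscopy excites fluorophores in a thin evanescent sheet — of the order of
100 nm — above the coverslip, by focusing a laser to a spot near the edge of
the objective back focal plane (BFP). With the spot held stationary, the
coherent illumination arrives from a single azimuth and the field is marred
by interference fringes and by shadows cast behind refractile cellular
structures. Spinning the spot in a circle around the BFP with a pair of
galvanometer mirrors, fast enough that each camera exposure averages over
all 360° of azimuthal incidence, removes these direction-dependent
irregularities and produces an effectively uniform field. Because the scan
settings can change between frames, alternating presets frame by frame gives
near-simultaneous recordings in different modes (TIRF, pseudo-widefield,
"skimming-plane"), which in turn lets the axial depth of Ca²⁺ release events
be read out from the ratio of their TIRF and widefield amplitudes.

This package is a hardware-free model of that instrument and its analysis
chain, for microscopists and modellers who want to explore the acquisition
scheme quantitatively:

* **Scan control** — galvanometer drive waveform synthesis
  (`synthesize_waveforms()`: x(t) = x₀ + A·sin 2πft,
  y(t) = y₀ + eA·cos(2πft + φ)) and frame-by-frame interleave schedules of
  up to three presets with camera triggers (`build_schedule()`,
  `frame_triggers()`).
* **TIRF optics** — critical angle θ_c = arcsin(n₂/n₁), the sine-condition
  BFP mapping r = f·n₁·sin θ, the evanescent penetration depth
  d = λ / (4π √(n₁² sin²θ − n₂²)), and lateral excitation fields for
  stationary-spot, spinning-spot, widefield and skimming modes with a
  phenomenological speckle/shadow model (`mode_field()`,
  `penetration_depth()`).
* **Simulation** — synthetic specimens (fluorophore film, beads, occluders,
  puff sites with rise/decay kinetics, cytosolic indicator) rendered through
  an EMCCD model (Poisson photons, gamma-distributed EM gain, read noise,
  black level) into interleaved, mode-tagged 16-bit stacks
  (`render_stack()`, `make_scenario()`).
* **Processing** — black-level subtraction, de-interleaving, pixelwise
  ΔF/F₀ = (F − F₀)/F₀ normalization, maximum-intensity projections, linked
  ROI traces, linescans and field-uniformity metrics (`deinterleave()`,
  `df_f0()`, `roi_trace()`, `uniformity_metrics()`).
* **Puff analysis** — per-event TIRF/WF amplitude ratios, site
  classification (mean ratio > 1.1 superficial, < 0.9 deep, ≥ 4 events per
  site), and depth estimation by inverting ratio(z) = k·e^(−z/d)
  (`analyze_puffs()`, `estimate_depth()`), with `tidy()` / `glance()` /
  `autoplot()` methods.

## Worked example

Four puff sites at known depths, imaged in alternating 5 ms TIRF/widefield
frames, recovered from the rendered movie alone:

```r
library(spintirf)

sc  <- make_scenario("puff_depths", seed = 7,
                     overrides = list(n_sites = 4,
                                      depths = c(0, 150, 300, 450)))
stk <- render_stack(sc$specimen, sc$schedule, sc$cfg, sc$camera,
                    seed = 7, speckle = sc$speckle, n_azimuths = 90)
stk
#> <image_stack> 460 frame(s) of 96x96 px, 5 ms exposure, modes: spinning_tirf, widefield

subs <- deinterleave(subtract_black(stk), 2)
nb   <- sum(subs$tirf$timestamps < 0.5)           # resting frames
rt   <- df_f0(subs$tirf, c(1, nb))
rw   <- df_f0(subs$wf,   c(1, nb))

ps <- sc$specimen$puff_sites; px <- sc$camera$pixel_size
rois <- setNames(lapply(1:4, \(i)
  roi_center(floor(ps$x[i] / px), floor(ps$y[i] / px), 3,
             label = as.character(i))), 1:4)
events <- purrr::map_dfr(1:4, \(i)
  tibble::tibble(site_id = i, t0 = ps$event_times[[i]] - 0.02,
                 t1 = ps$event_times[[i]] + 0.25))

d <- penetration_depth(488, bfp_radius_to_angle(0.925 * 3 * 1.45), optical_config())
analyze_puffs(rt, rw, rois, events, d = d)
#> <puff_analysis> 24 event(s) at 4 site(s); fraction of ratios > 1: 0.67
#> # A tibble: 4 × 7
#>   site_id n_events mean_ratio sd_ratio class            k depth_nm
#>     <int>    <int>      <dbl>    <dbl> <chr>        <dbl>    <dbl>
#> 1       1        6      3.73    0.285  superficial   3.54       0
#> 2       2        6      1.85    0.0969 superficial   3.50     143.
#> 3       3        6      1.01    0.0989 intermediate  3.48     276.
#> 4       4        6      0.576   0.103  deep          3.51     405.
```

The TIRF preset here scans at normalized radius 0.925, just above the TIR
threshold, giving a penetration depth d ≈ 224 nm. Each site's mean TIRF/WF
amplitude ratio falls with its depth; inverting ratio = k·e^(−z/d), with the
calibration k ≈ 3.5 measured from the resting baselines of the two modes,
recovers the true depths (0, 150, 300, 450 nm) to within a few tens of nm.

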