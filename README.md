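# qdsted

Quantitative analysis of STED nanoscopy images of blinking quantum dots,
with a matched point-scanning acquisition simulator.

Far red-shifted CdTe quantum dots (emission ~740 nm) can be imaged with a
775 nm depletion beam, adding a third spectral channel to standard
two-colour STED microscopy. Their use raises four quantitative problems
that this package addresses for microscopists and image analysts:

1. **Direct-excitation background.** The depletion beam itself excites the
   dots, adding a donut-shaped halo around every emitter in the STED image.
   Recording a second image with the depletion beam alone (*STEDonly*) and
   subtracting it (*STEDsub = STED − STEDonly*) recovers the super-resolved
   signal.
2. **Blinking.** Quantum dots switch stochastically between emissive (ON)
   and dark (OFF) states with dwell times of order 0.1–1 ms. In a raster
   scan this leaves dark stripes across each dot. The package models
   blinking as a two-state telegraph process with exponential dwells,
   builds per-dot *blinking masks* (ON/OFF pixel classification against the
   dot's expected radial profile), and summarizes them as the *blinking
   pixel ratio* (fraction of a dot's footprint classified OFF) and the
   background-subtracted *integrated brightness*. Splitting a fixed 200 µs
   pixel dwell into repeated faster lines (1×200 µs → 10×20 µs → 100×2 µs)
   averages blinking out; the simulator reproduces this trade-off.
3. **Resolution.** Line profiles through single dots are fitted with
   Lorentzians (STED) or Gaussians (confocal); FWHMs versus depletion power
   follow the standard depletion law `FWHM(I) = d_c / sqrt(1 + I/I_sat)`,
   which `fit_resolution_curve()` estimates from measured sweeps.
4. **Internalization biology.** In cells, the STEDonly donut doubles as an
   information channel: a single dot has a dark donut centre, an unresolved
   cluster fills it. Thresholding the centre-to-crest ratio classifies
   single vs cluster; combined with vesicle and tubulin masks this yields
   the fraction of dots inside vesicles (QDFI), the single fraction
   parameter (SFP = single fraction inside / single fraction outside), and
   per-dot distances to the nearest microtubule.

Every stage is backed by a synthetic-data generator (`generate_qd_field()`,
`simulate_acquisition()`, `generate_cell_scene()`) that emulates the
microscope: line-by-line raster scanning with configurable dwell/repeat
schedules, per-emitter continuous blink traces, channel PSFs
(Gaussian confocal, Lorentzian STED centre plus donut halo, donut-only
STEDonly), Poisson shot noise, and cell phantoms with exact colocalization
ground truth.

## Worked example

Simulate eight quantum dots, subtract the STEDonly background, and measure
each dot:

```r
library(qdsted)

cfg   <- scan_config(pixel_size_nm = 30, image_shape_px = c(120, 120),
                     dwell_time_us = 20, n_line_repeats = 10)  # 200 us/px
field <- generate_qd_field(8, cfg, photon_rate_per_us = 5,
                           min_separation_nm = 700, edge_margin_nm = 400,
                           seed = 11)
stack <- simulate_acquisition(field, cfg, background_fraction = 0.4,
                              seed = 11)
stack <- add_stedsub(stack)
qds   <- measure_qd_photophysics(stack$channels$STEDsub, pixel_size_nm = 30,
                                 known_fwhm_nm = 65, min_distance_px = 5)
qds[, c("x_nm", "y_nm", "integrated_brightness_counts",
        "blinking_pixel_ratio", "fwhm_nm")]
```

```
  x_nm y_nm integrated_brightness_counts blinking_pixel_ratio fwhm_nm
1  972 2324                         3674               0.0588    83.6
2  645 1208                         3050               0.1875    69.6
3 2865  766                         3295               0.0000    84.0
4  583 3071                         3147               0.1250    63.7
5 1753 1337                         3215               0.0000    71.3
6 2451 1997                         2926               0.2500    54.8
7 2950 2784                         3925               0.1111    75.7
8 1182  403                         3183               0.0000    86.5
```

All eight simulated dots are recovered. `blinking_pixel_ratio` is the
fraction of each dot's footprint that was dark while the scan crossed it
(0 = never dark; the mean here is 0.09 under the 10×20 µs schedule, which
suppresses apparent blinking relative to a single slow line).
`integrated_brightness_counts` sums background-subtracted counts over the
ON pixels. `fwhm_nm` is the Lorentzian-fitted width of the line profile
through each dot (mean 73.6 nm against a configured 65 nm PSF, the
difference being shot-noise scatter at this photon budget).

Group comparisons use the rank-sum test with the field's star convention:

```r
compare_groups(ratio_mowiol, ratio_pbs)  # p, stars, % difference of means
```

A full synthetic experiment (scene phantom → acquisition → subtraction →
detection → classification → colocalization statistics) runs through
`run_pipeline(config, mode = "full")`, or from a shell via
`Rscript inst/cli/qdsted.R full --config cfg.yml --seed 1 --out outdir`.

## Layout

- `R/` — scan geometry and PSF models, blinking model and simulator,
  STEDsub processing, photophysics measurements, cluster/colocalization
  metrics, I/O and pipeline orchestration
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code)
- `vignettes/qdsted-methods.Rmd` — model assumptions, parameter choices,
  numerical decisions, and limitations
- `inst/cli/qdsted.R` — command-line wrapper
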