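---
title: "Models and methods behind qdsted"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qdsted}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdsted)
```

This vignette records the scientific models the package implements, the
parameter choices that matter, and the places where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Imaging model

**Geometry.** A raster scan is described by `scan_config()`: pixel size
(nm), image shape, per-line pixel dwell (µs), number of line repeats, and
optional flyback dead time. Conventions, fixed once and used everywhere:
row/column indices are 0-based in timing formulas, the fast axis runs
along columns (x), and the centre of pixel `(i, j)` is at
`((j + 0.5) px, (i + 0.5) px)`. `pixel_clock()` orders dwell windows
line-by-line with all repeats of a row completing before the next row —
the ordering that makes blinking interact correctly with repeats. Flyback
defaults to 0; it is configurable because inter-line gaps change which
part of a blink trace each repeat samples.

**PSFs.** Three radial profiles (`psf_model()`), all peak-normalized to 1:

* Gaussian `exp(-4 ln2 r²/w²)` for the confocal channel;
* Lorentzian `1/(1 + 4 r²/w²)` for the depleted (STED) centre — its
  heavier tails fit depleted emitters better than a Gaussian, and line
  profiles through super-resolved dots are conventionally fitted with it;
* an LG01-like donut `(r²/s²) exp(1 − r²/s²)` for the direct-excitation
  background, with an exact zero at the centre and crest at `r = s`. The
  analytic form is a package choice; only donut-shaped images, not a
  formula, are available to match.

`render_psf()` evaluates profiles at pixel centres without area
integration; at the 25–30 nm pixels used here the difference is well below
shot noise.

**Resolution law.** The depletion law
`FWHM(I) = d_c / sqrt(1 + I/I_sat)` is standard STED theory; the package
adopts it because measured resolution-versus-power curves have the
characteristic saturating shape. It is a two-parameter model estimated by
Levenberg–Marquardt (`fit_resolution_curve()`). The instrument's confocal
FWHM is not published for this system, so it is a free configuration
parameter; the simulator defaults to `d_c = 250 nm` and `I_sat = 12 mW`,
chosen once so that the law passes through the published operating point
(~65 nm at 168 mW depletion power). Fits use `minpack.lm::nls.lm`
directly rather than `nlsLM()`: the latter fails while constructing its
`nls` result object on exact zero-residual fits, which the oracle tests
exercise deliberately.

## Blinking model

Blinking is a stationary two-state alternating renewal (telegraph)
process: independent exponential ON and OFF dwells with means `tau_on`,
`tau_off`. This is the simplest model consistent with the available
evidence, which bounds the dark-state lifetime to roughly 0.1–1 ms under
these imaging conditions. Defaults are `tau_on = tau_off = 0.45 ms`
(OFF occupancy 0.5 before suppression), inside that bracket. Because
exponential residuals are memoryless, drawing the first dwell from the
plain exponential already gives a stationary trace when the initial state
is drawn from the stationary distribution, which is the default.

The depletion beam suppresses blinking. This is modelled multiplicatively:
`tau_on` is scaled by `suppression_factor` (default 1.5) in the STED and
STEDonly channels. No published number constrains the magnitude; the value
is exposed in the configuration.

`trace_on_fraction()` integrates a trace's ON time over arbitrary dwell
windows exactly (piecewise-linear cumulative ON time), so expected counts
per pixel per repeat are exact given the trace. The asymptotic standard
error of a measured occupancy,
`Var = 2 tau_on² tau_off² / ((tau_on + tau_off)³ T)`, follows from the
exponential autocovariance of the two-state Markov process and is used as
the yardstick in the occupancy tests.

## Acquisition simulator

For each channel, emitter and dwell window: expected photons =
`photon_rate × dwell × PSF(channel) × ON-fraction`; counts are Poisson per
pixel per repeat, then summed over repeats. Channel PSFs: confocal =
Gaussian; STED = Lorentzian + `background_fraction` × donut; STEDonly =
`background_fraction` × donut. The direct-excitation background is linear
in the donut intensity with a single `background_fraction` parameter
(default 0.4) — the published account attributes the halo to direct
excitation by the depletion beam without a quantitative model, so a linear
one-parameter form is declared rather than inferred. Each emitter carries
one independent continuous trace per channel acquisition spanning the
whole scan; one global seed fans out deterministically to per-channel,
per-emitter substreams, so runs are reproducible and single emitters can
be re-simulated in isolation. Simulated `expected` images (occupancy-mean,
noise-free) are returned alongside the counts and anchor the conservation
tests.

Lorentzian tails decay slowly, so per-emitter support is truncated at
6×FWHM (Gaussian 2×FWHM, donut 3×scale); the conservation tests compare
against the same truncated render, and at these sizes the truncated tail
is ≲1% of the total.

**Clusters.** A site of multiplicity k is k emitters at independent
uniform-in-disk offsets within `cluster_radius_nm`, each with its own
blink trace. The default radius is 75 nm. This is a deliberate choice: for
the linear donut background model, an emitter offset `d` from the site
centre contributes `(d/s)² e^(1−d²/s²)` of its crest intensity at the
centre, so 20 nm offsets would fill the centre by only a few percent of
the crest for any plausible donut scale — optically indistinguishable from
a single dot, and inconsistent with the observable the classification
method rests on (clusters appearing as filled discs rather than donuts in
STEDonly images). 75 nm corresponds to dots spread within a vesicle-sized
region and is marginally unresolvable at 65–70 nm STED resolution.

**Cell phantoms.** `generate_cell_scene()` builds disk vesicles, random
line-strand tubulin rasterized at one pixel and dilated to ~100 nm width,
and places QD sites *constructively*: requested fractions (inside
vesicles, near tubulin, clustered inside/outside) are converted to counts
once by rounding, and sites are drawn from the matching region pixels with
dots at pixel centres — so the realized fractions equal the requested ones
exactly and ground truth is exact by construction, not probabilistically.
An optional minimum site separation avoids sub-resolution collisions that
no detector could undo; it defaults to 0 (dots may share a vesicle).

## Photophysics measurements

**Detection.** Local maxima above `median + 5×MAD` (Poisson-floored),
non-maximum suppression within `min_distance_px`, plus a local prominence
test: the peak must exceed the median of a surrounding annulus by
`threshold_sigma` times the annulus MAD. The prominence test exists
because subtraction doubles shot-noise variance on the halo ring of
STEDsub images while zeroing its mean; without it, noise maxima ring every
bright dot. Sub-pixel centres come from a background-subtracted 3×3 centre
of mass. Strong blinking can split one dot into two maxima along the slow
axis; widening `min_distance_px` (to ~1.5× the PSF FWHM in pixels) merges
them.

**Blinking mask.** The dot's expected non-blinking image is a radial
Lorentzian whose width and centre come from a 1D fit through the brightest
row, and whose amplitude is the maximum of per-row least-squares scales
over the brightest rows — the premise being that the brightest lines were
recorded fully ON. Pixels with predicted signal ≥ 20% of the predicted
peak are *considered*; a considered pixel is ON when its
background-subtracted counts reach 25% of the predicted signal. Both
thresholds are exposed; the defaults keep the false-OFF rate of simulated
non-blinking dots below 5% at photon budgets comparable to the recorded
data (this is verified by a test). The underlying reference procedure is
not public, so this construction is declared as the package's own.

**Integrated brightness** sums `max(counts − background, 0)` over the ON
pixels by default (`pixels = "considered"` is available). The ON-pixel
convention is what reproduces the observed brightness ordering across
dwell schedules: with repeated faster lines, blinking lowers many pixels
partially instead of blanking a few completely, and those partially-dark
pixels remain in the ON mask at reduced counts.

**Group statistics.** Brightness and ratio distributions are skewed, so
`compare_groups()` uses the two-sided Wilcoxon rank-sum test with the
four-level star convention (0.05/0.01/0.001/0.0001). Two effect summaries
are reported because both appear in practice: the relative difference of
means (a "40% decrease") and the ratio of means (an "increase to 403%").

## Cluster classification and colocalization

`donut_central_ratio()` divides background-subtracted mean counts at the
centre (default: the centre pixel only, where an ideal single-dot donut is
exactly zero) by the mean over the crest annulus (default radii 2.5–4.5 px,
bracketing a 100 nm donut scale at 25–30 nm pixels). Singles score ≈0,
clusters fill the centre. The classification cutoff defaults to 0.3, ties
classifying as single. SFP is the ratio of single fractions inside versus
outside the vesicle masks — the formula is the package's reading of a
qualitative description ("more single QDs inside ... as opposed to
outside"), declared as such. Inside/outside membership is
centroid-in-mask without dilation (a dilation radius is available for
membrane labels whose lumen is unlabelled). Distances to tubulin are exact
Euclidean centre-to-pixel-centre distances, zero when the centre lies in
the mask; no sub-pixel refinement. The distance map used by the scene
generator is an exact chunked brute-force minimum so that it coincides
with the declared exhaustive oracle by construction.

Bleed-through ratios come from single-label acquisitions: background-
subtracted mean signal over the fluorophore's structure mask in a foreign
channel divided by the same quantity in its own channel; the diagonal is 1
by definition. The published normalization procedure is not public; this
definition is the package's own and is validated by recovering injected
crosstalk in simulation.

## Numerical choices and degenerate inputs

* Fits: Levenberg–Marquardt (`nls.lm`), bounded below by a tenth of the
  sample spacing and above by 4× the profile span; a width pinned at its
  upper bound raises an error rather than returning a flat "fit".
* STEDsub: subtraction scale defaults to 1 (equal acquisition settings);
  negatives are preserved by default because fits and statistics on the
  clipped image would be biased, with `clip_negative = TRUE` for display
  and detection. Whether the reference analysis clipped is unknown; both
  behaviours exist.
* Degenerate inputs error loudly: empty considered masks, all-zero
  predictions, zero crest signal, empty tubulin masks, zero outside
  singles (undefined SFP), fewer than 3 powers, fewer than 5 profile
  samples.
* Ties in detection plateaus break deterministically to the first
  column-major position.
* Signed images are stored as offset-encoded 32-bit TIFF (integer counts
  round-trip exactly); unsigned counts as plain 16-bit.

## Problem sizes used by the tests and acceptance script

Simulated checks run at ROI scale (11–21 px across, one dot) with
50–200 replicates per claim, 120-site classification runs, 40-dot
phantoms, and 10×10⁴ ms blink traces. These sizes keep Monte-Carlo
standard errors a few times smaller than the tolerances being asserted
while completing in minutes on one core.

## What the synthetic data does and does not show

The generator reproduces the mechanisms the analysis relies on — donut
background, telegraph blinking interacting with dwell schedules, Poisson
noise, resolution scaling, cluster-filled donut centres, colocalization
geometry — so green tests demonstrate that the *analysis chain* measures
what it claims on data whose truth is known. They do not validate the
physical accuracy of the defaults (true dwell-time distributions,
suppression magnitude, background amplitude, cluster geometry in real
vesicles), nor microscope effects the generator omits: drift and stage
noise, detector afterpulsing, photobleaching, aberrated or vectorial PSFs,
spectral crosstalk beyond a linear mixing coefficient, and vesicle shapes
beyond disks. Quantities that depend on those specifics (absolute
blinking ratios or brightnesses, for example) should be compared between
conditions measured with this package, not against numbers from other
instruments.
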