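---
title: "Methods: multi-view shoot segmentation, growth analytics and PSII quenching analysis"
author: "shootpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view shoot segmentation, growth analytics and PSII quenching analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootpheno)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunables that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices behind the implementation.

## 1. The segmentation model

A shoot photographed against soil occupies a complicated region of RGB
space, but after conversion to HSV it collapses to a short arc on the hue
circle: saturation and value carry illumination, not identity. The
pipeline therefore thresholds the **hue channel alone**, by default on the
interval [80°, 160°] ("plant green"). The interval is configurable, and
Otsu's method on the hue channel is available (`use_otsu = TRUE`) for
setups without a standardized colour calibration; the fixed interval is the
default because with standardized image acquisition it is both simpler and
more stable than a data-driven threshold. Achromatic pixels (saturation 0)
have no hue and are always background.

Hue thresholding alone fails on *tendrils*: offshoots one or two pixels
wide. Such a pixel's colour is a mixture of plant and background (the
structure does not fill the pixel), so its hue drifts toward the soil, and
one lost pixel disconnects the whole offshoot — which mask clean-up then
discards. The pipeline recovers these structures with a **Canny edge
detector** on the value channel (Gaussian smoothing, Sobel gradients,
non-maximum suppression, double-threshold hysteresis): thin bright
structures produce strong, well-tracked contours even where their hue is
ambiguous.

### Fusing threshold and edges

`fuse_masks()` implements an anchored union: the fused mask is the
threshold mask plus every 8-connected edge component that touches it.
Anchoring is what rejects background contours (pot rims, soil speckle)
while keeping tendril contours attached to the stem. Two facts about Canny
output motivate the refinement step `segment_view()` applies to the raw
edge mask before fusion:

* the gradient ridge of a 1-px line sits on its two *flanking* rows, not on
  the line itself, so the raw edge mask brackets a tendril without
  containing it — closing the edge mask by 1 px (`edge_close_radius`)
  fills the gap so the structure's own pixels enter the fusion;
* the ridge of a *thick* structure straddles its boundary, so half of the
  contour pixels lie on background — admitting edge pixels only when their
  own hue falls within the foreground interval widened by
  `edge_hue_margin_deg` (default 30°/side) removes this halo while keeping
  mixed-colour tendril pixels, whose hue sits between soil and plant.

With this refinement, noiseless synthetic plants segment with recall and
precision 1.0, and the fused pipeline recovers ≥ 90 % of tendril pixels on
the erasure fixture (Section 5) while strictly beating hue thresholding
alone.

### Post-processing order and defaults

`postprocess_mask()` applies, in a fixed documented order: median filter →
closing → opening → small-component removal. The *defaults* disable the
first three (radii 0) and keep only the size filter
(`min_component_px = 8`): a 3×3 median filter or opening erases exactly the
1-px structures the pipeline exists to keep, so speckle clean-up is done by
component size instead, which cannot harm anything attached to the plant.
The filters remain available for imaging setups with coarser structures.
Canny defaults (`low = 15`, `high = 35` on Sobel magnitude of an 8-bit
value channel, `sigma = 1`) were chosen so that a thin line with ≥ 0.1
value contrast over pixel noise of sd 8 is tracked, while pure noise stays
below the hysteresis floor.

Trays hold a fixed number of pots side by side, so `split_tray()` assigns
connected components to equal-width vertical strips by centroid column — a
deliberately simple rule that matches the standardized tray geometry.

## 2. Growth analytics

Projections from three orthogonal views are combined as
\(A = \sqrt{A_x^2 + A_y^2 + A_z^2}\), a biomass proxy that is symmetric,
1-homogeneous and never below the largest projection. A missing view is
treated as a zero projection with a warning: the estimate is biased low but
remains defined and visibly flagged. Calibration divides known reference
areas (millimetre-paper bars imaged in the pots) by their pixel counts,
averaging references per view.

NGA divides by the first measuring day's area, making cohorts of different
initial size comparable; it is unit-free, hence invariant to calibration.
RGR uses the mean-of-logs form
\(\mathrm{RGR} = (\overline{\ln W_2} - \overline{\ln W_1})/(t_2 - t_1)\).
The mean over *log* areas (not the log of mean areas) is the classical
growth-analysis estimator; the two differ whenever growth is heterogeneous,
and the package tests pin the distinction. Intervals are consecutive
measuring days by default, with day-1-anchored intervals behind a flag
(`rgr_series(anchored = TRUE)`); day indices come from the input table,
never from file timestamps.

## 3. Quenching analysis

`protocol_timing()` encodes the measurement layout; its defaults are the
standard short induction protocol: F0 from the mean of the initial 5 s
dark window; FM from the first 800 ms saturation pulse; 17 s dark
relaxation; 70 s of actinic light with pulses 8/18/28/48/68 s after
actinic onset; FM′ from the last pulse; F(t) from a 1 s window immediately
before it. All windows are half-open \([t_0, t_1)\), and a window without
samples raises an error naming the window (F(t) is checked before FM′, so
a recording truncated before the last pulse reports the F(t) window).

F(t) is a short-window mean rather than a single sample — noise-robust and
configurable down to one sampling interval. Pulse plateaus can be
summarized as the maximum (default; standard practice), the mean of the top
quartile, or the plain mean; the max is upward-biased by roughly two noise
standard deviations on a flat noisy plateau, so quantitative recovery
studies on synthetic traces should use `"mean"`. FM is always taken from
the first (dark-adapted) pulse; relaxation-phase artefacts are ignored.
Dark-adaptation duration is metadata, not enforced. Traces are assumed
demodulated by the instrument (flash minus pre-flash baseline);
`demodulate_trace()` performs the subtraction for raw paired samples.

The derived quantities follow the standard energy-partition theory of PSII
fluorescence: F0′ estimated from F0, FM, FM′; the six parameters as in the
README. Two identities — Φ_P + Φ_f,D + Φ_NPQ = 1 and Φ_P = q_P·Φ_PSII —
hold algebraically and are enforced in tests to 1e−12; all yields are
invariant to rescaling every level by a common factor. `f0_prime()`
evaluates the no-quenching case FM′ = FM as F0 directly, because the
denominator is analytically 1 there and the naive floating evaluation is
off by an ulp. Pixel-wise analysis (`parameter_image()`) excludes pixels
whose F0 falls below a configurable noise floor, preventing division
blow-ups on background, and reports region medians with lower/upper
quartiles.

## 4. Group statistics

Comparisons use the Mann–Whitney U test with midrank ties: the exact null
distribution when samples are tie-free and \(n_1 n_2 \le 400\), otherwise
the normal approximation with tie and continuity corrections (delegated to
`stats::wilcox.test`; the test suite verifies the exact branch against full
enumeration of all labelings). Spearman's rho is the Pearson correlation of
midranks with a permutation p value — exact enumeration of all \(n!\)
orderings for \(n \le 8\) (via `pracma::perms`), seeded Monte-Carlo
otherwise, with an add-one correction so a Monte-Carlo p is never exactly
zero. All distribution summaries are median and quartiles under the
inclusive linear-interpolation rule (R's quantile type 7); the rule's name
travels with every summary so reports are auditable. Raw per-day p values
are reported without multiple-testing correction, and all tests are
two-sided.

One tie-break deserves note: Otsu's threshold is defined here as the
*smallest* minimizer of the within-class variance over the 256-bin
histogram. When two intensity populations are separated by an empty gap,
every cut through the gap ties, and the smallest-threshold rule lands just
past the lower population — a well-defined, reproducible answer where
implementations that scan downward would return the other end of the
plateau.

## 5. The synthetic-data generator

`make_plant_views()` renders a branching skeleton — an upright stem with
curvature jitter for front/side views, a radial rosette for the top view —
with leaf blobs and thin tendrils at the specified width, painted in
jittered plant-green hue over a flat or soil-textured background
(low-frequency brown noise plus bright speckle). A random jittered-path
skeleton was chosen over an L-system: it is simpler and suffices to
produce 1–2 px offshoots. Ground-truth masks are the rendered skeletons
themselves — constructed, never segmented — so accuracy can be scored
exactly. Everything is deterministic under the seed.

`tendril_coverage` models partial pixel coverage: each tendril pixel is
alpha-blended with the background, which is the physical mechanism by which
real sub-pixel structures acquire mixed colours. The canonical stress
fixture, `tendril_fixture_spec()`, uses coverage 0.3–0.8 with pixel noise
sd 8 over textured soil: hue thresholding then loses roughly 8–15 % of
tendril pixels (their blended, noise-perturbed hue leaves the green
interval) while the value-channel contrast (SNR ≈ 3 at worst) keeps them
visible to the edge detector. Lower coverage was rejected when designing
the fixture because it makes pixels statistically indistinguishable from
background — unrecoverable by any detector, hence uninformative as a test.

`make_growth_series()` draws \(W_i(d) = W_0 e^{rd} \varepsilon_{id}\) with
lognormal noise. The default rate, \(r = \ln(3.5)/20\) per day, makes the
day-21 NGA of a cohort measured on days 1, 5, 8, …, 21 equal 3.5 — the
fold-change regime of a fast-growing cultivar under cold acclimation;
\(\ln(2.5)/20\) gives the 2.5× regime of a slower one. (The elapsed time
between the first and last measuring day is 20 days, which is why the
denominator is 20 and not 21.)

`make_trace()` builds a piecewise induction curve whose transients decay to
their target levels in *finite* time (quadratic ramps rather than
exponentials), so the noiseless trace is exactly F0/FM/F(t)/FM′ on the
extraction windows and level recovery is exact, not approximate. Pulse
plateaus during the actinic phase decay from near FM toward exactly FM′ at
the last pulse, emulating the build-up of non-photochemical quenching.

### What passing tests do and do not show

The generator emulates the *geometry* (thin structures, multiple views,
trays of two), the *colorimetry* (hue-separable plant vs background, mixed
pixels on thin structures) and the *protocol timing* of real data. It does
not emulate specular highlights, shadows, overlapping plants, leaf venation
or 3-D canopy effects, nor instrument-specific detector nonlinearity.
Passing the suite therefore demonstrates correctness of the algorithms
under controlled conditions with known truth — it does not certify
accuracy on any particular camera or fluorometer, which requires the
calibration and validation steps (millimetre-paper references,
fresh-weight correlation, cross-checks against a point fluorometer) the
pipeline's report stage is built to support.

## 6. Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 10⁴
random level quadruples for the closure identities; 10³ pairs for the F0′
limit; 50 random images for the Otsu oracle; 20 noiseless plants × 3 views
at 128×128 px plus the seeded erasure fixture for segmentation; 200
replicates of 15-plant cohorts (lognormal sd 0.05) for RGR recovery; full
enumeration for all group sizes with \(n_1 + n_2 \le 10\) plus 2000 null
replicates (n = 15 per group) for the Mann–Whitney calibration; and a
two-cultivar demo dataset (2 trays × 2 plants per cultivar, 3 days, 3
views) run end-to-end twice to confirm bit-identical outputs under a fixed
seed. These sizes were chosen so the whole validation completes in a few
minutes on one CPU while leaving each check statistically meaningful.

## 7. Known limitations

* The hue interval, Canny thresholds and filter radii are declared
  defaults, not reconstructions of any particular instrument's settings;
  real deployments should calibrate them on reference images.
* Tray splitting assumes pots in a horizontal row; diagonal or stacked
  layouts need a custom splitter.
* The fluorescence analyser covers the steady-state quenching partition
  only: no fast-rise (O-J-I-P) fitting, no NPQ relaxation kinetics, no
  quantum yields of photoinactivated centres.
* Mann–Whitney p values with ties always use the normal approximation;
  for very small tied samples an exact conditional test would be
  preferable but is not implemented.
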