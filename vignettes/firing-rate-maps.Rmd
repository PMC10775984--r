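---
title: "Estimating firing rate maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating firing rate maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratemapr)
```

# The problem

Spatially modulated neurons — hippocampal place cells, entorhinal grid
cells, boundary cells — are characterized through *firing rate maps*: a
spatial raster giving the cell's average firing rate (Hz) at each location
of an environment. A map is estimated from two point processes observed
together: the animal's tracked positions (here `(t, x, y)` at 50 Hz) and
the cell's spike times. Both are far from normally distributed, the map is
their *ratio*, and every estimator involves tuning parameters (bin size,
smoothing strength) that are usually chosen by eye. `ratemapr` implements
six estimators together with a ground-truth simulation suite, so that map
accuracy can be quantified against a known spike-probability surface and
the parameters optimized rather than guessed.

# The estimators

All six methods share a common geometry: a square grid centred on the
arena with `ceiling(width / h)` bins of side `h` per axis, bins being
left-closed right-open intervals (points on the far edge fold into the
last bin). Centring the grid makes the arena symmetric within the bin
lattice for any `h`; the averaged shifted histogram exists precisely
because histogram results depend on this otherwise arbitrary placement.
Missing bins are `NA`, which is distinct from 0 (visited but silent).

**Histogram** (`histogram_map`). Spike counts divided by dwell time
(position counts times the 0.02 s sampling interval) per bin. Smoothing
uses a unit-sum Gaussian kernel of side `2 * ceiling(2 * sigma / h) + 1`
bins (always odd, at least four standard deviations) on zero-padded maps.
Zero padding represents the data as collected without extrapolating
activity beyond the sampled range; it attenuates mass near walls in both
numerator and denominator, so their ratio remains approximately unbiased.
Smoothing is applied *before* division by default: the raw spike and dwell
maps contain no missing values, so plain convolution is valid, and the
alternative (smoothing the ratio afterwards) does not generally improve
accuracy. For smoothing after division the package provides
`nan_aware_smooth()`, which renormalizes the kernel over non-missing
neighbours per pixel (weights always sum to one; out-of-map padding counts
as valid zeros so that a fully observed map reproduces the plain kernel
exactly) and never propagates missing values.

**Averaged shifted histogram** (`ash_map`). The mean of `m^2` histograms
with offset origins, computed equivalently by binning on an `h / m`
sub-grid and convolving with the separable quartic (biweight) kernel
`k(t) = 15/16 (1 - t^2)^2`, with per-axis weights
`w(i) = m k(i/m) / sum k(j/m)` that sum to `m`, conserving counts.
Spike and dwell ASHs are divided as in the histogram. The output lattice
is `m` times finer per axis; `m = 1` reproduces the unsmoothed histogram
bin-for-bin.

**Adaptive smoothing** (`adaptive_smooth_map`). Per bin, a circle is
expanded through 32 radii (one bin width to 640 mm, linearly spaced) until
the enclosed position-sample count `n_p` and spike count `n_s` satisfy
`r >= alpha / (n_p * sqrt(n_s))` with `r` in bin widths; the rate is then
`n_s / (n_p * f_s)`. The criterion is the canonical Skaggs-McNaughton
form, consistent with the conventional `alpha` range of 100-32000; bins
whose criterion is never satisfied (notably when no spike falls within the
largest radius) are left missing rather than zero, as a missing estimate
is distinct from an estimate of silence.

**Adaptive binning** (`adaptive_bin_map`). The same expanding search, but
the stopping rule is purely behavioural: the circle grows until it
encloses at least `t` seconds of dwell, and the rate is enclosed spikes
over enclosed dwell seconds — a K-nearest-neighbour style density
estimate with `K = t * sample_rate`.

Both adaptive methods have two implementations with identical contracts:
`pixelwise` measures true point-to-point distances from each bin centre,
while `convolution` counts on pre-binned zero-padded maps via circular
unity-gain kernels (a bin is inside radius `r` if its centre is within `r`
of the target bin centre). The convolution path is evaluated sparsely
through prefix-sum disc sums in C++, which is algebraically the same
convolution at a small fraction of the cost; the test suite checks that
the two implementations correlate above 0.99 per bin.

**KSDE** (`ksde_map`). The rate at a query point `x` is the ratio of
Gaussian kernel sums over spikes and over positions,
`sum_i K((s_i - x)/h) / (f_s * sum_t K((y_t - x)/h))`, with an isotropic
bandwidth `h`. The estimate is continuous: the query grid spacing sets
resolution only, and values at a fixed location are invariant to how
densely the map is queried. Data are reflected across all four arena
walls before summation (reflection boundary correction; with a separable
Gaussian this adds the per-axis reflected images, equivalent to all nine
mirrored copies). Because kernel sums never reach zero exactly, query
points farther than 50 mm from any position sample are set missing; this
cutoff is evaluated against positions binned at 1 mm, making it exact to
about a millimetre and independent of the query grid.

**Temporal KSDE** (`tksde_map`). First the per-sample spike counts are
convolved with a unit-gain Blackman window (`instantaneous_rate`); window
duration 0.125 s by default — 7 samples at 50 Hz, rounded to an odd
count — because shorter windows yield more accurate maps than the
traditional 2 s. The map value at a query point is then the
Gaussian-distance-weighted average of this instantaneous rate over all
samples, weights normalized to sum one. Unlike the ratio estimators, each
pass through a location contributes its own local rate estimate.

# Scoring maps against ground truth

`mise()` compares a map with the true spike-probability surface: the map
is expanded to the 1 mm lattice by nearest-neighbour (parent-bin)
interpolation, both surfaces are normalized to unit *sum* over the jointly
non-missing support, and the error is the mean squared difference over
that support (a Riemann sum with `dx = dy = 1` mm). Unit sum rather than
unit maximum is used because the error is stated in integrated-probability
units; a consequence is that MISE is invariant to rescaling the rate map,
so it measures shape, not calibration. Missing bins are excluded rather
than penalized — `empty_proportion()` tracks them separately.

`detect_fields()` thresholds a surface at 20% of its maximum and counts
contiguous regions larger than 36 cm^2. Connectivity is 8-neighbour by
default (configurable to 4): place fields are compact blobs, and a
diagonal-only split of one blob into two fields is almost always an
artefact of the lattice. An all-zero surface has no fields by definition.
`field_detect_error()` is the absolute difference against the field count
of the 1 mm truth surface. `alt_metrics()` (Pearson correlation,
Euclidean distance on the same support) ranks parameter combinations
similarly to MISE.

In parameter sweeps (`sweep_method`) the per-combination MISE is computed
through per-bin aggregates of the truth surface (`A`, `sum f`,
`sum f^2` per parent bin), which is algebraically identical to the
reference path — a unit test asserts equality to 1e-12 — while avoiding
re-expansion of the 1 mm lattice for every parameter combination.

# Parameter optimization

A sweep evaluates a (bin size x smoothing) grid, averaging four
objectives over cells: MISE, computation time, empty-bin proportion and
field-detection error. Pareto-optimal combinations are extracted by
exhaustive non-dominated filtering over the evaluated grid
(`pareto_front`): since the search space is a finite grid that has already
been evaluated, a genetic search would add stochasticity without finding
anything the filter cannot, and the exhaustive result is verifiable
against an O(n^2) dominance oracle. From the front, `select_balanced`
min-max normalizes MISE and computation time and picks the member closest
to the utopia point (the vector of front minima), ties broken toward
smaller MISE — the "balanced" solution; `select_min_error` ignores
everything but MISE.

Computation time is wall-clock around map construction only, by default
the median of three repeated builds to damp timer noise (`time_reps`).
The stacked adaptive sweep path (`fast = TRUE`) resolves all smoothing
values in one expanding pass and therefore reports no per-combination
time; it is used where only error objectives are needed.

`fit_parameter_regression` fits OLS planes
`parameter = b0 + b_r * r + b_d * d` over a design of selected solutions
(field radius `r` in mm, duration `d` in minutes), and
`predict_parameters` evaluates either a fitted object or the shipped
published coefficient table (`parameter_table_defaults`), where "smallest
available" bin sizes resolve to the caller's minimum. The shipped
coefficients derive from full-scale benchmark sweeps (with hardware-bound
timing objectives);
re-deriving them exactly is out of scope here (computation-time objectives
are hardware-bound), but the sign structure — larger fields call for
larger bins and stronger smoothing, longer sessions for smaller bins and
weaker smoothing, with the adaptive methods trending oppositely in
duration — is reproduced by scaled-down sweeps in the test suite.

# The simulation suite

`simulate_random_walk` emulates open-field foraging. The agent advances
in 1 s decision steps on a 5 mm grid; each step goes to the pixel
maximising the sum of five max-normalized terms: a Gaussian over step
distance (mu = 64, sigma = 128 pixels, i.e. a preferred speed of 32 cm/s),
a von Mises heading-persistence term (kappa = 1, normalized by its
analytic maximum), the inverted occupancy of a retrospective 8-minute
sliding window, a wall term and a centre term (plus an optional goal
bias). Decision points are joined by straight lines upsampled to 50 Hz,
uniform tracking jitter of +-85 mm is added per coordinate, the path is
smoothed with a robust second-difference (Whittaker) penalized spline with
penalty 128 — the discrete analogue of the penalized-spline smoothing
used on real tracking data — and clamped to the arena.

Three numerical choices here deserve justification, all fixed once against
the walk's design goals (space-filling coverage; weak wall repulsion;
dwell statistics matching a foraging rat) rather than left to the reader:

* *The agent's own pixel is excluded from the argmax.* The heading to the
  current pixel is undefined (`atan2(0, 0)`), and with it included the
  agent can park indefinitely on a spuriously self-reinforcing pixel.
* *Occupancy is stamped with a 40 mm footprint.* A rat samples a
  body-width swath, not a geometric line. With line-width occupancy the
  "unvisited" frontier begins a few millimetres beside the previous lap
  and the argmax walk degenerates into a tight perimeter spiral that
  never reaches the interior (interior dwell CV about 3.5); with the
  footprint, coverage is uniform (CV about 0.3-0.5 at 16 minutes).
* *The wall-distance Gaussian (sigma = 512) acts on the mm scale.* On the
  5 mm pixel scale a sigma of 512 varies by under 3% across the whole
  arena — the wall repulsion it is supposed to implement would vanish.
  The centre term is kept on the (nearly flat) pixel scale, since
  repulsion from all walls of a convex arena already implies attraction
  to its centre; in thigmotaxis mode the centre term is disabled and the
  wall term narrowed (sigma = 100 mm) and left uninverted.

`simulate_place_cell` builds ground truth: per size group (mean per-axis
variances 4000 / 8000 / 16000 mm^2, i.e. 2 SD field radii of 126 / 179 /
253 mm) a pool of 512 candidate fields is drawn with per-cell variation
N(0, 1000^2) clipped at 1000 mm^2, independent x/y variances, an xy
covariance equal to the mean variance times a N(0, 0.25^2) multiplier
clipped to [-1, 1] (redrawn if the matrix is not positive definite), and
uniform centroids. Each cell draws its field count from a gamma(5.73,
0.26) clipped above 1 and rounded (the source describes a continuous draw
without stating rounding), selects that many fields and merges them by
pointwise maximum. Each field surface is a unit-peak Gaussian, so the
surface value is a per-sample spike probability: peak in-field rates
approach the 50 Hz sampling rate and session mean rates land near 1 Hz,
which is what makes the subsequent downsampling step meaningful.

`simulate_spikes` reads the probability at each (1 mm-quantized) sample
position — through a temporally jittered index (N(0.01, 0.02) s, random
sign) to emulate tracking error and theta-scale drift — draws per-sample
Poisson counts plus Poisson(0.001) background, optionally multiplies the
probability by a 1.5 Hz oscillation spanning 0.2-1.8 (overdispersion;
mean 1, so expected counts are unchanged), and finally downsamples
uniformly without replacement to `floor(mean_rate * duration)` spikes,
with target rates N(1, 1) Hz clipped to [0.5, 10]. If fewer raw spikes
exist than the target, all are kept with a warning.

What the generator does *not* emulate: theta phase precession as a
structured (rather than jittered) process, directional or speed
modulation, bursting, electrode drift, and non-convex (alleyway) arenas.
Passing tests therefore demonstrate estimator correctness and the
parameter landscape under idealized Poisson place fields, not robustness
to every failure mode of real recordings.

# Pre-map heuristics

`ripley_h` computes Ripley's K (neighbour counts normalized by density),
its variance-stabilized form `L = sqrt(K / pi)` and `H = L - r`, whose
peak radius indexes cluster size. No edge correction is applied, matching
the procedure this package follows; the resulting downward bias grows
with `r`, which is documented rather than corrected and is why the CSR
sanity test restricts itself to radii well below the arena scale.
`estimate_field_radius` returns `0.75 * argmax H` over 64 radii from 5 mm
to half the arena width — the 0.75 calibration reflects fields whose
spacing is unconstrained. `sturges_bins` and `fd_bins` implement the
histogram rules-of-thumb; Sturges' bin size is truncated to whole mm
(70 mm for a 16-minute and 63 mm for a 64-minute session at 50 Hz, which
is what the truncation reproduces), and the Freedman-Diaconis rule comes
in a per-axis variant (larger of the two axis widths) and an L2-norm
variant applied to `sqrt(x^2 + y^2)`.

# Problem sizes

The full study design (3 durations x 3 field-size groups x 256 cells x
dense parameter grids x 6 methods) is a cluster-scale computation. The
package's own benchmarks use desk-scale cohorts chosen as the smallest
sizes at which the qualitative claims stabilize across seeds: 8
trajectories for rule-of-thumb statistics, 48 cells (16 per group) for
field-size estimation, 24 cells with 8 x 8 log-spaced parameter grids for
the adaptive-binning sweep, and 12 cells with 6 x 6 grids for the sweep
trend tests. Computation-time comparisons across methods are reported but
never asserted against published values, being hardware-bound.

# Known limitations

* Ripley's K has no edge correction; estimates for fields near walls are
  biased small.
* The KSDE's dense-data cost is quadratic-like (all samples enter every
  query); sessions beyond ~30 minutes at fine query grids are slow, which
  mirrors the method's standing in the original comparison.
* The published regression coefficients are shipped as defaults but not
  re-derived; only their sign structure is validated at desk scale.
* `smooth_stage = "after_division"` together with the ASH sub-grid is not
  offered; the ASH is always smoothed by construction.
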