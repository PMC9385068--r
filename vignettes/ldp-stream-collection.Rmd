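---
title: "Locally private stream collection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally private stream collection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldpstream)
```

## The model

Each wearable device holds a stream $s = (t_1,x_1),\dots,(t_n,x_n)$ of a
single numerical attribute sampled at (typically) one-minute intervals.
The collector wants the per-timestamp mean over $w$ devices,
$\mathrm{AVG}(x_i) = \frac1w \sum_{\text{devices}} x_i$, but the devices
are unwilling to ship raw values. Under local differential privacy each
device perturbs its own data with budget $\varepsilon$; the smaller
$\varepsilon$, the stronger the protection and the noisier the data.

Perturbing all $n$ points splits $\varepsilon$ into $n$ tiny shares and
drowns the signal (the `"dwork"` baseline demonstrates this). The scheme
implemented here instead spends the budget only on the stream's
*salient points* and lets the collector interpolate the rest.

### Salient-point identification

With per-point derivatives $d_i = (x_i - x_{i-1})/(t_i - t_{i-1})$, three
kinds of points are redundant: equal-value runs ($d_i = 0$), same-trend
runs (consecutive derivatives of equal sign), and rapid fluctuations
(trend turns within the interval threshold $\alpha$ of the last kept
point). The algorithm removes zero-derivative points first, then scans
the remainder keeping only sign-change points whose distance
$t_{\mathrm{cur}} - t_{\mathrm{sta}}$ from the last kept point exceeds
$\alpha$; the first and last observations are always kept. Two details
of the traversal were genuinely open and are resolved as follows:

* the scan is seeded with the *first real observation* (which also
  initializes $t_{\mathrm{sta}}$), never with an artificial origin point,
  since a fabricated $(0,0)$ knot would corrupt the reconstruction;
* derivatives used in the trend comparison are the ones each survivor
  had in the original stream, not recomputed between survivors.

A zero derivative cannot reach the trend scan, so "same sign" is the
strict test $d_j d_{j+1} > 0$.

### Adaptive Laplace perturbation

The $p$ salient values are normalized with statistics of the salient set
itself, $y_i = (x_i - \bar x)/(x_{\max} - x_{\min}) \in [-1,1]$, and each
point gets the weight

$$r_i = \frac{e^\varepsilon - 1}{2e^\varepsilon + 2}\, y_i + \frac12
  \in [0, 1],$$

computed from the *total* budget, while the Laplace scale uses the
per-point share $\varepsilon_i = \varepsilon/p$:

$$x_i^* = x_i + r_i \cdot \mathrm{Lap}(\Delta s / \varepsilon_i),
  \qquad \Delta s = x_{\max} - x_{\min}.$$

The injected noise has zero mean, so $x_i^*$ is unbiased; $r_i \le 1$
makes its variance at most that of the unweighted salient-point Laplace
baseline (`"kim"`). Since $r_i$ is a function of the private value, the
composite mechanism's noise scale is data-dependent; this package
documents and evaluates the mechanism as defined and asserts no formal
privacy guarantee. The slope factor is evaluated as
$(1-e^{-\varepsilon})/(2(1+e^{-\varepsilon}))$, which is numerically
stable for large $\varepsilon$. When all salient values are equal,
$\Delta s = 0$ and the scale is undefined; values pass through
unperturbed with a warning rather than crashing mid-pipeline.

### Reconstruction and aggregation

The collector interpolates each device's noisy knots back onto the full
grid. All three methods are interpolants (exact at the knots):

* **linear** — chords between knots; the least smoothing and, on the
  benchmark, the lowest error;
* **pchip** — C¹ piecewise-cubic Hermite with Fritsch–Carlson knot
  slopes (weighted harmonic mean of adjacent secants, weights
  $2h_k + h_{k-1}$ and $h_k + 2h_{k-1}$; zero slope at local extrema),
  delegated to `pracma::pchip`; with two knots it reduces to the chord;
* **spline** — C² cubic spline. The continuity conditions fix only the
  interior; the not-a-knot end condition is used because it is the
  default of the numerical environments such curves are usually produced
  with. No installed interpolation routine offers not-a-knot, so the
  moment system is solved directly in the package; two knots collapse to
  the chord and three to the unique parabola. Extrapolation is refused
  by all methods — the pipeline never needs it because endpoints are
  always salient.

Mean estimation averages reconstructed values per timestamp; utility is
scored by MRE (relative usability; requires a strictly positive actual
mean, which heart-rate data and the generator guarantee) and RMSE
(attribute units, more sensitive to outliers). The expected error grows
with the number of noised points and shrinks as $1/(\varepsilon\sqrt w)$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1 | total per-device privacy budget (dimensionless); benchmarks sweep 0.5/1/2 |
| `alpha` | 30 | minimum spacing (minutes) for a trend turn to be kept; larger values compress more aggressively |
| `mechanism` | `adaptive` | `adaptive`, `kim` (unweighted salient Laplace), `dwork` (all-points Laplace, budget ε/n) |
| `recon` | `linear` | `linear`, `pchip`, `spline` |
| `reps` | 20 | independent noise repetitions averaged into the reported metrics |
| `seed` | — | master seed; every (repetition, cell, device) derives its own sub-seed |

Seeds are combined with a small counter-based mix (kept below $2^{31}$),
so sweep cells are independently reproducible. Within a sweep, noise
seeds are derived per (size, budget, repetition) but deliberately *not*
per mechanism or reconstruction method: those comparisons are paired on
identical noise draws, the controlled-variable design that makes small
error differences (linear vs pchip) detectable at modest repetition
counts.

## The synthetic generator

`generate_streams()` emulates condensed minute-resolution heart-rate
streams: 600 points per device, integer bpm, per-device value ranges
drawn from eight canonical subject ranges spanning 57–121 bpm. Each
stream is a random concatenation of three segment kinds chosen to
exercise exactly the redundancy the salient scan removes:

* constant plateaus of 8–40 min (zero derivatives),
* monotone ramps of 15–60 min with strictly alternating direction
  (same-trend runs whose endpoints are genuine turning points),
* short oscillation bursts of 6–20 min with 1–3 bpm amplitude (turns
  inside the α-window).

Default mixture weights are 0.35/0.45/0.20. At α = 30 the scan keeps
roughly 10–15 of 600 points per device (~98% compression), matching the
regime in which a per-point budget of ε/p remains useful. What the
generator does *not* emulate: activity-driven non-stationarity, sensor
dropouts, inter-device correlation, and measurement error of real
wearables — so passing benchmarks show the pipeline's behaviour under
its intended signal structure, not performance on any particular real
cohort. Real PAMAP2 heart-rate channels can be substituted through
`load_pamap2()` (first valid reading per minute, a choice the raw
sub-second sampling leaves open) plus `condense(., 5)`, which keeps the
first record of every five.

Replication to the benchmark record counts (120K–600K) copies base
streams under fresh device ids and leaves the true mean unchanged; every
copy is perturbed independently, the only choice consistent with the
$1/\sqrt w$ error decay.

## Numerical and degenerate-input choices

* Laplace noise is drawn by inverse CDF from one uniform per sample, so
  runs are bit-reproducible under a seed.
* Timestamps need not be unit-spaced; derivatives and the α-window use
  true timestamp differences.
* Streams shorter than 2 points, non-increasing timestamps, duplicate
  timestamps and non-numeric CSV rows are rejected at ingestion.
* `noise_factor = 0` gives a noise-free diagnostic path: with linear
  reconstruction on piecewise-linear data whose breakpoints are spaced
  wider than α, the pipeline is exact (MRE = RMSE = 0), separating
  compression loss from injected noise in any debugging session.

## Benchmark sizes

The shipped tests and examples use 8 base devices × 600 points
replicated to 120K–600K records with 20 repetitions (50 for the scaling
checks), sizes at which the full benchmark suite completes in about a
minute on a single CPU while leaving the qualitative orderings (error
falling in ε, in w; adaptive < kim < dwork; linear ≤ pchip ≤ spline)
clearly resolved.

```{r demo, eval = FALSE}
streams <- replicate_devices(generate_streams(8, seed = 42), 120000)
fit <- ldp_mean(streams, epsilon = 1, reps = 20, seed = 7)
summary(fit)
plot(fit)
```

## Known limitations

* No formal ε-LDP accounting for the adaptive mechanism (noise scale is
  data-dependent, and salient-point *positions* are released exactly).
* The pipeline operates on complete collected windows; there is no
  streaming/online mode.
* MRE is undefined when the actual mean crosses zero; use RMSE for
  attributes without a positivity guarantee.
* Values are not clamped to a physiological range, so reconstructed
  curves can leave it — deliberately, since clamping would bias the mean
  estimate.
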