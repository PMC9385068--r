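# ldpstream

Locally private collection of single-attribute numerical stream data from
wearable devices — e.g. minute-resolution heart rate — with the noise
added **on the device**, so raw physiological data never leaves it, while
the collector can still estimate the population's mean curve accurately.

The package is aimed at researchers evaluating local-differential-privacy
(LDP) trade-offs on time-series sensor data: it implements the full
device/collector pipeline, two Laplace-mechanism comparison baselines, a
seedable synthetic heart-rate generator, and an MRE/RMSE benchmark
harness.

## The scheme

For a device stream *s = (t₁,x₁),…,(tₙ,xₙ)* and total privacy budget ε:

1. **Salient-point identification** (device). Using per-point derivatives
   *dᵢ = (xᵢ−xᵢ₋₁)/(tᵢ−tᵢ₋₁)*, remove zero-derivative runs, same-trend
   runs, and trend turns closer than a threshold α (default 30 min) to the
   last kept point. The surviving *p ≪ n* points (endpoints always
   included) carry the curve's shape, so the per-point budget εᵢ = ε/p
   stays usable.
2. **Adaptive Laplace perturbation** (device). Normalize the salient
   values to yᵢ ∈ [−1,1], form the adaptive random value
   *rᵢ = ((e^ε−1)/(2e^ε+2))·yᵢ + ½ ∈ [0,1]*, and release
   *xᵢ\* = xᵢ + rᵢ·Lap(Δs/εᵢ)* with sensitivity Δs = x_max−x_min of the
   salient values. The noise has zero mean, so each xᵢ\* is unbiased; the
   rᵢ factor shrinks it adaptively below the plain Laplace mechanism.
3. **Reconstruction** (collector). Interpolate each device's noisy
   salient points back onto the full grid — piecewise linear, shape-
   preserving cubic Hermite (pchip), or not-a-knot cubic spline — then
   estimate the mean curve *AVG_est(xᵢ) = (1/w)·Σ xᵢ\** over *w* devices.

Utility is scored against the true mean curve by mean relative error
(MRE) and root-mean-square error (RMSE); the expected error scales as
*O(p/(ε√w))*. Baselines: `"kim"` (same salient pipeline, unweighted
Laplace noise) and `"dwork"` (plain Laplace on every point, budget ε/n).

Note: the adaptive weight rᵢ depends on the private value, so the noise
scale is data-dependent; the package evaluates the mechanism's utility
and makes no formal privacy claim.

## Worked example

```r
library(ldpstream)
streams <- replicate_devices(generate_streams(8, seed = 42), 120000)
fit <- ldp_mean(streams, epsilon = 0.5, alpha = 30,
                mechanism = "adaptive", recon = "linear",
                reps = 20, seed = 7)
summary(fit)
#> Locally private mean-curve estimate
#>   devices: 200   grid: 600 pts   mechanism: adaptive   recon: linear
#>   epsilon: 0.5   alpha: 30   reps: 20   seed: 7
#>   salient points per device: 12.0 of 600 (98.0% removed)
#>   MRE:  0.2748 (se 0.017)
#>   RMSE: 30.05 (se 1.7)
```

Eight synthetic heart-rate devices (600 minutes each, value ranges
57–121 bpm) are replicated to 200 devices / 120 000 records. Salient
extraction keeps ~12 of 600 points per device, so each point receives a
budget of ε/12. At the strictest budget tested (ε = 0.5) the private
mean-curve estimate is off by ~27% on average (MRE 0.27, RMSE ≈ 30 bpm);
`plot(fit)` overlays the estimated and actual curves, and
`residuals(fit)` gives the per-minute gap.

Comparing mechanisms over budgets:

```r
run_sweep(generate_streams(8, seed = 42), epsilons = c(0.5, 1, 2),
          sizes = 120000, mechanisms = c("adaptive", "kim", "dwork"),
          reps = 20, seed = 7)
#>  mechanism  recon epsilon data_size reps      mre     rmse
#>   adaptive linear     0.5    120000   20  0.29194   32.038
#>        kim linear     0.5    120000   20  0.57439   63.247
#>      dwork linear     0.5    120000   20 34.43265 3924.978
#>   adaptive linear     1.0    120000   20  0.15326   16.844
#>        kim linear     1.0    120000   20  0.29401   32.231
#>      dwork linear     1.0    120000   20 17.20928 1963.409
#>   adaptive linear     2.0    120000   20  0.07271    7.983
#>        kim linear     2.0    120000   20  0.14179   15.392
#>      dwork linear     2.0    120000   20  8.72960  990.986
```

Error halves as ε doubles, the adaptive mechanism roughly halves the MRE
of the unweighted salient baseline at every budget, and perturbing every
point ("dwork") is unusable at stream length 600.

A thin command-line wrapper is installed under `exec/`:

```sh
ldpstream demo --seed 1
ldpstream simulate --devices 8 --seed 1 --out streams.csv
ldpstream sweep --in streams.csv --epsilon 0.5,1,2 --out errors.csv
```

Real PAMAP2 heart-rate data (subjects 101–108) can be used instead of the
generator via `load_pamap2("<path>/Protocol")` followed by
`condense(., 5)` per stream; the data set is never downloaded.

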