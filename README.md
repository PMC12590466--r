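# poredeg

Single-molecule quantification of RNA degradation from solid-state
nanopore recordings.

## The problem

RNA integrity is usually assessed by gel electrophoresis, which needs
~100 ng of material and quantifies poorly. Solid-state nanopore sensing
works from picograms: each molecule translocating the pore produces a
transient current blockade whose **peak depth** grows with strand size,
so a single recording yields a per-molecule size readout — the
single-molecule analogue of a gel lane. `poredeg` turns such recordings
into quantitative degradation estimates for people studying RNA
stability (storage buffers, thermal protocols, cation effects on
self-cleavage) and for anyone who needs an RNA-integrity number from too
little material for a gel.

## The model

Peak blockade currents of a partially degraded sample follow a
two-component mixture on [0, ∞):

    f(x) = w · g(x; μ, σ) + (1 − w) · (1/β) · exp(−x/β)

with `g` a Gaussian renormalized to non-negative support. Intact
molecules are one size, spread normally by conformational flexibility
(mean μ, sd σ); stochastic self-cleavage gives approximately exponential
fragment lengths and hence an exponential peak-current component (scale
β). The Gaussian scaling coefficient **w is the full-length fraction** —
the key output. Parameters are fitted by maximum likelihood from
event-level peak currents (`fit_mixture()`); because the fitted density
is normalized, the model mass below the detection threshold estimates
the fragments too small to detect, and the intact estimate is reduced
accordingly (a truncated-likelihood mode makes the correction exact).
Full-length fractions across incubation times are then fitted to
`A·exp(−k·t)` by least squares (`fit_decay()`), giving degradation rate
constants and half-lives `ln 2 / k` for cross-condition comparison
(`compare_conditions()`).

The package also contains event detection from raw current–time traces
(moving-median baseline, robust σ thresholding with hysteresis; peak
current, dwell time and event charge deficit per event) and a seeded
simulator of the whole physical chain (stochastic fragmentation →
length-to-current mapping → trace synthesis with a ground-truth event
ledger), so every stage is testable without instrument data.

## Worked example

```r
library(poredeg)

# a sample of 2000 detected events whose true composition is 60% intact
truth <- mixture_params(w = 0.6, mu = 0.9, sigma = 0.12, beta = 0.25)
x <- simulate_peak_currents(truth, n = 2000, threshold = 0.05, seed = 1)
fit <- fit_mixture(x, threshold = 0.05, mode = "truncated", seed = 1)
fit
#> <mixture_fit> n=2000  mode=truncated  loglik=107.6699
#>   full-length fraction w = 0.6148
#>   mu=0.8962 nA  sigma=0.1271 nA  beta=0.2479 nA
#>   threshold=0.05 nA  sub-threshold mass=0.0703
```

The fitted `w` recovers the programmed 60% intact fraction to ~1.5
percentage points; `sub-threshold mass` says the model attributes 7% of
all molecules to fragments below the 0.05 nA detection limit.

```r
times <- c(0, 15, 30, 60, 120)                    # minutes at 70 C
w_li  <- c(0.83, 0.65, 0.52, 0.33, 0.13)          # full-length fractions
w_na  <- c(0.84, 0.78, 0.72, 0.60, 0.43)
fits <- list(LiCl = fit_decay(times, w_li), NaCl = fit_decay(times, w_na))
fits$LiCl
#> <decay_fit> model=free_amplitude  A=0.8265  k=0.0154375 /min  half-life=44.9 min  rss=5.156e-05

compare_conditions(fits)
#>   condition   k_per_min half_life_min fold_change
#> 1      LiCl 0.015437456      44.90035    2.749314
#> 2      NaCl 0.005615021     123.44516    1.000000
```

The comparison table orders conditions fastest-degrading first and
reports each rate as a fold-change over the slowest — here the
lithium-like series self-cleaves 2.7× faster than the sodium-like one.

For raw recordings, start from `read_trace()` + `detect_events()` (or
drive a whole condition × time matrix from a manifest with
`run_experiment()`); see the vignette in `vignettes/` for the model,
its assumptions and all numerical choices.

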