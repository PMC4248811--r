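# ribbonflux

Quantitative analysis of clathrin and synaptic-vesicle dynamics at
ribbon synapses from live-cell fluorescence microscopy, with synthetic
ground-truth data generators for end-to-end validation.

Sensory neurons retrieve fused synaptic-vesicle membrane within
seconds — an order of magnitude faster than classical clathrin-mediated
endocytosis of surface receptors. Testing how clathrin participates in
that fast retrieval takes three quantitative readouts, all of which
this package implements for R users working with such recordings (or
wanting a tested reference implementation):

* **FCS/FCCS** — infer mobility and co-movement of labelled proteins
  from intensity-fluctuation correlations in a confocal volume. The
  autocorrelation `g(τ) = ⟨δF(t) δF(t+τ)⟩ / ⟨F⟩²` is fitted with the 3D
  diffusion model `g(τ) = b + trip(τ) · (γ/N) · (1+(τ/τD)^a)⁻¹ ·
  (1+(τ/τD)^a/s²)^(-1/2)` (optional triplet term, one or two diffusing
  components), giving the residence time `τD`, the diffusion
  coefficient `D = r0²/(4 τD)`, and — from the dual-colour
  cross-correlation amplitude with crosstalk correction — the number of
  co-diffusing (bound) molecules
  `N_bound = N_g (N_r + Q N_g)/N_cc − Q N_g`.
* **FRAP** — normalise bleach-recovery traces and fit
  `f(t) = mobile · (1 − e^(−t/τ))` for the recovery constant and mobile
  fraction.
* **TIRF event analysis** — segment a synaptic-terminal footprint
  (Laplace-enhanced temporal-SD projection, 8-connected thresholding),
  extract background-corrected ΔF/F traces, select responders crossing
  ±4×SD of baseline, classify accumulation vs loss events within a 10 s
  window, fit recovery kinetics (single/double exponential with
  F-test model selection), and measure each event's distance to the
  nearest ribbon punctum.

A Brownian-dynamics photon-trace simulator (Rcpp), a FRAP curve
generator and a TIRF movie generator produce every input with known
ground truth, so the whole pipeline is testable without microscope
data.

## Worked example

Simulate seven 200 s FCS "cells" of a slow clathrin-like species
(D = 0.0096 µm²/s, five molecules in the volume), average their
correlation curves and fit the diffusion model:

```r
library(ribbonflux)

curves <- lapply(1:7, function(s) {
  cfg <- fcs_sim_config(fcs_species(n_mean = 5, D = 0.0096, brightness_g = 20),
                        beam = fcs_beam(r0 = 0.25, z = 1.25),
                        dt = 1e-3, duration = 200, seed = s)
  autocorrelate(simulate_fcs_trace(cfg)$green, max_lag = 15)
})
fit <- fit_correlation(average_curves(curves), init = list(s_ratio = 5))
fit
#> <diffusion_fit> 1 component(s), converged
#>   N = 5.013, tau_d = 1.577 s, amplitude g(0+) = 0.1995, rss = 0.000179
diffusion_coefficient(fit$params$tau_d, r0 = 0.25)
#> [1] 0.009910536
```

The fitted occupancy (5.01 vs 5 planted), amplitude (0.1995 vs 1/5)
and diffusion coefficient (0.0099 vs 0.0096 µm²/s planted) come back
within a few percent. A noisy FRAP trace and a synthetic TIRF movie
round-trip the same way:

```r
fit_frap(simulate_frap_trace(tau = 7.1, mobile_fraction = 0.6,
                             noise_sigma = 0.02, dt = 0.1, duration = 40,
                             seed = 3), pre_bleach = 1)
#> <frap_fit> tau = 7.09 +/- 0.081 s, mobile fraction = 0.601 +/- 0.0017

sim <- simulate_tirf_movie(movie_sim_config(seed = 1))   # 13 planted events
ana <- analyze_movie(sim$movie, ribbon_image = sim$ribbon_image)
head(ana$events[, c("class", "peak_dff", "distance_to_ribbon", "recovery_tau")], 4)
#>          class   peak_dff distance_to_ribbon recovery_tau
#> 1         loss -0.6891456          0.8085165     15.88670
#> 2         loss -0.7039714          0.7845211     15.19258
#> 3 accumulation  0.7369325          0.8410588     14.13003
#> 4 accumulation  0.6191869          0.3126428     10.61360
match_events(ana$events, sim$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

Events planted on rings 0.4 µm (fusion) and 0.8 µm (clathrin
accumulation/loss) from the ribbon centres are recovered at those
distances; `distance_distribution()` turns them into histograms whose
modes separate the two populations. Condition comparisons work from
fitted kinetics and event counts:

```r
compare_conditions(list(counts = 203), list(counts = 109))
#> <condition_comparison>
#>   event count reduced 1.86-fold (control / treated)
```

A configuration-driven runner executes a whole chain reproducibly
(`run_pipeline(system.file("extdata/demo_config.json",
package = "ribbonflux"))`), stamping all outputs with the seed and a
config hash.

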