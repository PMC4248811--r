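# Shared fixtures, built in code at test time.

# Cheap fast-species configuration for simulator statistics tests:
# tau_d = r0^2/(4D) = 2 ms, far above the 0.1 ms binning.
cheap_fcs_config <- function(n_mean = 5, seed = 1, duration = 2,
                             dt = 1e-4, brightness_g = 1) {
  fcs_sim_config(fcs_species(n_mean = n_mean, D = 5,
                             brightness_g = brightness_g),
                 beam = fcs_beam(r0 = 0.2, z = 1),
                 dt = dt, duration = duration, seed = seed)
}

# Brute-force Monte-Carlo average of the 3D Gaussian detection weight
# over uniform positions in the simulation box (independent oracle for
# the simulated mean count rate).
mc_detection_factor <- function(beam, half, n = 2e5, seed = 99) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr
  }
  with_seed(seed, {
    x <- runif(n, -half[1], half[1])
    y <- runif(n, -half[2], half[2])
    z <- runif(n, -half[3], half[3])
    mean(exp(-2 * (x^2 + y^2) / beam$r0^2 - 2 * z^2 / beam$z^2))
  })
}

# Direct (brute-force) correlation estimator, written independently of
# the package internals, as the oracle for the correlator tests.
brute_corr <- function(f1, f2, lags_k) {
  n <- length(f1)
  d1 <- f1 - mean(f1); d2 <- f2 - mean(f2)
  sapply(lags_k, function(k)
    sum(d1[1:(n - k)] * d2[(k + 1):n]) / (n - k)) / (mean(f1) * mean(f2))
}
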