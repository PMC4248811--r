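test_that("degenerate and deterministic configurations behave as declared", {
  # no emitters, explicitly allowed: all-zero traces
  cfg0 <- fcs_sim_config(list(), beam = fcs_beam(0.2, 1), dt = 1e-4,
                         duration = 0.1, allow_empty = TRUE)
  sim0 <- simulate_fcs_trace(cfg0)
  expect_true(all(sim0$green == 0) && all(sim0$red == 0))
  # ... and rejected without the flag
  expect_error(fcs_sim_config(list(), beam = fcs_beam(0.2, 1), dt = 1e-4,
                              duration = 0.1), "allow_empty")
  expect_error(fcs_sim_config(fcs_species(5, 5), beam = fcs_beam(0.2, 1),
                              dt = -1, duration = 1), "dt")

  # identical seeds give bit-identical traces; different seeds differ
  s1 <- simulate_fcs_trace(cheap_fcs_config(seed = 7, duration = 0.5))
  s2 <- simulate_fcs_trace(cheap_fcs_config(seed = 7, duration = 0.5))
  s3 <- simulate_fcs_trace(cheap_fcs_config(seed = 8, duration = 0.5))
  expect_identical(as.numeric(s1$green), as.numeric(s2$green))
  expect_false(identical(as.numeric(s1$green), as.numeric(s3$green)))
})

test_that("simulated amplitude and count rate match independent predictions", {
  # 10-seed batch at desk scale; fitted g(0+) should be 1/n_mean and the
  # mean count rate n_box * brightness * <W>_box (Monte-Carlo oracle)
  n_mean <- 5
  amps <- means <- numeric(10)
  for (s in 1:10) {
    cfg <- cheap_fcs_config(n_mean = n_mean, seed = 300 + s, duration = 3,
                            dt = 5e-5)
    sim <- simulate_fcs_trace(cfg)
    fit <- fit_correlation(autocorrelate(sim$green, max_lag = 0.3),
                           init = list(s_ratio = 5))
    amps[s] <- fit$amplitude
    means[s] <- mean(sim$green)
  }
  se_amp <- sd(amps) / sqrt(10)
  expect_lt(abs(mean(amps) - 1 / n_mean), 3 * se_amp + 1e-12)

  cfg <- cheap_fcs_config(n_mean = n_mean, seed = 1)
  beam <- cfg$beam
  n_box <- suppressWarnings(
    simulate_fcs_trace(cheap_fcs_config(n_mean = n_mean, seed = 1,
                                        duration = 0.01)))$truth$n_box
  pred <- n_box * 1 * mc_detection_factor(beam, cfg$box_half_widths)
  se_mean <- sd(means) / sqrt(10)
  expect_lt(abs(mean(means) - pred), 3 * se_mean + 1e-3)
})

test_that("trace mean and variance scale linearly with occupancy", {
  m2 <- v2 <- m8 <- v8 <- numeric(10)
  for (s in 1:10) {
    lo <- simulate_fcs_trace(cheap_fcs_config(n_mean = 2, seed = 500 + s))
    hi <- simulate_fcs_trace(cheap_fcs_config(n_mean = 8, seed = 600 + s))
    m2[s] <- mean(lo$green); v2[s] <- var(as.numeric(lo$green))
    m8[s] <- mean(hi$green); v8[s] <- var(as.numeric(hi$green))
  }
  # 4x occupancy: means and variances both 4x (shot + number fluctuations
  # are each proportional to concentration); n_box rounding shifts the
  # realised ratio slightly, so compare against the realised occupancies
  r <- mean(m8) / mean(m2)
  se_r <- r * sqrt(var(m8) / (10 * mean(m8)^2) + var(m2) / (10 * mean(m2)^2))
  expect_lt(abs(r - 4), 3 * se_r + 0.05)
  rv <- mean(v8) / mean(v2)
  se_rv <- rv * sqrt(var(v8) / (10 * mean(v8)^2) + var(v2) / (10 * mean(v2)^2))
  expect_lt(abs(rv - 4), 3 * se_rv + 0.2)
})

test_that("ground truth tables round-trip losslessly through CSV", {
  same_values <- function(a, b) {
    if (is.character(b) || is.logical(b)) expect_identical(a, b)
    else expect_equal(as.numeric(a), as.numeric(b), tolerance = 0)  # exact
  }
  sim <- simulate_fcs_trace(cheap_fcs_config(seed = 2, duration = 0.25))
  f <- tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, f)
  back <- read_ground_truth(f)
  expect_identical(dim(back), dim(sim$truth))
  for (cl in names(sim$truth)) same_values(back[[cl]], sim$truth[[cl]])

  mv <- simulate_tirf_movie(movie_sim_config(seed = 3))
  f2 <- tempfile(fileext = ".csv")
  write_ground_truth(mv$truth, f2)
  back2 <- read_ground_truth(f2)
  for (cl in names(mv$truth)) same_values(back2[[cl]], mv$truth[[cl]])
})

test_that("frap generator hits its closed-form endpoints", {
  tr <- simulate_frap_trace(tau = 7.1, mobile_fraction = 0.6, noise_sigma = 0,
                            dt = 0.1, duration = 40)
  expect_equal(tr$f[1], 0)
  expect_equal(tail(tr$f, 1), 0.6 * (1 - exp(-40 / 7.1)), tolerance = 1e-12)
  expect_lt(abs(tail(tr$f, 1) - 0.6), 0.01)
  # immobile pool only: identically zero
  expect_true(all(simulate_frap_trace(5, 0, 0, 0.1, 20)$f == 0))
  expect_error(simulate_frap_trace(5, 1.2, 0, 0.1, 20), "mobile_fraction")
  expect_error(simulate_frap_trace(5, 0.5, 0, 0.1, 10), "duration")
})
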