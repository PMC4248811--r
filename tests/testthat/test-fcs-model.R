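test_that("diffusion model reproduces closed-form values", {
  # amplitude: g(0) = gamma/N + baseline
  expect_equal(fcs_model_g(0, N = 5, tau_d = 1, baseline = 1), 1.2)
  # at tau = tau_d with negligible axial term the lateral factor is 1/2
  expect_equal(fcs_model_g(1, N = 1, tau_d = 1, s_ratio = 1e12), 0.5,
               tolerance = 1e-9)
  # zero triplet fraction: triplet prefactor is exactly 1
  tau <- 10^seq(-5, 1, length.out = 40)
  expect_equal(fcs_model_g(tau, N = 3, tau_d = 0.01, T = 0),
               fcs_model_g(tau, N = 3, tau_d = 0.01, T = 0, tau_t = 1e-6))
  # triplet fraction without a triplet time is rejected
  expect_error(fcs_model_g(tau, N = 3, tau_d = 0.01, T = 0.2), "tau_t")
})

test_that("two-component model degenerates correctly", {
  tau <- 10^seq(-5, 1, length.out = 50)
  # Y = 1 leaves only the first component
  expect_equal(fcs_model_g(tau, N = 4, tau_d = 0.02, Y = 1, tau_d2 = 2),
               fcs_model_g(tau, N = 4, tau_d = 0.02))
  # model with zero baseline is strictly decreasing in lag
  g <- fcs_model_g(tau, N = 4, tau_d = 0.02, Y = 0.6, tau_d2 = 2)
  expect_true(all(diff(g) < 0))
  # printed rendering carries its +1 offset and power -1 axial term
  gp <- fcs_model_g(0, N = 5, tau_d = 1, as_printed = TRUE)
  expect_equal(gp, 1 + 0.2)
})

test_that("noiseless curves are fitted back to the generating parameters", {
  lags <- 10^seq(-4, 1.2, length.out = 80)
  curve <- structure(data.frame(lag = lags,
                                g = fcs_model_g(lags, N = 10, tau_d = 2.3)),
                     class = c("correlation_curve", "data.frame"))
  fit <- fit_correlation(curve, init = list(s_ratio = 5))
  expect_true(fit$converged)
  expect_equal(fit$params$N, 10, tolerance = 1e-6)
  expect_equal(fit$params$tau_d, 2.3, tolerance = 1e-6)

  # two components: 95% slow + 5% fast minority, recovered within 1e-4
  g2 <- fcs_model_g(lags, N = 10, tau_d = 0.003, Y = 0.05, tau_d2 = 2.3)
  curve2 <- structure(data.frame(lag = lags, g = g2),
                      class = c("correlation_curve", "data.frame"))
  fit2 <- fit_correlation(curve2, components = 2L,
                          init = list(s_ratio = 5, tau_d = 0.01, tau_d2 = 1))
  expect_true(fit2$converged)
  expect_lt(abs(fit2$params$tau_d - 0.003) / 0.003, 1e-4)
  expect_lt(abs(fit2$params$tau_d2 - 2.3) / 2.3, 1e-4)
  expect_lt(abs(fit2$params$Y - 0.05), 1e-4)
})

test_that("residence time converts to diffusion coefficient and back", {
  expect_equal(diffusion_coefficient(tau_d = 1, r0 = 0.2), 0.01)
  expect_equal(diffusion_coefficient(tau_d = 1, r0 = 0.2, geometry_factor = 2), 0.02)
  # calibrating the waist from one printed pair and applying it to another
  r0 <- beam_radius(D = 0.005, tau_d = 4.61)
  expect_equal(r0, 0.3036, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(2.3, r0), 0.01002, tolerance = 5e-4)
  expect_error(diffusion_coefficient(-1, 0.2))
  expect_error(beam_radius(0.005, 4.61, geometry_factor = 3))
})

test_that("bound-number arithmetic follows the crosstalk-corrected relation", {
  res <- n_bound(10, 10, 20)
  expect_equal(res$n_bound, 5)
  expect_equal(res$frac_green_bound, 0.5)
  expect_equal(res$frac_red_bound, 0.5)
  # hand arithmetic with crosstalk: 10*(10+1)/20 - 1
  expect_equal(n_bound(10, 10, 20, q = 0.1)$n_bound, 4.5)
  # vanishing cross-correlation amplitude means nothing co-diffuses
  expect_lt(n_bound(10, 10, 1e12)$n_bound, 1e-9)
  # overcorrection clips at zero with a warning
  expect_warning(res0 <- n_bound(2, 2, 1e6, q = 0.5), "overcorrect")
  expect_equal(res0$n_bound, 0)
  expect_true(res0$clipped)
  expect_error(n_bound(-1, 2, 3))
})
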