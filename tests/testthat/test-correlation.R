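test_that("autocorrelation matches exact results on constructed traces", {
  # constant trace: delta F is identically zero
  const <- intensity_trace(rep(3, 64), dt = 1)
  expect_equal(autocorrelate(const, max_lag = 10, scheme = "direct")$g,
               rep(0, 10))

  # alternating 2,0,2,0,...: mean 1, g(1) = -1, g(2) = +1 by symmetry
  alt <- intensity_trace(rep(c(2, 0), 4), dt = 1)
  g <- autocorrelate(alt, max_lag = 2, scheme = "direct")$g
  expect_equal(g, c(-1, 1))

  # zero-mean trace is rejected with a normalisation error
  expect_error(autocorrelate(intensity_trace(rep(0, 100), dt = 1), max_lag = 5),
               "mean")
  # max_lag beyond half the duration is rejected
  expect_error(autocorrelate(alt, max_lag = 5), "half")
})

test_that("multiple-tau scheme equals the brute-force direct estimator", {
  set.seed(41)
  for (n in c(4096L, 10000L)) {
    tr <- intensity_trace(rpois(n, 8) + rbinom(n, 1, 0.3) * 5, dt = 1e-3)
    direct <- autocorrelate(tr, max_lag = n * 1e-3 / 3, scheme = "direct")
    mtau <- autocorrelate(tr, max_lag = n * 1e-3 / 3, scheme = "multiple-tau")
    shared <- intersect(direct$lag, mtau$lag)
    expect_gt(length(shared), 30)
    gd <- direct$g[match(shared, direct$lag)]
    gm <- mtau$g[match(shared, mtau$lag)]
    expect_lt(max(abs(gd - gm) / pmax(abs(gd), 1e-30)), 1e-8)
    # and the direct scheme itself agrees with an independent oracle
    oracle <- brute_corr(as.numeric(tr), as.numeric(tr), round(shared / 1e-3))
    expect_equal(gm, oracle, tolerance = 1e-10)
  }
})

test_that("cross-correlation identities hold", {
  set.seed(5)
  x <- intensity_trace(rpois(2048, 6), dt = 1e-3)
  ac <- autocorrelate(x, max_lag = 0.5)
  # self-cross identity
  expect_equal(crosscorrelate(x, x, max_lag = 0.5)$g, ac$g)
  # normalisation is scale-invariant
  x2 <- intensity_trace(2 * as.numeric(x), dt = 1e-3)
  expect_equal(crosscorrelate(x, x2, max_lag = 0.5)$g, ac$g, tolerance = 1e-12)
  # mismatched traces are rejected
  y <- intensity_trace(rpois(1024, 6), dt = 1e-3)
  expect_error(crosscorrelate(x, y, max_lag = 0.2), "length")
  expect_error(crosscorrelate(x, intensity_trace(rpois(2048, 6), dt = 2e-3),
                              max_lag = 0.2), "dt")
})

test_that("independent noise traces show no cross-correlation beyond 3 SE", {
  set.seed(17)
  a <- intensity_trace(rpois(20000, 10), dt = 1e-3)
  b <- intensity_trace(rpois(20000, 10), dt = 1e-3)
  cc <- crosscorrelate(a, b, max_lag = 0.8, n_blocks = 8)
  # with ~80 lags an isolated 3 SE excursion is expected by chance;
  # genuine co-diffusion would push many lags far beyond it
  expect_lte(sum(abs(cc$g) > 3 * cc$se), 2)
  expect_lt(abs(mean(cc$g / cc$se)), 1)
})

test_that("curve averaging and CSV round-trips preserve values", {
  set.seed(3)
  tr1 <- intensity_trace(rpois(4096, 7), dt = 1e-3)
  tr2 <- intensity_trace(rpois(4096, 7), dt = 1e-3)
  c1 <- autocorrelate(tr1, max_lag = 1); c2 <- autocorrelate(tr2, max_lag = 1)
  avg <- average_curves(list(c1, c2))
  expect_equal(avg$g, (c1$g + c2$g) / 2)
  f <- tempfile(fileext = ".csv")
  write_curve_csv(f, avg)
  back <- read_curve_csv(f)
  expect_equal(back$g, avg$g)
  expect_equal(back$lag, avg$lag)
})
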