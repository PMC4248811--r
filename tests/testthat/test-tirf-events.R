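test_that("Laplace enhancement follows the 5-point stencil", {
  expect_equal(laplace_enhance(matrix(7, 9, 9)), matrix(0, 9, 9))
  ramp <- outer(1:9, 1:9, function(r, c) 2 * r + 3 * c)
  expect_equal(laplace_enhance(ramp)[2:8, 2:8], matrix(0, 7, 7))
  img <- matrix(0, 7, 7); img[4, 4] <- 10
  L <- laplace_enhance(img)
  expect_equal(L[4, 4], -40)
  nb <- c(L[3, 4], L[5, 4], L[4, 3], L[4, 5])
  expect_true(all(nb > 0))
  expect_equal(sum(nb), -L[4, 4])
  expect_error(laplace_enhance(1:5), "matrix")
})

test_that("segmentation labels 8-connected components deterministically", {
  # blank image: a valid empty ROI set
  expect_equal(nrow(segment_rois(matrix(0, 20, 20))$rois), 0)

  # two disjoint 3x3 squares, correct centroids in raster order
  img <- matrix(0, 20, 20)
  img[3:5, 3:5] <- 100
  img[12:14, 15:17] <- 100
  rs <- segment_rois(img, threshold_sd = 1e-9, min_pixels = 4,
                     pixel_size = 0.1)
  expect_equal(nrow(rs$rois), 2)
  expect_equal(rs$rois$n_pixels, c(9, 9))
  expect_equal(rs$rois$x, c(3.5, 15.5) * 0.1)
  expect_equal(rs$rois$y, c(3.5, 12.5) * 0.1)

  # diagonal-only contact joins under 8-connectivity
  img2 <- matrix(0, 10, 10)
  img2[2, 2] <- 1; img2[3, 3] <- 1; img2[4, 4] <- 1; img2[5, 5] <- 1
  rs2 <- segment_rois(img2, threshold_sd = 1e-9, min_pixels = 2)
  expect_equal(nrow(rs2$rois), 1)
  expect_equal(rs2$rois$n_pixels, 4)
  # min_pixels filters small components
  rs3 <- segment_rois(img2, threshold_sd = 1e-9, min_pixels = 5)
  expect_equal(nrow(rs3$rois), 0)
})

test_that("trace extraction produces exact dF/F for constructed movies", {
  fr <- 60; H <- 16; W <- 16
  st <- array(100, dim = c(fr, H, W))
  st[31:fr, 5:7, 5:7] <- 200            # ROI doubles at frame 31
  mv <- tirf_movie(st, 0.1, 0.1, stimulus_onset_frame = 25L,
                   stimulus_duration = 0.5)
  lab <- matrix(0L, H, W); lab[5:7, 5:7] <- 1L; lab[10:12, 10:12] <- 2L
  rois <- structure(list(labels = lab,
                         rois = data.frame(id = 1:2, n_pixels = 9,
                                           x = c(0.55, 1.05), y = c(0.55, 1.05)),
                         pixel_size = 0.1), class = "roi_set")
  tx <- extract_traces(mv, rois, baseline_frames = 20L,
                       background = matrix(FALSE, H, W), footprint = lab > 0)
  # constant ROI: dF/F identically 0; doubling ROI: 0 then 1
  expect_equal(tx$dff[, 2], rep(0, fr))
  expect_equal(tx$dff[, 1], c(rep(0, 30), rep(1, 30)))
  # zero-baseline ROI is flagged and excluded
  st0 <- st; st0[, 10:12, 10:12] <- 0
  mv0 <- tirf_movie(st0, 0.1, 0.1, 25L, 0.5)
  tx0 <- extract_traces(mv0, rois, baseline_frames = 20L,
                        background = matrix(FALSE, H, W), footprint = lab > 0)
  expect_equal(tx0$excluded, 2L)
  expect_true(all(is.na(tx0$dff[, 2])))
})

test_that("threshold crossing selects responders by sign", {
  set.seed(8)
  base_sd <- 0.01
  noise <- matrix(rnorm(200 * 3, 0, base_sd), 200, 3)
  dff <- noise
  dff[, 1] <- dff[, 1] + c(rep(0, 99), rep(8 * base_sd, 101))   # rise
  dff[, 2] <- dff[, 2] - c(rep(0, 99), rep(8 * base_sd, 101))   # fall
  dff[150, 3] <- 3 * base_sd                                    # subthreshold
  det <- detect_responders(dff, baseline_window = c(1, 90), onset_frame = 95,
                           k_sd = 4)
  expect_equal(det$responder, c(TRUE, TRUE, FALSE))
  expect_equal(det$sign[1:2], c(1L, -1L))
  expect_error(detect_responders(dff, baseline_window = c(1, 3),
                                 onset_frame = 95), "5 frames")
})

test_that("monotone rises and falls classify as accumulation and loss", {
  fr <- 150; H <- 24; W <- 24
  base <- 100
  prof <- c(rep(0, 29), seq(0, 1, length.out = 11), rep(1, fr - 40))
  st <- array(base, dim = c(fr, H, W))
  for (f in 1:fr) {
    st[f, 6:8, 6:8] <- base * (1 + prof[f])        # monotone rise
    st[f, 16:18, 16:18] <- base * (1 - 0.5 * prof[f])  # monotone fall
  }
  mv <- tirf_movie(st, 0.1, 0.1, stimulus_onset_frame = 30L,
                   stimulus_duration = 0.5)
  lab <- matrix(0L, H, W); lab[6:8, 6:8] <- 1L; lab[16:18, 16:18] <- 2L
  rois <- structure(list(labels = lab,
                         rois = data.frame(id = 1:2, n_pixels = 9,
                                           x = c(0.65, 1.65), y = c(0.65, 1.65)),
                         pixel_size = 0.1), class = "roi_set")
  tx <- extract_traces(mv, rois, baseline_frames = 20L,
                       background = matrix(FALSE, H, W), footprint = lab >= 0)
  # noiseless baseline: use a tiny absolute threshold via per-roi sd + epsilon
  tx$dff <- tx$dff + matrix(rnorm(fr * 2, 0, 1e-4), fr, 2)
  ev <- classify_events(mv, rois, tx, window_s = 10, k_sd = 4)
  expect_equal(ev$class[order(ev$roi)], c("accumulation", "loss"))
})

test_that("the pipeline recovers planted events and is affine-invariant", {
  sim <- simulate_tirf_movie(movie_sim_config(seed = 21))
  ana <- analyze_movie(sim$movie, ribbon_image = sim$ribbon_image)
  sc <- match_events(ana$events, sim$truth)
  expect_gte(sc$recall, 0.8)   # crowded footprints can merge two hotspots
  expect_gte(sc$precision, 0.95)
  expect_true(sc$class_exact)
  # planted amplitudes are recovered from the traces within 10% at the
  # event centre (3x3 pixel ROI, 3-frame smoothing to tame shot noise)
  # well-separated events so each 3x3 patch sees a single hotspot
  hi <- simulate_tirf_movie(movie_sim_config(seed = 22, amp_sd = 25,
                                             n_fusion = 2, n_accumulation = 2,
                                             n_loss = 0, min_separation = 0.8))
  px <- hi$movie$pixel_size
  for (i in seq_len(nrow(hi$truth))) {
    r <- round(hi$truth$y[i] / px + 0.5); c <- round(hi$truth$x[i] / px + 0.5)
    lab <- matrix(0L, dim(hi$movie$stack)[2], dim(hi$movie$stack)[3])
    lab[(r - 1):(r + 1), (c - 1):(c + 1)] <- 1L
    # mean Gaussian weight over the 3x3 patch at the true sub-pixel offset
    yc <- ((r - 1):(r + 1) - 0.5) * px; xc <- ((c - 1):(c + 1) - 0.5) * px
    patch <- mean(exp(-outer((yc - hi$truth$y[i])^2, (xc - hi$truth$x[i])^2, "+") /
                        (2 * 0.15^2)))
    rois <- structure(list(labels = lab,
                           rois = data.frame(id = 1L, n_pixels = 9L,
                                             x = hi$truth$x[i], y = hi$truth$y[i]),
                           pixel_size = px), class = "roi_set")
    tx <- extract_traces(hi$movie, rois, baseline_frames = 20L,
                         background = matrix(FALSE, nrow(lab), ncol(lab)))
    sm <- stats::filter(tx$dff[, 1], rep(1 / 3, 3))
    # measured peak in counts over the local baseline (which includes any
    # overlapping ribbon punctum) against the planted peak amplitude
    amp_meas <- max(sm, na.rm = TRUE) * tx$f0[1] / patch
    expect_lt(abs(amp_meas - hi$truth$amplitude_counts[i]) /
                hi$truth$amplitude_counts[i], 0.1)
  }
  # affine rescaling of the whole movie leaves the classification unchanged
  sim2 <- sim
  sim2$movie$stack <- 2.5 * sim$movie$stack + 40
  ana2 <- analyze_movie(sim2$movie, ribbon_image = sim$ribbon_image)
  expect_equal(ana2$events$class, ana$events$class)
  expect_equal(ana2$events$x, ana$events$x, tolerance = 1e-9)
  expect_equal(ana2$events$peak_dff, ana$events$peak_dff, tolerance = 1e-9)
})

test_that("zero-event movies match the noise model and yield no responders", {
  cfg <- movie_sim_config(seed = 31, n_fusion = 0, n_accumulation = 0,
                          n_loss = 0)
  sim <- simulate_tirf_movie(cfg)
  expect_equal(nrow(sim$truth), 0)
  # per-pixel temporal SD inside the footprint ~ sqrt(gain^2 B + read^2)
  st <- sim$movie$stack
  base <- apply(st[1:20, , , drop = FALSE], c(2, 3), mean)
  inside <- base > 100
  flat <- matrix(st, nrow = dim(st)[1])
  sds <- apply(flat[, as.vector(inside)], 2, sd)
  theory <- sqrt(cfg$gain^2 * cfg$baseline + cfg$read_noise_sd^2)
  expect_lt(abs(mean(sds) - theory) / theory, 0.05)
  # no responders at any threshold from 3 SD up
  for (k in c(3, 4, 6)) {
    ana <- analyze_movie(sim$movie, k_sd = k)
    expect_equal(nrow(ana$events), 0)
  }
  # count conservation on a mixed configuration
  sim13 <- simulate_tirf_movie(movie_sim_config(seed = 32, n_fusion = 6,
                                                n_accumulation = 4, n_loss = 3))
  expect_equal(nrow(sim13$truth), 13)
  expect_equal(as.vector(table(sim13$truth$class)[c("fusion", "accumulation", "loss")]),
               c(6L, 4L, 3L))
})

test_that("false responders on pure noise decrease from k = 3 to k = 4", {
  # 100 seeded Gaussian-noise movies, fixed 3x3-tile ROI grid
  counts3 <- counts4 <- numeric(100)
  H <- 24
  lab <- matrix(0L, H, H)
  tile <- 1L
  for (r in 0:2) for (c in 0:2) {
    lab[(r * 8 + 1):(r * 8 + 8), (c * 8 + 1):(c * 8 + 8)] <- tile
    tile <- tile + 1L
  }
  rois <- structure(list(labels = lab,
                         rois = data.frame(id = 1:9, n_pixels = 64,
                                           x = 0, y = 0),
                         pixel_size = 0.1), class = "roi_set")
  for (s in 1:100) {
    set.seed(7000 + s)
    st <- array(100 + rnorm(200 * H * H, 0, 5), dim = c(200, H, H))
    mv <- tirf_movie(st, 0.1, 0.1, stimulus_onset_frame = 21L,
                     stimulus_duration = 0.5)
    tx <- extract_traces(mv, rois, baseline_frames = 20L,
                         background = matrix(FALSE, H, H),
                         footprint = lab > 0)
    d3 <- detect_responders(tx$dff, tx$baseline_window, 21L, k_sd = 3)
    d4 <- detect_responders(tx$dff, tx$baseline_window, 21L, k_sd = 4)
    counts3[s] <- sum(d3$responder); counts4[s] <- sum(d4$responder)
  }
  expect_lt(mean(counts4), mean(counts3))
})
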