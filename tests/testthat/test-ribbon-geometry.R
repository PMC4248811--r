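test_that("ribbon puncta are localised to within a pixel", {
  px <- 0.1
  rs <- (seq_len(40) - 0.5) * px; cs <- (seq_len(40) - 0.5) * px
  img <- 500 * exp(-(outer((rs - 1.0)^2, (cs - 1.0)^2, "+")) / (2 * 0.2^2))
  rib <- detect_ribbons(img, pixel_size = px)
  expect_equal(nrow(rib$centers), 1)
  expect_lt(abs(rib$centers$x - 1.0), px)
  expect_lt(abs(rib$centers$y - 1.0), px)
  expect_gt(rib$centers$radius, 0)

  # two identical puncta: deterministic raster order (topmost row first)
  img2 <- img + 500 * exp(-(outer((rs - 3.0)^2, (cs - 2.0)^2, "+")) / (2 * 0.2^2))
  rib2 <- detect_ribbons(img2, pixel_size = px)
  expect_equal(nrow(rib2$centers), 2)
  expect_lt(rib2$centers$y[1], rib2$centers$y[2])
  # featureless image: empty map
  expect_equal(nrow(detect_ribbons(matrix(1, 30, 30))$centers), 0)
})

test_that("nearest-ribbon distances follow the tie-break and identity rules", {
  rib <- structure(list(centers = data.frame(id = 1:2, x = c(0, 2), y = c(0, 0),
                                             intensity = 1, radius = 0.2)),
                   class = "ribbon_map")
  r <- nearest_ribbon_distance(c(0.4, 0), rib)
  expect_equal(r$distance, 0.4)
  expect_equal(r$ribbon, 1)
  expect_equal(nearest_ribbon_distance(c(2, 0), rib)$distance, 0)
  # equidistant: lowest index wins
  expect_equal(nearest_ribbon_distance(c(1, 0), rib)$ribbon, 1)
  empty <- structure(list(centers = data.frame()), class = "ribbon_map")
  expect_error(nearest_ribbon_distance(c(0, 0), empty), "empty")
})

test_that("distances are invariant under rigid motions of all coordinates", {
  set.seed(9)
  ribs <- data.frame(id = 1:4, x = runif(4, 0, 5), y = runif(4, 0, 5),
                     intensity = 1, radius = 0.2)
  pts <- cbind(runif(25, 0, 5), runif(25, 0, 5))
  rot <- function(p, th, d) cbind(cos(th) * p[, 1] - sin(th) * p[, 2] + d[1],
                                  sin(th) * p[, 1] + cos(th) * p[, 2] + d[2])
  th <- 0.83; d <- c(2.7, -1.1)
  rib2 <- ribs; rib2[, c("x", "y")] <- rot(as.matrix(ribs[, c("x", "y")]), th, d)
  m1 <- structure(list(centers = ribs), class = "ribbon_map")
  m2 <- structure(list(centers = rib2), class = "ribbon_map")
  p2 <- rot(pts, th, d)
  for (i in seq_len(nrow(pts))) {
    d1 <- nearest_ribbon_distance(pts[i, ], m1)$distance
    d2 <- nearest_ribbon_distance(p2[i, ], m2)$distance
    expect_lt(abs(d1 - d2), 1e-9)
  }
})

test_that("distance histograms report the correct mode bin", {
  h <- distance_distribution(rep(0.4, 12))
  expect_equal(sum(h$counts), 12)
  expect_equal(sum(h$counts > 0), 1)
  expect_true(h$breaks[h$mode_bin] <= 0.4 && 0.4 <= h$breaks[h$mode_bin + 1])
  # a single zero falls in the first bin
  expect_equal(distance_distribution(0)$mode_bin, 1)
  # ring of planted events at 0.8 um with 0.05 um jitter
  set.seed(13)
  d8 <- abs(rnorm(500, 0.8, 0.05))
  h8 <- distance_distribution(d8)
  expect_lt(abs(h8$mode_center - 0.8), 0.1)
  # two rings at 0.4 and 0.8 separate into distinct modes
  d4 <- abs(rnorm(500, 0.4, 0.05))
  h4 <- distance_distribution(d4)
  expect_lt(abs(h4$mode_center - 0.4), 0.1)
  expect_true(h8$mode_center > h4$mode_center)
  expect_error(distance_distribution(numeric(0)), "at least one")
})

test_that("Pearson colocalisation behaves like a correlation", {
  set.seed(19)
  a <- matrix(rnorm(100 * 100, 50, 10), 100, 100)
  expect_equal(pearson_coloc(a, a), 1)
  expect_equal(pearson_coloc(a, -a + 7), -1)
  b <- matrix(rnorm(100 * 100, 50, 10), 100, 100)
  expect_lt(abs(pearson_coloc(a, b)), 0.05)
  # invariance under positive affine rescaling
  expect_equal(pearson_coloc(a, b), pearson_coloc(3 * a + 2, b), tolerance = 1e-12)
  expect_error(pearson_coloc(a, b[1:50, 1:50]), "shape")
  expect_error(pearson_coloc(a, matrix(5, 100, 100)), "constant")
})
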