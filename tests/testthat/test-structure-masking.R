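test_that("gradient orientation recovers step-edge geometry", {
  h <- matrix(0, 20, 20)
  h[11:20, ] <- 255                       # horizontal edge, vertical change
  fh <- gradient_orientation(h)
  expect_true(all(abs(fh$phi[10:11, 5:15] - 90) < 1e-9))
  expect_gt(min(fh$magnitude[10:11, 5:15]), 0)

  v <- matrix(0, 20, 20)
  v[, 11:20] <- 255                       # vertical edge, horizontal change
  fv <- gradient_orientation(v)
  expect_true(all(abs(fv$phi[5:15, 10:11]) < 1e-9))

  flat <- gradient_orientation(matrix(42, 10, 10))
  expect_equal(flat$magnitude, matrix(0, 10, 10))
  q <- quantize_orientation(flat, 12L, mag_threshold = 2)
  expect_true(all(is.na(q$quantized)))
})

test_that("orientation quantization uses half-open 15-degree bins", {
  phi <- matrix(c(0, 14.999, 15, 90, 179.9, 45), 2, 3)
  f <- quantize_orientation(field_from_phi(phi), 12L, mag_threshold = 2)
  expect_equal(as.vector(f$quantized), c(0L, 0L, 1L, 6L, 11L, 3L))
  # sub-threshold magnitude is excluded
  f2 <- quantize_orientation(field_from_phi(phi, magnitude = 1), 12L, 2)
  expect_true(all(is.na(f2$quantized)))
  expect_error(quantize_orientation(field_from_phi(phi), 1L), "at least 2")
})

test_that("pattern complexity counts occupied orientation bins", {
  # flat image: every pixel gated out, PC = 0
  flat <- quantize_orientation(gradient_orientation(matrix(9, 12, 12)))
  expect_equal(pattern_complexity(flat), matrix(0L, 12, 12))

  # single ideal step edge: one orientation in edge-band regions
  h <- matrix(0, 20, 20)
  h[11:20, ] <- 255
  f <- quantize_orientation(gradient_orientation(h))
  pc <- pattern_complexity(f)
  expect_true(all(pc[9:12, 5:15] == 1))
  expect_true(all(pc[1:5, ] == 0))

  # a 5x5 region occupying all 12 bins yields PC = 12 at its center
  phi <- matrix(7.5, 9, 9)  # bin 0 background
  phi[3:7, 3:7] <- matrix(c((0:11) * 15 + 7.5, rep(7.5, 13)), 5, 5)
  fa <- quantize_orientation(field_from_phi(phi), 12L, 2)
  expect_equal(pattern_complexity(fa)[5, 5], 12L)

  expect_error(pattern_complexity(f, region_window = 4L), "odd")
  expect_error(pattern_complexity(gradient_orientation(h)), "quantized")
})

test_that("pipeline pattern complexity equals the brute-force recount", {
  for (seed in c(1, 5)) {
    for (bins in c(4L, 12L)) {
      img <- generate_fixture(fixture_spec("random_texture", c(16L, 16L),
                                           seed = seed))
      y <- rgb_to_ycbcr(img)$y
      f <- quantize_orientation(gradient_orientation(y), bins, 2)
      expect_equal(pattern_complexity(f, 5L),
                   matrix(as.integer(pc_bruteforce(f, 5L)), 16, 16))
    }
  }
})

test_that("pattern masking is zero at PC 0 and strictly increasing", {
  pm <- function(v) pattern_masking(matrix(v, 5, 5))[1, 1]
  expect_equal(pm(0), 0)
  expect_equal(pm(1), 0.8 / 1.01)
  expect_equal(pm(12), 0.8 * 12^2.7 / (144 + 0.01))
  grid <- vapply(0:12, pm, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("directional gradients respond to edges, not offsets", {
  expect_equal(directional_gradients(matrix(50, 10, 10)),
               matrix(0, 10, 10))
  h <- matrix(0, 20, 20)
  h[11:20, ] <- 255
  g <- directional_gradients(h)
  expect_gt(g[10, 10], 0)
  expect_equal(g[3, 10], 0)
  # zero-sum kernels: constant offsets vanish
  set.seed(4)
  p <- matrix(runif(100, 0, 200), 10, 10)
  expect_equal(directional_gradients(p + 55), directional_gradients(p),
               tolerance = 1e-9)
  ks <- directional_kernels()
  expect_length(ks, 4L)
  expect_true(all(vapply(ks, sum, numeric(1)) == 0))
})

test_that("edge weight dips on the edge line and recovers with distance", {
  expect_equal(edge_weight(matrix(99, 16, 16)), matrix(1, 16, 16))
  v <- matrix(0, 32, 32)
  v[, 17:32] <- 255
  edges <- canny_edges(v)
  # the detected edge hugs the known step line
  expect_true(all(which(apply(edges, 2, any)) %in% 14:19))
  expect_true(any(edges))

  w <- edge_weight(v)
  expect_true(all(w >= 0.1 & w <= 1))
  # oracle: explicit loop smoothing of the known edge mask
  k <- outer(exp(-(-3:3)^2 / (2 * 0.8^2)), exp(-(-3:3)^2 / (2 * 0.8^2)))
  k <- k / sum(k)
  w0 <- ifelse(edges, 0.1, 1)
  w0p <- w0[c(rep(1, 3), 1:32, rep(32, 3)), c(rep(1, 3), 1:32, rep(32, 3))]
  expected <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    expected[i, j] <- sum(k * w0p[i:(i + 6), j:(j + 6)])
  }
  expect_equal(w, pmin(pmax(expected, 0.1), 1), tolerance = 1e-12)

  # monotone recovery away from the edge, weight 1 far from it
  profile <- w[16, ]
  expect_equal(profile[1], 1)
  expect_equal(profile[32], 1)
  expect_lt(min(profile), 1)
  left <- profile[1:which.min(profile)]
  expect_true(all(diff(left) < 1e-9))
  expect_error(edge_weight(v, low = 0.5, high = 0.2), "low < high")
})

test_that("edge protection scales gradients by channel gain and weight", {
  g <- matrix(10, 6, 6)
  w1 <- matrix(1, 6, 6)
  expect_equal(edge_protection(matrix(0, 6, 6), w1, "Y"),
               threshold_map(matrix(0, 6, 6), "EP", "Y"))
  expect_equal(edge_protection(g, w1, "Y")[1, 1], 1.17)
  expect_equal(edge_protection(g, w1, "Cb")[1, 1] /
                 edge_protection(g, w1, "Y")[1, 1], 0.65 / 0.117)
  expect_error(edge_protection(g, w1, "L"), "unknown channel")
  # equally strong gradient is protected (smaller EP) at an edge pixel
  w_edge <- matrix(0.1, 6, 6)
  expect_lt(edge_protection(g, w_edge, "Y")[3, 3],
            edge_protection(g, w1, "Y")[3, 3])
})
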