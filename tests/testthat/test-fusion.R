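test_that("masking factors combine by product and respect labels", {
  d <- c(5L, 5L)
  cm <- threshold_map(matrix(3.384, 5, 5), "CM", "Y")
  pm <- threshold_map(matrix(0.7921, 5, 5), "PM", "Y")
  ep <- threshold_map(matrix(1.17, 5, 5), "EP", "Y")
  vm <- visual_masking(cm, pm, ep)
  expect_equal(vm[1, 1], 3.384 * 0.7921 * 1.17)
  expect_equal(visual_masking(cm, pm,
                              threshold_map(matrix(0, 5, 5), "EP", "Y")),
               threshold_map(matrix(0, 5, 5), "VM", "Y"))
  expect_error(visual_masking(cm, pm,
                              threshold_map(matrix(1, 5, 5), "EP", "Cb")),
               "different channel")

  vms_id <- modulate_masking(vm, matrix(1, 5, 5))
  expect_equal(as.vector(vms_id), as.vector(vm))
  expect_identical(attr(vms_id, "kind"), "VMS")
  expect_equal(modulate_masking(vm, matrix(0, 5, 5))[3, 3], 0)
  expect_equal(modulate_masking(threshold_map(matrix(4, 5, 5), "VM", "Y"),
                                matrix(0.75, 5, 5))[1, 1], 3)
})

test_that("NAMM fusion discounts the overlap and is sandwiched", {
  la <- threshold_map(matrix(20, 5, 5), "LA", "Y")
  expect_equal(namm_fuse(la, threshold_map(matrix(0, 5, 5), "VMS", "Y")),
               threshold_map(matrix(20, 5, 5), "JND_S", "Y"))
  expect_equal(namm_fuse(la, threshold_map(matrix(10, 5, 5), "VMS",
                                           "Y"))[1, 1], 27)
  t0 <- threshold_map(matrix(7, 5, 5), "VMS", "Y")
  expect_equal(namm_fuse(threshold_map(matrix(7, 5, 5), "LA", "Y"),
                         t0)[1, 1], 1.7 * 7)
  expect_error(namm_fuse(la, t0, alpha = 1), "\\[0, 1\\)")

  set.seed(21)
  for (i in 1:5) {
    la_m <- matrix(runif(100, 0, 25), 10, 10)
    vm_m <- matrix(runif(100, 0, 25), 10, 10)
    j <- unclass(namm_fuse(threshold_map(la_m, "LA", "Y"),
                           threshold_map(vm_m, "VMS", "Y")))
    expect_true(all(j >= pmax(la_m, vm_m) - 1e-12))
    expect_true(all(j <= la_m + vm_m + 1e-12))
    # monotone: larger masking never lowers the fused threshold
    j2 <- unclass(namm_fuse(threshold_map(la_m, "LA", "Y"),
                            threshold_map(vm_m * 1.2, "VMS", "Y")))
    expect_true(all(j2 >= j - 1e-12))
  }
})

test_that("sensitivity parameters are squared shares of the distance ratio", {
  expect_equal(sensitivity_params(c(1, 1, 1)),
               c(Y = 1, Cb = 1, Cr = 1) / 3)
  # direct arithmetic oracle for the default ratio
  d2 <- c(1, 0.432, 0.501)^2
  expect_equal(unname(sensitivity_params()), d2 / sum(d2))
  set.seed(2)
  for (i in 1:5) {
    s <- sensitivity_params(runif(3, 0.1, 2))
    expect_equal(sum(s), 1)
  }
  expect_error(sensitivity_params(c(1, 0, 1)), "positive")
})

test_that("color-sensitivity weights invert sensitivities and sum to 3", {
  expect_equal(cs_weights(c(1, 1, 1) / 3), c(Y = 1, Cb = 1, Cr = 1))
  # reciprocal-and-rescale oracle on the published sensitivity triple
  s <- c(0.695, 0.130, 0.175)
  expect_equal(unname(cs_weights(s)), 3 * (1 / s) / sum(1 / s))
  expect_equal(round(cs_weights(s), 3),
               c(Y = 0.291, Cb = 1.554, Cr = 1.155))
  set.seed(6)
  for (i in 1:5) {
    raw <- runif(3, 0.05, 0.9)
    w <- cs_weights(raw / sum(raw) / 1.0001)
    expect_equal(sum(w), 3)
    # ordering is inverse: most sensitive channel gets smallest weight
    expect_equal(order(w), rev(order(raw / sum(raw) / 1.0001)))
  }
  expect_error(cs_weights(c(0.5, 0.5, 0)), "\\(0, 1\\)")
})

test_that("apply_cs rescales a labelled map by its channel weight", {
  w <- c(Y = 0.291, Cb = 1.554, Cr = 1.155)
  ym <- threshold_map(matrix(3, 5, 5), "JND_S", "Y")
  expect_equal(apply_cs(ym, w)[1, 1], 0.873)
  cbm <- threshold_map(matrix(2, 5, 5), "JND_S", "Cb")
  expect_equal(unclass(apply_cs(cbm, w))[2, 2], 2 * 1.554)
  expect_equal(unclass(apply_cs(ym, c(Y = 1, Cb = 1, Cr = 1))),
               unclass(ym), ignore_attr = TRUE)
  expect_error(apply_cs(threshold_map(matrix(1, 5, 5), "JND_S"), w),
               "channel label")
})

test_that("flat mid-gray image reduces to weighted luminance adaptation", {
  img <- generate_fixture(fixture_spec("flat", c(32L, 32L), level = 128))
  res <- csjnd_compute(img)
  la128 <- 3 * (128 - 127) / 128 + 3
  expect_equal(mval(res$components$Y$vm), matrix(0, 32, 32))
  expect_equal(mval(res$components$Y$jnd), matrix(la128, 32, 32))
  expect_equal(mval(res$maps$Y),
               matrix(res$weights[["Y"]] * la128, 32, 32))
  expect_equal(mval(res$maps$Cb),
               matrix(res$weights[["Cb"]] * la128, 32, 32))
})

test_that("model variants obey their algebraic relations", {
  img <- generate_fixture(fixture_spec("random_texture", c(32L, 32L),
                                       seed = 5))
  res_b <- csjnd_compute(img, csjnd_config(variant = "B"))
  res_s <- csjnd_compute(img, csjnd_config(variant = "S"))
  res_c <- csjnd_compute(img, csjnd_config(variant = "C"))
  res_f <- csjnd_compute(img, csjnd_config(variant = "full"))
  w <- res_f$weights
  for (ch in c("Y", "Cb", "Cr")) {
    # full = CS o (S variant); C = CS o (B variant)
    expect_equal(mval(res_f$maps[[ch]]),
                 w[[ch]] * mval(res_s$maps[[ch]]), tolerance = 1e-12)
    expect_equal(mval(res_c$maps[[ch]]),
                 w[[ch]] * mval(res_b$maps[[ch]]), tolerance = 1e-12)
  }
  # with unit weights the full variant collapses onto the S variant
  res_f1 <- csjnd_compute(img, csjnd_config(
    variant = "full",
    fusion = list(d_ratio = c(Y = 1, Cb = 1, Cr = 1),
                  cs_from = "unrounded")))
  expect_equal(lapply(res_f1$maps, mval), lapply(res_s$maps, mval),
               tolerance = 1e-12)
  # B equals S when saliency is disabled (degenerate modulation is 1)
  res_s_off <- csjnd_compute(img, csjnd_config(
    variant = "S", saliency = list(enabled = FALSE)))
  expect_equal(lapply(res_s_off$maps, mval),
               lapply(res_b$maps, mval), tolerance = 1e-12)
})
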