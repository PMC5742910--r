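test_that("invalid map configurations are rejected", {
  expect_error(map_gen_config(image_size = c(0, 10)), "positive")
  expect_error(map_gen_config(activation_fraction = -0.1), "fractions")
  expect_error(map_gen_config(activation_fraction = 0.7,
                              artifact_fraction = 0.5), "fractions")
  expect_error(map_gen_config(intensity_heterogeneity = -1), ">= 0")
  expect_error(map_gen_config(noise_amplitude = 30), "noise_amplitude")
})

test_that("identical config and seed give bit-identical images", {
  cfg <- small_map_config(seed = 42)
  a <- generate_component_map(cfg)
  b <- generate_component_map(cfg)
  expect_identical(unclass(a)[, , ], unclass(b)[, , ])
  expect_identical(attr(a, "true_labels"), attr(b, "true_labels"))
  c <- generate_component_map(small_map_config(seed = 43))
  expect_false(identical(unclass(a)[, , ], unclass(c)[, , ]))
})

test_that("fractions control the class composition", {
  cfg <- small_map_config(seed = 7, activation_fraction = 0,
                          artifact_fraction = 0)
  img <- generate_component_map(cfg)
  seg <- segment_colors(img)
  expect_equal(unname(seg$class_counts[["blue"]]), 0L)
  expect_equal(unname(seg$class_counts[["red"]]), 0L)
  expect_true(seg$class_counts[["grey"]] > 0)

  cfg2 <- small_map_config(seed = 7, activation_fraction = 0.1,
                           artifact_fraction = 0.05)
  lab2 <- attr(generate_component_map(cfg2), "true_labels")
  n_brain <- sum(lab2 != 1L)
  expect_equal(sum(lab2 == 4L), round(0.1 * n_brain))
  expect_equal(sum(lab2 == 5L), round(0.05 * n_brain))
})

test_that("activation sits in the occipital third, artifacts elsewhere", {
  img <- generate_component_map(small_map_config(seed = 3))
  lab <- attr(img, "true_labels")
  h <- nrow(lab)
  blue_rows <- row(lab)[lab == 4L]
  red_rows <- row(lab)[lab == 5L]
  expect_true(all(blue_rows > 2 * h / 3))
  expect_true(all(red_rows <= 2 * h / 3))
})

test_that("zero heterogeneity and noise collapse entropy to zero", {
  cfg <- small_map_config(seed = 5, intensity_heterogeneity = 0,
                          noise_amplitude = 0, activation_fraction = 0,
                          artifact_fraction = 0)
  b <- image_ben(generate_component_map(cfg))
  expect_equal(b$entropy_bits, 0)
  # with activation present a second intensity bin appears
  cfg2 <- small_map_config(seed = 5, intensity_heterogeneity = 0,
                           noise_amplitude = 0)
  expect_gt(image_ben(generate_component_map(cfg2))$entropy_bits, 0)
})

test_that("with noise disabled every pixel sits on its intended class", {
  for (seed in 1:5) {
    cfg <- small_map_config(seed = seed, noise_amplitude = 0)
    img <- generate_component_map(cfg)
    seg <- segment_colors(img)
    expect_identical(unname(seg$labels[, ]), attr(img, "true_labels"))
  }
})

test_that("sub-margin noise never flips the intended class", {
  for (seed in 1:10) {
    cfg <- small_map_config(seed = seed, noise_amplitude = 8,
                            intensity_heterogeneity = 25)
    img <- generate_component_map(cfg)
    seg <- segment_colors(img)
    expect_identical(unname(seg$labels[, ]), attr(img, "true_labels"))
  }
})

test_that("mean BEN is monotone non-decreasing in the dispersion parameter", {
  cfg <- map_gen_config(seed = 31)
  grid <- c(0, 2, 5, 10, 20, 40, 60)
  vals <- vapply(grid, brainentropy:::mean_ben_at, numeric(1),
                 config = cfg, n_maps = 12)
  expect_true(all(diff(vals) > -0.01))
  expect_gt(vals[length(vals)] - vals[1], 0.3)
})

test_that("calibration hits its target and orders with the target", {
  cfg <- map_gen_config(seed = 19)
  d_star <- calibrate_heterogeneity(0.64, cfg, n_maps = 25)
  d_prime <- calibrate_heterogeneity(0.56, cfg, n_maps = 25)
  expect_lt(d_prime, d_star)
  # verify on maps not used during the search
  fresh <- map_gen_config(seed = 7919)
  fresh$intensity_heterogeneity <- d_star
  bens <- vapply(1:30, function(i) {
    fresh$seed <- 7919 + i
    image_ben(generate_component_map(fresh))$ben
  }, numeric(1))
  expect_lt(abs(mean(bens) - 0.64), 0.02)

  expect_equal(calibrate_heterogeneity(0, cfg), 0)
  expect_error(calibrate_heterogeneity(0.99, cfg, n_maps = 5),
               "achievable range")
  expect_error(calibrate_heterogeneity(1.2, cfg), "target_ben")
})

test_that("the calibration curve inverts accurately", {
  cfg <- map_gen_config(seed = 23)
  curve <- calibration_curve(cfg, n_maps = 6)
  expect_false(is.unsorted(curve$ben))
  for (target in c(0.45, 0.56, 0.64, 0.75)) {
    h <- heterogeneity_for_ben(target, curve)
    m <- brainentropy:::mean_ben_at(h, cfg, n_maps = 15)
    expect_lt(abs(m - target), 0.025)
  }
})
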