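test_that("pure reference colours are classified as themselves", {
  img <- image_from_classes(matrix(c("white", "blue", "grey", "red"), 2, 2))
  seg <- segment_colors(img)
  cls <- attr(seg$labels, "classes")
  expect_identical(matrix(cls[seg$labels], 2, 2),
                   matrix(c("white", "blue", "grey", "red"), 2, 2))
  expect_identical(
    seg$class_counts,
    c(background = 0L, white = 1L, grey = 1L, blue = 1L, red = 1L))
  expect_identical(seg$retained_mask,
                   matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
})

test_that("an all-black image is pure background with nothing retained", {
  img <- component_image(array(0, dim = c(3, 4, 3)))
  seg <- segment_colors(img)
  expect_true(all(attr(seg$labels, "classes")[seg$labels] == "background"))
  expect_false(any(seg$retained_mask))
  expect_true(all(is.na(seg$retained_gray)))
  expect_error(intensity_histogram(seg$retained_gray), "no retained pixels")
})

test_that("labels partition every pixel and counts are consistent", {
  for (seed in 1:5) {
    set.seed(seed)
    img <- random_image(7, 9)
    seg <- segment_colors(img)
    expect_equal(sum(seg$class_counts), 7 * 9)
    expect_true(all(seg$labels %in% 1:5))
    expect_equal(as.integer(table(factor(seg$labels, levels = 1:5))),
                 as.integer(seg$class_counts))
    cls <- attr(seg$labels, "classes")[seg$labels]
    expect_identical(seg$retained_mask,
                     matrix(cls %in% c("white", "grey", "blue"), 7, 9))
  }
})

test_that("segmentation matches the brute-force nearest-colour oracle", {
  profiles <- default_color_profiles()
  for (seed in 1:8) {
    set.seed(seed)
    h <- sample(1:8, 1); w <- sample(1:8, 1)
    img <- random_image(h, w)
    seg <- segment_colors(img, profiles)
    expect_identical(as.integer(seg$labels),
                     as.integer(nearest_color_oracle(img, profiles)))
    expect_identical(dim(seg$labels), c(h, w))
  }
})

test_that("distance ties break by the canonical class order", {
  # (64,64,64) is equidistant from background and grey: background wins
  img <- gray_image(64L)
  seg <- segment_colors(img)
  expect_equal(attr(seg$labels, "classes")[seg$labels[1, 1]], "background")
})

test_that("classification is permutation-equivariant across pixel positions", {
  set.seed(42)
  img <- random_image(6, 6)
  seg <- segment_colors(img)
  perm <- sample(36)
  arr <- unclass(img)
  permuted <- array(c(matrix(arr[, , 1], 36)[perm],
                      matrix(arr[, , 2], 36)[perm],
                      matrix(arr[, , 3], 36)[perm]), dim = c(6, 6, 3))
  seg_p <- segment_colors(component_image(permuted))
  expect_identical(as.integer(seg_p$labels), as.integer(seg$labels)[perm])
  expect_identical(seg_p$class_counts, seg$class_counts)
})

test_that("red artifact removal excludes red pixels and is idempotent", {
  img <- image_from_classes(matrix(c("white", "red", "grey", "red",
                                     "blue", "white"), 2, 3))
  seg <- segment_colors(img)
  expect_false(any(seg$retained_mask[seg$labels == 5L]))  # by construction
  cleaned <- remove_red_artifacts(seg)
  expect_identical(cleaned$retained_mask, seg$retained_mask)
  expect_identical(cleaned$class_counts, seg$class_counts)  # labels keep red
  twice <- remove_red_artifacts(cleaned)
  expect_identical(twice, cleaned)

  # with zero red pixels the operation is the identity
  img2 <- image_from_classes(matrix(c("white", "grey"), 1, 2))
  seg2 <- segment_colors(img2)
  expect_identical(remove_red_artifacts(seg2), seg2)
})

test_that("grayscale conversion follows BT.601 luminance on retained pixels", {
  img <- image_from_classes(matrix(c("white", "blue", "grey", "red"), 2, 2))
  mask <- matrix(TRUE, 2, 2)
  g <- to_grayscale(img, mask)
  expect_equal(g[1, 1], 255L)                       # white
  expect_equal(g[2, 1], 29L)                        # blue: round(0.114 * 255)
  expect_equal(g[1, 2], 128L)                       # grey
  expect_equal(g[2, 2], round(0.299 * 255))         # red
  g2 <- to_grayscale(img, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(is.na(g2), matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_error(to_grayscale(img, matrix(TRUE, 3, 2)), "dimensions")
})

test_that("invalid colour profiles are rejected", {
  p <- default_color_profiles()
  dup <- p; dup$R[2] <- 0; dup$G[2] <- 0; dup$B[2] <- 0   # white == background
  expect_error(segment_colors(gray_image(100L), dup), "duplicate")
  expect_error(validate_color_profiles(p[-1, ]), "five classes")
  bad <- p; bad$R[1] <- 300
  expect_error(validate_color_profiles(bad), "\\[0, 255\\]")
})

test_that("custom profiles reorder to canonical order and drive segmentation", {
  p <- default_color_profiles()[c(3, 1, 5, 2, 4), ]
  v <- validate_color_profiles(p)
  expect_identical(v$class, color_classes())
  img <- image_from_classes(matrix("blue", 2, 2))
  expect_equal(unname(segment_colors(img, p)$class_counts[["blue"]]), 4L)
})
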