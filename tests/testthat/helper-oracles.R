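# Independent oracles and tiny fixture builders used across the suite.

# Shannon entropy by direct summation over the multiset of intensities.
entropy_oracle <- function(intensities) {
  v <- as.vector(intensities)
  v <- v[!is.na(v)]
  n <- length(v)
  H <- 0
  for (u in unique(v)) {
    p <- sum(v == u) / n
    H <- H - p * log2(p)
  }
  H
}

# Per-pixel nearest-reference-colour scan (explicit double loop).
nearest_color_oracle <- function(image, profiles) {
  ref <- as.matrix(profiles[, c("R", "G", "B")])
  d <- dim(image)
  out <- matrix(NA_integer_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      px <- as.numeric(image[i, j, ])
      dist <- sqrt(rowSums(sweep(ref, 2, px)^2))
      out[i, j] <- which(dist == min(dist))[1]   # first = canonical order
    }
  }
  out
}

# Pearson chi-squared from first principles (expected counts from margins).
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Mann-Whitney U as an exhaustive pair count: x_i above y_j plus half-ties.
u_count_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Build a component image from a character matrix of class names rendered at
# the reference colours.
image_from_classes <- function(classes,
                               profiles = default_color_profiles()) {
  idx <- match(classes, profiles$class)
  stopifnot(!anyNA(idx))
  d <- dim(classes)
  arr <- array(0, dim = c(d, 3L))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(profiles[[c("R", "G", "B")[ch]]][idx], d[1], d[2])
  }
  component_image(arr)
}

# Achromatic image with the given integer gray levels (all pixels grey/white
# class for levels in [70, 255]).
gray_image <- function(levels, ncol = length(levels)) {
  g <- matrix(levels, ncol = ncol)
  component_image(array(rep(g, 3L), dim = c(dim(g), 3L)))
}

# Random small RGB image for oracle-equivalence checks.
random_image <- function(h, w) {
  component_image(array(sample(0:255, h * w * 3, replace = TRUE),
                        dim = c(h, w, 3L)))
}

small_map_config <- function(seed, ...) {
  map_gen_config(image_size = c(32L, 32L), seed = seed, ...)
}
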