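#' 256-bin intensity histogram of retained pixels
#'
#' Tallies retained grayscale intensities (integers 0-255) into 256 bins and
#' normalises by the total retained pixel count to obtain the probability
#' function p(i) used by the entropy calculation.
#'
#' @param retained_gray integer matrix or vector of grayscale intensities;
#'   `NA` entries (non-retained pixels) are ignored.
#' @return an object of class `intensity_histogram`: list with `counts`
#'   (integer, length 256, bin i holds intensity i-1), `p` (probabilities),
#'   and `n` (retained pixel count).
#' @examples
#' h <- intensity_histogram(c(0, 0, 128, 255))
#' h$p[c(1, 129, 256)]
#' @export
intensity_histogram <- function(retained_gray) {
  v <- as.vector(retained_gray)
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no retained pixels: segmentation produced an empty image")
  }
  if (any(v < 0 | v > 255) || any(v != round(v))) {
    stop("intensities must be integers in [0, 255]")
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, p = counts / length(v), n = length(v)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("<intensity_histogram>", x$n, "pixels,",
      sum(x$counts > 0), "occupied bins\n")
  invisible(x)
}

#' Shannon entropy of an intensity histogram
#'
#' Computes \eqn{H = -\sum_i p_i \log_2 p_i} over the occupied bins, with the
#' convention \eqn{0 \log_2 0 = 0}. For a 256-bin histogram the result lies in
#' `[0, 8]` bits: 0 when all pixels share one intensity, 8 for an exactly
#' uniform distribution.
#'
#' @param h an [intensity_histogram()], or a numeric vector of counts or
#'   probabilities.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))   # 1.5 bits
#' @export
shannon_entropy <- function(h) {
  p <- if (inherits(h, "intensity_histogram")) h$p else {
    x <- as.numeric(h)
    if (any(!is.finite(x)) || any(x < 0) || sum(x) <= 0) {
      stop("histogram must be non-negative with positive total")
    }
    x / sum(x)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalise entropy to the unit interval
#'
#' Divides entropy in bits by the 256-level maximum \eqn{\log_2 256 = 8}, so
#' that BEN lies in `[0, 1]` regardless of image size.
#'
#' @param entropy_bits entropy in bits, in `[0, 8]`.
#' @return normalised entropy (BEN) in `[0, 1]`.
#' @export
normalize_ben <- function(entropy_bits) {
  if (any(!is.finite(entropy_bits)) || any(entropy_bits < 0) ||
      any(entropy_bits > 8)) {
    stop("entropy_bits must lie in [0, 8]")
  }
  entropy_bits / 8
}

#' Brain entropy of one component image
#'
#' Runs the full per-image chain: colour segmentation, red-artifact removal,
#' grayscale conversion, 256-bin histogram, Shannon entropy, normalisation.
#'
#' @param image a [component_image()].
#' @param profiles colour profiles (see [default_color_profiles()]).
#' @return an object of class `ben_result`: list with `entropy_bits`, `ben`
#'   (normalised to `[0, 1]`), and `n_pixels` (retained count).
#' @export
image_ben <- function(image, profiles = default_color_profiles()) {
  seg <- remove_red_artifacts(segment_colors(image, profiles))
  h <- intensity_histogram(seg$retained_gray)
  bits <- shannon_entropy(h)
  structure(list(entropy_bits = bits, ben = normalize_ben(bits),
                 n_pixels = h$n),
            class = "ben_result")
}

#' @export
print.ben_result <- function(x, ...) {
  cat(sprintf("<ben_result> %.4f bits, BEN = %.4f (%d pixels)\n",
              x$entropy_bits, x$ben, x$n_pixels))
  invisible(x)
}

#' Subject-level brain entropy
#'
#' Computes BEN for each of a subject's component images (two closely matched
#' sequential images by convention) and aggregates by the arithmetic mean. A
#' subject whose images yield no retained pixels anywhere (no meaningful
#' activation detected) is flagged excluded rather than raising an error,
#' mirroring how such participants are dropped from group analyses.
#'
#' @param images list of [component_image()] objects for one subject.
#' @param subject_id identifier (defaults to the first image's).
#' @param profiles colour profiles.
#' @param images_per_subject expected number of images (default 2).
#' @return an object of class `subject_ben`: list with `subject_id`,
#'   `image_bens`, `image_bits`, `ben` (mean of `image_bens`, `NA` if
#'   excluded), and `excluded` (logical).
#' @export
subject_ben <- function(images, subject_id = NULL,
                        profiles = default_color_profiles(),
                        images_per_subject = 2L) {
  if (!is.list(images) || length(images) != images_per_subject) {
    stop("expected exactly ", images_per_subject, " images for the subject")
  }
  if (is.null(subject_id)) subject_id <- attr(images[[1]], "subject_id")
  res <- lapply(images, function(img) {
    tryCatch(image_ben(img, profiles), error = function(e) NULL)
  })
  excluded <- any(vapply(res, is.null, logical(1)))
  if (excluded) {
    return(structure(list(subject_id = subject_id, image_bens = NA_real_,
                          image_bits = NA_real_, ben = NA_real_,
                          excluded = TRUE),
                     class = "subject_ben"))
  }
  bens <- vapply(res, `[[`, numeric(1), "ben")
  bits <- vapply(res, `[[`, numeric(1), "entropy_bits")
  structure(list(subject_id = subject_id, image_bens = bens,
                 image_bits = bits, ben = mean(bens), excluded = FALSE),
            class = "subject_ben")
}

#' @export
print.subject_ben <- function(x, ...) {
  if (x$excluded) {
    cat("<subject_ben>", x$subject_id, "EXCLUDED (no retained pixels)\n")
  } else {
    cat(sprintf("<subject_ben> %s BEN = %.4f (images: %s)\n", x$subject_id,
                x$ben, paste(sprintf("%.4f", x$image_bens), collapse = ", ")))
  }
  invisible(x)
}
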