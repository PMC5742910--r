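#' Segment an activation image into the five colour classes
#'
#' Assigns every pixel to the colour class whose reference colour is nearest
#' in Euclidean RGB distance. Ties are broken deterministically by the
#' canonical class order (background, white, grey, blue, red). Pixels of the
#' white, grey and blue classes are retained for entropy analysis; background
#' and red-artifact pixels are excluded.
#'
#' @param image a [component_image()] (or H x W x 3 array in `[0, 255]`).
#' @param profiles colour-profile table as from [default_color_profiles()].
#' @return an object of class `segmentation_result`: a list with
#'   \describe{
#'     \item{labels}{H x W integer matrix of class indices, with the class
#'       names in `attr(labels, "classes")`.}
#'     \item{retained_mask}{H x W logical, `TRUE` where class is white, grey
#'       or blue.}
#'     \item{retained_gray}{H x W integer grayscale (BT.601 luminance), `NA`
#'       outside the retained mask.}
#'     \item{class_counts}{named integer vector of pixel counts per class.}
#'   }
#' @examples
#' img <- component_image(array(c(255, 0, 255, 0, 255, 0), c(1, 2, 3)))
#' seg <- segment_colors(img)
#' seg$class_counts
#' @export
segment_colors <- function(image, profiles = default_color_profiles()) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  profiles <- validate_color_profiles(profiles)
  ref <- as.matrix(profiles[, c("R", "G", "B")])
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- matrix(as.numeric(image), ncol = 3L)          # N x 3, column-major
  # squared Euclidean distance to each reference colour
  d2 <- matrix(0, nrow = nrow(px), ncol = nrow(ref))
  for (k in seq_len(nrow(ref))) {
    d2[, k] <- (px[, 1] - ref[k, 1])^2 + (px[, 2] - ref[k, 2])^2 +
      (px[, 3] - ref[k, 3])^2
  }
  idx <- max.col(-d2, ties.method = "first")          # first = canonical order
  labels <- matrix(as.integer(idx), nrow = h, ncol = w)
  attr(labels, "classes") <- profiles$class
  retained <- matrix(idx %in% which(profiles$class %in%
                                      c("white", "grey", "blue")),
                     nrow = h, ncol = w)
  counts <- tabulate(idx, nbins = nrow(profiles))
  names(counts) <- profiles$class
  res <- structure(
    list(labels = labels,
         retained_mask = retained,
         retained_gray = to_grayscale(image, retained),
         class_counts = counts,
         subject_id = attr(image, "subject_id")),
    class = "segmentation_result")
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", paste(dim(x$labels), collapse = " x "),
      "pixels;", sum(x$retained_mask), "retained\n")
  print(x$class_counts)
  invisible(x)
}

#' Remove red artifact signals from a segmentation
#'
#' Red pixels do not represent occipital activation and are treated as
#' artifacts: they are excluded from the retained mask and from the retained
#' grayscale image. The class labels themselves are unchanged (the audit
#' record keeps the red count). The operation is idempotent.
#'
#' @param result a `segmentation_result` from [segment_colors()].
#' @return the cleaned `segmentation_result`.
#' @export
remove_red_artifacts <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  red <- which(attr(result$labels, "classes") == "red")
  drop <- result$labels == red
  result$retained_mask[drop] <- FALSE
  result$retained_gray[drop] <- NA_integer_
  result
}

#' Convert retained pixels to 8-bit grayscale
#'
#' Maps each retained pixel to its BT.601 luminance
#' `round(0.299 R + 0.587 G + 0.114 B)`, clamped to `[0, 255]`. Non-retained
#' pixels carry no intensity (`NA`).
#'
#' @param image H x W x 3 array in `[0, 255]`.
#' @param mask H x W logical retained mask.
#' @return H x W integer matrix, `NA` outside `mask`.
#' @export
to_grayscale <- function(image, mask) {
  d <- dim(image)
  if (is.null(dim(mask)) || !all(dim(mask) == d[1:2])) {
    stop("mask dimensions must match the image")
  }
  g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
               0.114 * image[, , 3])
  g <- pmin(pmax(g, 0), 255)
  g[!mask] <- NA
  storage.mode(g) <- "integer"
  matrix(g, nrow = d[1], ncol = d[2])
}

#' Write a label-map audit image
#'
#' Renders the class labels of a segmentation using the reference colours, for
#' visual audit of the segmentation, and optionally writes the per-class pixel
#' counts alongside as CSV.
#'
#' @param result a `segmentation_result`.
#' @param path output PNG path.
#' @param counts_path optional CSV path for the class counts.
#' @param profiles colour profiles used to render classes.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(result, path, counts_path = NULL,
                            profiles = default_color_profiles()) {
  stopifnot(inherits(result, "segmentation_result"))
  profiles <- validate_color_profiles(profiles)
  ref <- as.matrix(profiles[, c("R", "G", "B")]) / 255
  idx <- as.integer(result$labels)
  d <- dim(result$labels)
  arr <- array(0, dim = c(d, 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(ref[idx, ch], nrow = d[1])
  png::writePNG(arr, path)
  if (!is.null(counts_path)) {
    utils::write.csv(
      data.frame(class = names(result$class_counts),
                 pixels = as.integer(result$class_counts)),
      counts_path, row.names = FALSE)
  }
  invisible(path)
}
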