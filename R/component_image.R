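#' Construct a component image
#'
#' A component image is one rendered activation overlay (an ICA spatial map
#' drawn over anatomy) attributed to a subject: an H x W x 3 array of 8-bit
#' RGB values.
#'
#' @param pixels numeric or integer array of dimension H x W x 3 with values
#'   in `[0, 255]`.
#' @param subject_id subject identifier (scalar character).
#' @param component_index integer index of the ICA component the image renders.
#' @param source_path optional path the image was read from.
#' @return an object of class `component_image` (an integer H x W x 3 array
#'   with metadata attributes).
#' @export
component_image <- function(pixels, subject_id = NA_character_,
                            component_index = NA_integer_,
                            source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have H, W >= 1")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255)) {
    stop("channel values must be finite and in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels,
            subject_id = as.character(subject_id),
            component_index = as.integer(component_index),
            source_path = as.character(source_path),
            class = c("component_image", "array"))
}

#' @export
print.component_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<component_image> %d x %d, subject %s, component %s\n",
              d[1], d[2], attr(x, "subject_id"),
              attr(x, "component_index")))
  invisible(x)
}

#' Read a component image from a PNG file
#'
#' Reads an 8-bit RGB (or RGBA/greyscale, converted) PNG into a
#' [component_image()].
#'
#' @param path PNG file path.
#' @inheritParams component_image
#' @return a `component_image`.
#' @export
read_component_image <- function(path, subject_id = NA_character_,
                                 component_index = NA_integer_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {                       # greyscale -> RGB
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {                     # drop alpha
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 2L) {                     # grey + alpha
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  component_image(round(img * 255), subject_id = subject_id,
                  component_index = component_index, source_path = path)
}

#' Write a component image to a PNG file
#'
#' @param image a [component_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_component_image <- function(image, path) {
  stopifnot(inherits(image, "component_image"))
  arr <- unclass(image) / 255
  attributes(arr) <- list(dim = dim(image))
  png::writePNG(arr, path)
  invisible(path)
}
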