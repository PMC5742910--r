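#' Colour classes and reference profiles
#'
#' The segmentation recognises exactly five colour classes. Their canonical
#' order (used for deterministic tie-breaking) is background, white, grey,
#' blue, red. Reference colours default to maximally separated 8-bit RGB
#' values; datasets rendered with other conventions can override them.
#'
#' @return `color_classes()` returns the five class names in canonical order.
#' @export
color_classes <- function() {
  c("background", "white", "grey", "blue", "red")
}

#' @rdname color_classes
#' @return `default_color_profiles()` returns a data frame with columns
#'   `class`, `R`, `G`, `B` (one row per class, canonical order).
#' @examples
#' default_color_profiles()
#' @export
default_color_profiles <- function() {
  data.frame(
    class = color_classes(),
    R = c(0L, 255L, 128L, 0L, 255L),
    G = c(0L, 255L, 128L, 0L, 0L),
    B = c(0L, 255L, 128L, 255L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Validate a colour-profile table
#'
#' Checks that a profile table defines all five classes exactly once with
#' distinct, in-range reference colours, and returns it reordered canonically.
#'
#' @param profiles data frame with columns `class`, `R`, `G`, `B`.
#' @return the validated profile table in canonical class order.
#' @export
validate_color_profiles <- function(profiles) {
  req <- c("class", "R", "G", "B")
  if (!is.data.frame(profiles) || !all(req %in% names(profiles))) {
    stop("profiles must be a data frame with columns class, R, G, B")
  }
  if (!setequal(profiles$class, color_classes()) ||
      nrow(profiles) != length(color_classes())) {
    stop("profiles must contain each of the five classes exactly once: ",
         paste(color_classes(), collapse = ", "))
  }
  rgb <- as.matrix(profiles[, c("R", "G", "B")])
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    stop("reference colours must have channel values in [0, 255]")
  }
  if (anyDuplicated(apply(rgb, 1L, paste, collapse = ","))) {
    stop("duplicate reference colours: classes must have distinct colours")
  }
  profiles <- profiles[match(color_classes(), profiles$class), req]
  rownames(profiles) <- NULL
  profiles
}

#' Read colour profiles from a CSV file
#'
#' Expects a header `class,R,G,B` (a `name` column is accepted as an alias
#' for `class`).
#'
#' @param path CSV file path.
#' @return validated profile data frame.
#' @export
read_color_profiles <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"class" %in% names(tab) && "name" %in% names(tab)) {
    names(tab)[names(tab) == "name"] <- "class"
  }
  validate_color_profiles(tab)
}

# Smallest Euclidean distance between any two reference colours; pixel noise
# must stay well under half of this so nearest-colour classification is stable.
min_profile_distance <- function(profiles = default_color_profiles()) {
  rgb <- as.matrix(validate_color_profiles(profiles)[, c("R", "G", "B")])
  d <- as.matrix(stats::dist(rgb))
  min(d[upper.tri(d)])
}
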