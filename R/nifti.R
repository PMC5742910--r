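#' Render an axial slice of a NIfTI statistic volume as a component image
#'
#' Optional adapter for users whose component maps live in NIfTI statistic
#' volumes rather than exported PNG overlays. One axial slice is rendered
#' with the package's colour convention: voxels with statistic above
#' `threshold` become blue activation, voxels below `-threshold` become red,
#' and the remaining in-mask voxels are drawn as achromatic tissue whose gray
#' level scales with the underlying anatomy/statistic magnitude. Requires the
#' RNifti package.
#'
#' The rendering is a convenience, not a reconstruction of any particular
#' viewer's output; for published analyses export the viewer's own overlay
#' PNG and use [read_component_image()].
#'
#' @param path NIfTI file.
#' @param slice axial slice index (defaults to the middle slice).
#' @param threshold absolute statistic threshold for activation colouring.
#' @param subject_id,component_index metadata for the returned image.
#' @return a [component_image()].
#' @export
read_nifti_component_slice <- function(path, slice = NULL, threshold = 2.3,
                                       subject_id = NA_character_,
                                       component_index = NA_integer_) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input")
  }
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  if (length(d) < 3) stop("expected a 3D (or 4D) NIfTI volume")
  if (length(d) == 4) vol <- vol[, , , 1]
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- vol[, , slice]
  mask <- is.finite(sl) & sl != 0
  g <- matrix(0, nrow(sl), ncol(sl))
  if (any(mask)) {
    v <- abs(sl[mask])
    rng <- range(v)
    scale <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
    g[mask] <- round(80 + 100 * scale)          # grey decision region
  }
  R <- g; G <- g; B <- g
  pos <- mask & sl > threshold
  neg <- mask & sl < -threshold
  R[pos] <- 0; G[pos] <- 0; B[pos] <- 255
  R[neg] <- 255; G[neg] <- 0; B[neg] <- 0
  component_image(array(c(R, G, B), dim = c(dim(sl), 3L)),
                  subject_id = subject_id,
                  component_index = component_index, source_path = path)
}
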