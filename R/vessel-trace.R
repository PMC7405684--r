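#' Vessel centerline trace
#'
#' A manually (or synthetically) traced vessel centerline. Coordinates are
#' 0-based pixel coordinates with x increasing rightwards (columns), y
#' increasing downwards (rows), and integer positions referring to pixel
#' centers — the convention used throughout the package. A trace marks only
#' the main branch central to any major bifurcation.
#'
#' @param id Character vessel identifier.
#' @param class Vessel class, `"arteriole"` or `"venule"`.
#' @param points Numeric n x 2 matrix (columns x, y) of polyline vertices in
#'   pixel coordinates; at least two distinct points, no repeated consecutive
#'   points.
#' @param source `"manual"` or `"synthetic"`.
#' @return An object of class `vessel_trace`.
#' @export
vessel_trace <- function(id, class = c("arteriole", "venule"), points,
                         source = c("manual", "synthetic")) {
  class <- match.arg(class)
  source <- match.arg(source)
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) {
    stopf("trace '%s': points must be an n x 2 matrix with n >= 2", id)
  }
  storage.mode(points) <- "double"
  d <- diff(points)
  if (any(rowSums(abs(d)) == 0)) {
    stopf("trace '%s': repeated consecutive points", id)
  }
  structure(
    list(id = as.character(id), class = class, points = points,
         source = source),
    class = "vessel_trace"
  )
}

#' @export
print.vessel_trace <- function(x, ...) {
  cat(sprintf("<vessel_trace> id=%s class=%s points=%d source=%s\n",
              x$id, x$class, nrow(x$points), x$source))
  invisible(x)
}

#' Reference circle for slice pooling
#'
#' The fixed-diameter circle, visually centered on the retina, inside which
#' perpendicular slices are pooled for the ensemble width measurement
#' (1.72 mm diameter at P6, 2.05 mm at P9 in the developmental flat-mount
#' protocol).
#'
#' @param center Numeric length-2 (x, y) center in pixel coordinates.
#' @param diameter_um Circle diameter in micrometers (> 0).
#' @param pixel_scale Image scale in micrometers per pixel (> 0).
#' @return An object of class `reference_circle`.
#' @export
reference_circle <- function(center, diameter_um, pixel_scale) {
  stopifnot(length(center) == 2, is.finite(center))
  if (!is.numeric(diameter_um) || diameter_um <= 0) {
    stopf("diameter_um must be > 0")
  }
  if (!is.numeric(pixel_scale) || pixel_scale <= 0) {
    stopf("pixel_scale must be > 0")
  }
  structure(
    list(center = as.numeric(center), diameter_um = as.numeric(diameter_um),
         pixel_scale = as.numeric(pixel_scale)),
    class = "reference_circle"
  )
}

#' Vessel measurement configuration
#'
#' Tunable parameters of the vessel-caliber algorithm, with defaults suited
#' to fluorescently labelled (bright-vessel) flat-mount images.
#'
#' @param nominal_radius_px Expected vessel half-width in pixels; sets the
#'   default dilation radius and slice half-length.
#' @param dilate_radius_px Radius for thickening the centerline so the mask
#'   generously covers the vessel (default 2 x nominal radius).
#' @param half_length_px Half-length of perpendicular slices (default 3 x
#'   nominal radius; must exceed the expected half-width by at least 50%).
#' @param step_px Sampling step along the slice normal, in pixels.
#' @param smooth_halfwin Half-window (pixels along the chain) of the moving
#'   average applied before tangent estimation.
#' @param min_slices Minimum number of in-circle slices for a width to be
#'   considered reliable.
#' @param dark_vessels Set `TRUE` for bright-field images where vessels are
#'   darker than the background; the image is inverted before normalization.
#' @param background_fraction Fraction of the outermost slice offsets used to
#'   estimate the local background of the ensemble profile.
#' @return A list of class `vessel_config`.
#' @export
vessel_config <- function(nominal_radius_px = 8,
                          dilate_radius_px = 2 * nominal_radius_px,
                          half_length_px = 3 * nominal_radius_px,
                          step_px = 0.25,
                          smooth_halfwin = 5,
                          min_slices = 20,
                          dark_vessels = FALSE,
                          background_fraction = 0.2) {
  stopifnot(nominal_radius_px > 0, dilate_radius_px >= 0,
            half_length_px > 0, step_px > 0, smooth_halfwin >= 0,
            min_slices >= 1, background_fraction > 0,
            background_fraction < 0.5)
  structure(
    list(nominal_radius_px = nominal_radius_px,
         dilate_radius_px = dilate_radius_px,
         half_length_px = half_length_px,
         step_px = step_px,
         smooth_halfwin = as.integer(smooth_halfwin),
         min_slices = as.integer(min_slices),
         dark_vessels = isTRUE(dark_vessels),
         background_fraction = background_fraction),
    class = "vessel_config"
  )
}
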