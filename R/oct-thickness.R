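# OCT layer-thickness sampling: given segmented boundary depth curves, derive
# per-layer and composite thicknesses at fixed lateral distances on both
# sides of the optic disc. Segmentation itself is performed upstream (by the
# acquisition software); boundaries are inputs here.

# boundary order, vitreous to sclera
OCT_BOUNDARY_NAMES <- c("ILM", "RNFGC/IPL", "IPL/INL", "OPL", "ELM", "RPE")

# layer -> (upper boundary, lower boundary). The RNFL and GCL are never
# separated (their reflectance profiles are too similar to delineate), hence
# the combined RNFGC complex. The ELM is carried in the data model but no
# reported layer uses it.
OCT_LAYER_MAP <- list(
  "RNFGC"      = c("ILM", "RNFGC/IPL"),
  "IPL"        = c("RNFGC/IPL", "IPL/INL"),
  "INL"        = c("IPL/INL", "OPL"),
  "RNFGC+IPL"  = c("ILM", "IPL/INL"),
  "inner"      = c("ILM", "OPL"),
  "outer"      = c("OPL", "RPE"),
  "total"      = c("ILM", "RPE")
)

#' Standard lateral measurement offsets
#'
#' Four lateral distances on both sides of the optic disc: -400, -300, -200,
#' -100, +100, +200, +300, +400 micrometers.
#' @return Numeric vector of 8 offsets, um.
#' @export
oct_offsets <- function() c(-400, -300, -200, -100, 100, 200, 300, 400)

#' Segmented OCT boundary curves
#'
#' @param lateral_um Lateral positions of the sampling grid, um (increasing).
#' @param depths Named list or matrix of boundary depths (um, increasing away
#'   from the vitreous) over the lateral grid; names must be ILM, RNFGC/IPL,
#'   IPL/INL, OPL, ELM, RPE. Depths must be strictly ordered at every lateral
#'   position.
#' @param disc_center_um Lateral position of the optic-disc center, um.
#'   Offsets are measured from the disc center.
#' @return An `oct_boundaries` object.
#' @export
oct_boundaries <- function(lateral_um, depths, disc_center_um = 0) {
  if (is.list(depths)) depths <- do.call(cbind, depths)
  depths <- as.matrix(depths)
  if (!all(OCT_BOUNDARY_NAMES %in% colnames(depths))) {
    stopf("depths must include boundaries: %s",
          paste(OCT_BOUNDARY_NAMES, collapse = ", "))
  }
  depths <- depths[, OCT_BOUNDARY_NAMES, drop = FALSE]
  stopifnot(length(lateral_um) == nrow(depths), !is.unsorted(lateral_um))
  for (j in seq_len(ncol(depths) - 1)) {
    if (any(depths[, j] >= depths[, j + 1])) {
      stopf("boundary ordering violated: %s crosses %s",
            OCT_BOUNDARY_NAMES[j], OCT_BOUNDARY_NAMES[j + 1])
    }
  }
  structure(
    list(lateral_um = as.numeric(lateral_um), depths = depths,
         disc_center_um = disc_center_um),
    class = "oct_boundaries"
  )
}

#' @export
print.oct_boundaries <- function(x, ...) {
  cat(sprintf("<oct_boundaries> %d lateral samples over [%g, %g] um, disc at %g um\n",
              length(x$lateral_um), min(x$lateral_um), max(x$lateral_um),
              x$disc_center_um))
  invisible(x)
}

boundary_depth_at <- function(b, name, lateral) {
  stats::approx(b$lateral_um, b$depths[, name], xout = lateral, rule = 1)$y
}

#' Layer thickness at one lateral offset
#'
#' Thickness is the depth of the layer's lower boundary minus that of its
#' upper boundary at `disc_center + offset`, with linear interpolation
#' between grid points and measurement along the depth (A-scan) axis. Layer
#' names: RNFGC, IPL, INL, RNFGC+IPL, inner (ILM to OPL), outer (OPL to
#' RPE), total (ILM to RPE).
#'
#' @param boundaries An [oct_boundaries()].
#' @param layer Layer name (see above).
#' @param offset_um Signed lateral offset from the disc center; its absolute
#'   value must be one of 100, 200, 300, 400 um.
#' @return Thickness, um.
#' @export
layer_thickness <- function(boundaries, layer, offset_um) {
  stopifnot(inherits(boundaries, "oct_boundaries"))
  if (!layer %in% names(OCT_LAYER_MAP)) {
    stopf("unknown layer '%s' (use %s)", layer,
          paste(names(OCT_LAYER_MAP), collapse = ", "))
  }
  if (!abs(offset_um) %in% c(100, 200, 300, 400)) {
    stopf("offset must be +/-100, 200, 300 or 400 um from the disc center")
  }
  pos <- boundaries$disc_center_um + offset_um
  pair <- OCT_LAYER_MAP[[layer]]
  up <- boundary_depth_at(boundaries, pair[1], pos)
  lo <- boundary_depth_at(boundaries, pair[2], pos)
  if (is.na(up) || is.na(lo)) stopf("offset %g um outside boundary support", offset_um)
  if (lo <= up) stopf("boundary ordering violated at offset %g um", offset_um)
  lo - up
}

#' Full layer-thickness profile for one eye
#'
#' Evaluates all seven reported layers at the eight standard lateral offsets
#' (four distances on both sides of the disc).
#'
#' @param boundaries An [oct_boundaries()].
#' @return Data frame `layer`, `offset_um`, `thickness_um` (56 rows).
#' @export
thickness_profile <- function(boundaries) {
  grid <- expand.grid(layer = names(OCT_LAYER_MAP), offset_um = oct_offsets(),
                      stringsAsFactors = FALSE)
  grid$thickness_um <- mapply(function(l, o) layer_thickness(boundaries, l, o),
                              grid$layer, grid$offset_um)
  grid <- grid[order(match(grid$layer, names(OCT_LAYER_MAP)), grid$offset_um), ]
  rownames(grid) <- NULL
  grid
}

#' Per-animal thickness profile from one or two eyes
#'
#' The per-animal value for each (layer, offset) cell is the mean of the
#' available eyes' values.
#'
#' @param profiles List of [thickness_profile()] data frames (one per eye).
#' @return Data frame `layer`, `offset_um`, `thickness_um`, `n_eyes`.
#' @export
average_eye_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all <- do.call(rbind, profiles)
  agg <- stats::aggregate(thickness_um ~ layer + offset_um, data = all, FUN = mean)
  agg$n_eyes <- length(profiles)
  agg <- agg[order(match(agg$layer, names(OCT_LAYER_MAP)), agg$offset_um), ]
  rownames(agg) <- NULL
  agg
}

#' Read OCT boundaries from JSON
#'
#' Expects a JSON object mapping each boundary name to parallel arrays
#' `lateral_um` and `depth_um`, plus `disc_center_um`.
#'
#' @param path JSON path.
#' @return An [oct_boundaries()].
#' @export
read_oct_boundaries <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lat <- x[[OCT_BOUNDARY_NAMES[1]]]$lateral_um
  depths <- sapply(OCT_BOUNDARY_NAMES, function(nm) {
    b <- x[[nm]]
    if (is.null(b)) stopf("boundary '%s' missing from %s", nm, path)
    if (!isTRUE(all.equal(b$lateral_um, lat))) stopf("boundary grids differ")
    b$depth_um
  })
  oct_boundaries(lat, depths, x$disc_center_um %||% 0)
}

#' Write OCT boundaries to JSON
#'
#' @param boundaries An [oct_boundaries()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_oct_boundaries <- function(boundaries, path) {
  payload <- lapply(OCT_BOUNDARY_NAMES, function(nm) {
    list(lateral_um = boundaries$lateral_um,
         depth_um = as.numeric(boundaries$depths[, nm]))
  })
  names(payload) <- OCT_BOUNDARY_NAMES
  payload$disc_center_um <- boundaries$disc_center_um
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
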