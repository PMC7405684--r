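# Synthetic OCT boundary geometry with analytically known thicknesses. Each
# boundary depth is a constant plus an optional smooth polynomial in the
# lateral distance from the disc center, so every layer thickness has a
# closed form at any offset.

#' Specification of synthetic OCT boundaries
#'
#' @param boundary_offsets Named list (ILM, RNFGC/IPL, IPL/INL, OPL, ELM,
#'   RPE), each entry a numeric vector of polynomial coefficients
#'   `c(constant, linear, quadratic, ...)` of depth (um) in the lateral
#'   distance from the disc center (um). Defaults approximate an adult mouse
#'   retina. Depth functions must never cross over the lateral extent.
#' @param lateral_extent Total lateral extent of the scan, um.
#' @param grid_step_um Lateral sampling step (a divisor of 100 keeps the
#'   standard offsets exactly on the grid).
#' @param disc_center_um Lateral position of the disc center, um.
#' @param seed Integer seed (for generators that randomize this spec).
#' @return A `synthetic_oct_spec` object.
#' @export
synthetic_oct_spec <- function(boundary_offsets = list(
                                 "ILM" = 0, "RNFGC/IPL" = 35, "IPL/INL" = 85,
                                 "OPL" = 120, "ELM" = 190, "RPE" = 220),
                               lateral_extent = 1000, grid_step_um = 10,
                               disc_center_um = 0, seed = 1) {
  if (!all(OCT_BOUNDARY_NAMES %in% names(boundary_offsets))) {
    stopf("boundary_offsets must name all of: %s",
          paste(OCT_BOUNDARY_NAMES, collapse = ", "))
  }
  stopifnot(lateral_extent >= 800, grid_step_um > 0)
  structure(
    list(boundary_offsets = boundary_offsets[OCT_BOUNDARY_NAMES],
         lateral_extent = lateral_extent, grid_step_um = grid_step_um,
         disc_center_um = disc_center_um, seed = as.integer(seed)),
    class = "synthetic_oct_spec"
  )
}

eval_depth_poly <- function(coefs, x) {
  out <- numeric(length(x)) + 0
  for (p in seq_along(coefs)) out <- out + coefs[p] * x^(p - 1)
  out
}

#' Generate synthetic OCT boundaries with analytic ground truth
#'
#' Evaluates each boundary's depth polynomial on the lateral grid and returns
#' both the [oct_boundaries()] object and the analytic thickness table — the
#' pointwise differences of the depth functions, evaluated in closed form at
#' the eight standard offsets. Crossing boundaries are rejected.
#'
#' @param spec A [synthetic_oct_spec()].
#' @return List with `boundaries` and `analytic` (data frame `layer`,
#'   `offset_um`, `thickness_um`).
#' @export
generate_oct_boundaries <- function(spec) {
  stopifnot(inherits(spec, "synthetic_oct_spec"))
  half <- spec$lateral_extent / 2
  rel <- seq(-half, half, by = spec$grid_step_um)
  depths <- sapply(spec$boundary_offsets, eval_depth_poly, x = rel)
  colnames(depths) <- OCT_BOUNDARY_NAMES
  boundaries <- oct_boundaries(rel + spec$disc_center_um, depths,
                               spec$disc_center_um)
  grid <- expand.grid(layer = names(OCT_LAYER_MAP), offset_um = oct_offsets(),
                      stringsAsFactors = FALSE)
  grid$thickness_um <- mapply(function(l, o) {
    pair <- OCT_LAYER_MAP[[l]]
    eval_depth_poly(spec$boundary_offsets[[pair[2]]], o) -
      eval_depth_poly(spec$boundary_offsets[[pair[1]]], o)
  }, grid$layer, grid$offset_um)
  grid <- grid[order(match(grid$layer, names(OCT_LAYER_MAP)), grid$offset_um), ]
  rownames(grid) <- NULL
  list(boundaries = boundaries, analytic = grid)
}

#' Random non-crossing synthetic OCT geometry
#'
#' Draws jittered boundary constants and smooth low-order polynomial bumps,
#' re-drawing until the strict boundary ordering holds over the full lateral
#' extent. Useful for property tests of additivity and symmetry.
#'
#' @param seed Integer seed.
#' @param lateral_extent,grid_step_um,disc_center_um Passed through to
#'   [synthetic_oct_spec()].
#' @return A `synthetic_oct_spec`.
#' @export
random_oct_spec <- function(seed = 1, lateral_extent = 1000,
                            grid_step_um = 10, disc_center_um = 0) {
  base <- c(0, 35, 85, 120, 190, 220)
  with_seed(seed, {
    repeat {
      offs <- lapply(seq_along(base), function(i) {
        c(base[i] + stats::rnorm(1, 0, 4),
          stats::rnorm(1, 0, 0.01),
          stats::rnorm(1, 0, 2e-5))
      })
      names(offs) <- OCT_BOUNDARY_NAMES
      spec <- synthetic_oct_spec(offs, lateral_extent, grid_step_um,
                                 disc_center_um, seed = seed)
      ok <- tryCatch({ generate_oct_boundaries(spec); TRUE },
                     error = function(e) FALSE)
      if (ok) return(spec)
    }
  })
}
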