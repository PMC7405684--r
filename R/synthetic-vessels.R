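# Synthetic flat-mount vessel images with analytically known widths, used to
# validate the caliber algorithm. Vessels are rendered on a 4x supersampled
# grid and box-downsampled, so the stated true width is meaningful at
# subpixel precision.

#' Specification of a synthetic vessel image
#'
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_scale Micrometers per pixel (> 0).
#' @param vessels List of vessels; each a list with `points` (n x 2 polyline,
#'   0-based pixel coordinates), `true_width_um` (> 0), `class`
#'   (`"arteriole"`/`"venule"`), `peak_brightness` (units above background),
#'   and `profile_shape` (`"rectangular"` or `"gaussian"`; for a Gaussian
#'   cross-section the true width is its FWHM).
#' @param background_level Background brightness (arbitrary units).
#' @param background_gradient Linear brightness ramp along x, units per px.
#' @param noise_sd Standard deviation of additive white Gaussian pixel noise.
#' @param reference_circle Optional [reference_circle()] recorded with the
#'   ground truth.
#' @param seed Integer RNG seed.
#' @return A `synthetic_vessel_spec` object.
#' @export
synthetic_vessel_spec <- function(image_size = c(256, 256), pixel_scale = 2,
                                  vessels, background_level = 100,
                                  background_gradient = 0, noise_sd = 0,
                                  reference_circle = NULL, seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 8), pixel_scale > 0,
            noise_sd >= 0, length(vessels) >= 1)
  h <- image_size[1]; w <- image_size[2]
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    stopifnot(!is.null(v$points), !is.null(v$true_width_um))
    v$points <- as.matrix(v$points)
    if (v$true_width_um <= 0) stopf("vessel %d: true_width_um must be > 0", i)
    if (any(v$points[, 1] < 0 | v$points[, 1] > w - 1 |
              v$points[, 2] < 0 | v$points[, 2] > h - 1)) {
      stopf("vessel %d: polyline leaves the image bounds", i)
    }
    v$class <- match.arg(v$class %||% "arteriole", c("arteriole", "venule"))
    v$peak_brightness <- v$peak_brightness %||% 100
    v$profile_shape <- match.arg(v$profile_shape %||% "rectangular",
                                 c("rectangular", "gaussian"))
    v$id <- v$id %||% sprintf("V%02d", i)
    vessels[[i]] <- v
  }
  structure(
    list(image_size = as.integer(image_size), pixel_scale = pixel_scale,
         vessels = vessels, background_level = background_level,
         background_gradient = background_gradient, noise_sd = noise_sd,
         reference_circle = reference_circle, seed = as.integer(seed)),
    class = "synthetic_vessel_spec"
  )
}

# Minimum distance from points (px, py) to a polyline (n x 2 matrix).
dist_to_polyline <- function(px, py, pts) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1)) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[i + 1, 1]; by <- pts[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + tt * vx)
    dy <- py - (ay + tt * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Render a synthetic vessel image
#'
#' Renders each vessel with its stated cross-section profile (full width
#' `true_width_um / pixel_scale` pixels) on a 4x supersampled grid, box
#' downsamples, then adds the background level, the linear gradient, and
#' seeded white Gaussian noise. Where vessels overlap the brightest
#' contribution wins.
#'
#' @param spec A [synthetic_vessel_spec()].
#' @return List with `image` (numeric matrix), `truth` (data frame of
#'   per-vessel true widths), and `traces` (list of [vessel_trace()]).
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_vessel_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  ss <- 4L
  hs <- h * ss; ws <- w * ss
  # supersample coordinates of subpixel centers, in output-pixel units
  sx <- (seq_len(ws) - 1) / ss - 0.5 + 1 / (2 * ss)
  sy <- (seq_len(hs) - 1) / ss - 0.5 + 1 / (2 * ss)
  vmat <- matrix(0, hs, ws)
  for (v in spec$vessels) {
    half_w <- (v$true_width_um / spec$pixel_scale) / 2
    pad <- half_w * if (v$profile_shape == "gaussian") 3 else 1.2
    xr <- range(v$points[, 1]); yr <- range(v$points[, 2])
    ci <- which(sx >= xr[1] - pad & sx <= xr[2] + pad)
    ri <- which(sy >= yr[1] - pad & sy <= yr[2] + pad)
    if (!length(ci) || !length(ri)) next
    px <- rep(sx[ci], each = length(ri))
    py <- rep(sy[ri], times = length(ci))
    d <- dist_to_polyline(px, py, v$points)
    contrib <- if (v$profile_shape == "rectangular") {
      v$peak_brightness * (d <= half_w)
    } else {
      sigma <- (2 * half_w) / (2 * sqrt(2 * log(2)))  # FWHM = true width
      v$peak_brightness * exp(-d^2 / (2 * sigma^2))
    }
    block <- matrix(contrib, nrow = length(ri), ncol = length(ci))
    vmat[ri, ci] <- pmax(vmat[ri, ci], block)
  }
  # box downsample ss x ss blocks
  img <- vmat
  dim(img) <- c(ss, h, hs * ws / (ss * h))
  img <- colMeans(img)                       # h x ws
  img <- t(img)                              # ws x h
  dim(img) <- c(ss, w, h)
  img <- t(colMeans(img))                    # h x w
  # background + gradient along x (evaluated at output pixel centers)
  img <- img + spec$background_level +
    spec$background_gradient * matrix(rep(0:(w - 1), each = h), h, w)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed, matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  traces <- lapply(spec$vessels, function(v) {
    vessel_trace(v$id, v$class, v$points, source = "synthetic")
  })
  truth <- data.frame(
    id = vapply(spec$vessels, `[[`, character(1), "id"),
    class = vapply(spec$vessels, `[[`, character(1), "class"),
    true_width_um = vapply(spec$vessels, `[[`, numeric(1), "true_width_um"),
    profile_shape = vapply(spec$vessels, `[[`, character(1), "profile_shape"),
    stringsAsFactors = FALSE
  )
  list(image = img, truth = truth, traces = traces)
}

#' Write a synthetic vessel dataset to disk
#'
#' Writes the image as 16-bit grayscale TIFF (brightness clipped to
#' `[0, 65535]` counts) and the ground truth — vessel centerlines, classes,
#' true widths, pixel scale, and the reference circle — as JSON.
#'
#' @param generated Output of [generate_vessel_image()].
#' @param spec The [synthetic_vessel_spec()] used.
#' @param dir Output directory (created if missing).
#' @param stem File stem for `<stem>.tif` / `<stem>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_vessel_dataset <- function(generated, spec, dir, stem = "vessels") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tif"))
  jsn <- file.path(dir, paste0(stem, ".json"))
  img <- pmax(pmin(generated$image / 65535, 1), 0)
  tiff::writeTIFF(img, tif, bits.per.sample = 16)
  payload <- list(
    vessels = lapply(seq_along(spec$vessels), function(i) {
      v <- spec$vessels[[i]]
      list(id = v$id, class = v$class,
           points_px = unname(as.matrix(v$points)),
           true_width_um = v$true_width_um)
    }),
    pixel_scale_um_per_px = spec$pixel_scale
  )
  if (!is.null(spec$reference_circle)) {
    payload$reference_circle <- list(
      center_px = spec$reference_circle$center,
      diameter_um = spec$reference_circle$diameter_um
    )
  }
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(image = tif, json = jsn))
}

#' Read a grayscale retinal image (TIFF or PNG)
#'
#' @param path Image path; 16-bit TIFF values are returned in counts
#'   (0-65535), PNG in 0-255/0-65535 depending on bit depth.
#' @return Numeric matrix.
#' @export
read_retinal_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stopf("unsupported image format '%s'", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]   # first channel of RGB(A)
  img * 65535
}

#' Read a vessel-trace JSON file
#'
#' Parses the dataset schema written by [write_vessel_dataset()]: vessel
#' centerlines with class labels and optional reference circle.
#'
#' @param path JSON path.
#' @param source Provenance label for the traces.
#' @return List with `traces`, `pixel_scale`, and `circle` (or `NULL`).
#' @export
read_vessel_json <- function(path, source = "manual") {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vs <- x$vessels
  traces <- if (is.data.frame(vs)) {
    lapply(seq_len(nrow(vs)), function(i) {
      vessel_trace(vs$id[i], vs$class[i], vs$points_px[[i]], source = source)
    })
  } else {
    lapply(vs, function(v) vessel_trace(v$id, v$class, v$points_px, source = source))
  }
  circle <- NULL
  if (!is.null(x$reference_circle)) {
    circle <- reference_circle(unlist(x$reference_circle$center_px),
                               x$reference_circle$diameter_um,
                               x$pixel_scale_um_per_px)
  }
  list(traces = traces, pixel_scale = x$pixel_scale_um_per_px, circle = circle)
}
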