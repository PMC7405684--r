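# Hybrid flat-mount vessel-caliber algorithm: thin the traced centerline to a
# single-pixel chain, thicken it to a covering mask, rescale brightness from
# the under-mask histogram, extract brightness slices perpendicular to the
# local tangent, pool the slices inside the reference circle into an ensemble
# profile, and read the vessel width at the mid-brightness level.

#' Thin a traced centerline to a single-pixel chain
#'
#' Rasterizes the polyline into an ordered, 8-connected chain of unique
#' pixels (0-based integer coordinates), preserving the endpoints. Every
#' chain pixel lies within half a pixel diagonal (~0.71 px) of the continuous
#' polyline.
#'
#' @param trace A [vessel_trace()].
#' @return Integer n x 2 matrix (columns x, y) of chain pixels.
#' @export
thin_centerline <- function(trace) {
  pts <- if (inherits(trace, "vessel_trace")) trace$points else as.matrix(trace)
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  if (all(seg_len == 0)) stopf("degenerate trace: all points identical")
  # dense sampling at <= 0.25 px guarantees consecutive rounded pixels are
  # 8-connected and within 0.71 px of the continuous line
  xs <- ys <- list()
  for (i in seq_len(nrow(seg))) {
    n <- max(2L, ceiling(seg_len[i] / 0.25) + 1L)
    tt <- seq(0, 1, length.out = n)
    xs[[i]] <- pts[i, 1] + tt * seg[i, 1]
    ys[[i]] <- pts[i, 2] + tt * seg[i, 2]
  }
  x <- round(unlist(xs))
  y <- round(unlist(ys))
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  chain <- cbind(x = x[keep], y = y[keep])
  storage.mode(chain) <- "integer"
  chain
}

#' Thicken a chain into a covering mask
#'
#' Marks every pixel within `radius_px` (Euclidean) of any chain pixel,
#' producing a binary mask that generously covers the vessel.
#'
#' @param chain Integer n x 2 chain from [thin_centerline()].
#' @param radius_px Dilation radius in pixels (>= expected vessel half-width).
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the given dimensions.
#' @export
dilate_centerline <- function(chain, radius_px, dim) {
  stopifnot(radius_px >= 0, length(dim) == 2)
  h <- as.integer(dim[1]); w <- as.integer(dim[2])
  r <- ceiling(radius_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius_px^2, , drop = FALSE]
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(off))) {
    x <- chain[, 1] + off$dx[k]
    y <- chain[, 2] + off$dy[k]
    ok <- x >= 0 & x < w & y >= 0 & y < h
    mask[cbind(y[ok] + 1L, x[ok] + 1L)] <- TRUE
  }
  mask
}

#' Normalize image brightness from the under-mask histogram
#'
#' Estimates the background level (lower mode) and vessel level (upper mode)
#' from a 64-bin histogram of the pixels under the thickened-centerline mask,
#' then affinely rescales the whole image so background maps to 0 and vessel
#' to 1. The two modes are located on either side of the Otsu threshold of
#' the histogram, with ties broken toward the extremes, and each level is the
#' mean of the pixel values in its modal bin.
#'
#' @param image Numeric matrix.
#' @param thick_mask Logical matrix from [dilate_centerline()].
#' @param bins Number of histogram bins.
#' @return List with `image` (rescaled), `background_level`, `vessel_level`.
#' @export
normalize_brightness <- function(image, thick_mask, bins = 64) {
  stopifnot(identical(dim(image), dim(thick_mask)))
  vals <- image[thick_mask]
  if (length(vals) == 0) stopf("empty mask")
  rng <- range(vals)
  if (diff(rng) == 0) stopf("no vessel contrast: under-mask histogram is degenerate")
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- findInterval(vals, brk, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = bins)
  thr_bin <- otsu_threshold_bin(counts)
  lower <- which(counts[seq_len(thr_bin)] == max(counts[seq_len(thr_bin)]))
  lower_bin <- min(lower)                       # tie toward the low extreme
  upper_counts <- counts[(thr_bin + 1):bins]
  if (all(upper_counts == 0)) stopf("no vessel contrast: unimodal histogram")
  upper <- which(upper_counts == max(upper_counts))
  upper_bin <- thr_bin + max(upper)             # tie toward the high extreme
  background <- mean(vals[bin == lower_bin])
  vessel <- mean(vals[bin == upper_bin])
  if (!is.finite(background) || !is.finite(vessel) || vessel <= background) {
    stopf("no vessel contrast: could not separate background and vessel modes")
  }
  list(image = (image - background) / (vessel - background),
       background_level = background, vessel_level = vessel)
}

# Otsu's between-class-variance threshold on binned counts; returns the last
# bin of the lower class.
otsu_threshold_bin <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  mids <- seq_len(n)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  cand <- which(bcv[-n] == max(bcv[-n]))
  cand[ceiling(length(cand) / 2)]
}

#' Estimate unit tangents along a chain
#'
#' Smooths the chain coordinates with a moving average (half-window
#' `halfwin`, shrunk symmetrically near the ends) and takes central
#' differences; the two endpoints use one-sided differences.
#'
#' @param chain Integer n x 2 chain.
#' @param halfwin Smoothing half-window in chain pixels.
#' @return Numeric n x 2 matrix of unit tangent vectors.
#' @export
estimate_tangents <- function(chain, halfwin = 5) {
  n <- nrow(chain)
  if (n < 2) stopf("chain too short for tangents")
  sm <- apply(chain, 2, function(v) {
    vapply(seq_len(n), function(i) {
      w <- min(halfwin, i - 1, n - i)
      mean(v[(i - w):(i + w)])
    }, numeric(1))
  })
  tx <- numeric(n); ty <- numeric(n)
  idx <- 2:(n - 1)
  if (n > 2) {
    tx[idx] <- sm[idx + 1, 1] - sm[idx - 1, 1]
    ty[idx] <- sm[idx + 1, 2] - sm[idx - 1, 2]
  }
  tx[1] <- sm[2, 1] - sm[1, 1]; ty[1] <- sm[2, 2] - sm[1, 2]
  tx[n] <- sm[n, 1] - sm[n - 1, 1]; ty[n] <- sm[n, 2] - sm[n - 1, 2]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(x = tx / len, y = ty / len)
}

#' Extract brightness slices perpendicular to the vessel
#'
#' For each chain pixel, samples the (normalized) image by bilinear
#' interpolation along the normal direction at fixed sub-pixel steps, giving
#' a brightness profile over signed offsets in `[-half_length_px,
#' +half_length_px]`. Profiles whose support leaves the image are dropped.
#'
#' @param image Numeric matrix (normalized brightness).
#' @param chain Integer n x 2 chain.
#' @param tangents Unit tangents from [estimate_tangents()].
#' @param half_length_px Slice half-length in pixels (should exceed the
#'   expected half-width by at least 50%).
#' @param step_px Sampling step along the normal.
#' @return List with `offsets` (numeric vector), `profiles` (kept x offsets
#'   matrix), and `kept` (indices of chain points whose profile survived).
#' @export
extract_perpendicular_slices <- function(image, chain, tangents,
                                         half_length_px, step_px = 0.25) {
  stopifnot(half_length_px > 0, step_px > 0)
  offsets <- seq(-half_length_px, half_length_px, by = step_px)
  n <- nrow(chain); m <- length(offsets)
  nx <- -tangents[, 2]; ny <- tangents[, 1]
  X <- rep(chain[, 1], each = m) + rep(nx, each = m) * offsets
  Y <- rep(chain[, 2], each = m) + rep(ny, each = m) * offsets
  v <- bilinear_sample(image, X, Y)
  profiles <- matrix(v, nrow = n, ncol = m, byrow = TRUE)
  kept <- which(rowSums(is.na(profiles)) == 0)
  if (length(kept) == 0) stopf("all perpendicular slices leave the image")
  list(offsets = offsets, profiles = profiles[kept, , drop = FALSE],
       kept = kept)
}

#' Clip a chain to the reference circle
#'
#' Returns the indices of chain points strictly inside the reference circle
#' (distance to center, converted to micrometers, strictly less than the
#' circle radius). Points exactly on the circle are excluded.
#'
#' @param chain Integer n x 2 chain.
#' @param circle A [reference_circle()].
#' @return Integer vector of chain indices.
#' @export
clip_to_circle <- function(chain, circle) {
  stopifnot(inherits(circle, "reference_circle"))
  d_um <- sqrt((chain[, 1] - circle$center[1])^2 +
                 (chain[, 2] - circle$center[2])^2) * circle$pixel_scale
  inside <- which(d_um < circle$diameter_um / 2)
  if (length(inside) == 0) stopf("vessel outside reference circle")
  inside
}

#' Ensemble-average perpendicular slices
#'
#' Pointwise mean across slice profiles at each signed offset, yielding a
#' central-tendency cross-section that dilutes the random effects of side
#' branches.
#'
#' @param profiles Numeric slices x offsets matrix.
#' @param min_slices Minimum acceptable number of slices.
#' @return Numeric profile with attribute `n_slices`.
#' @export
ensemble_average <- function(profiles, min_slices = 20) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < min_slices) {
    stopf("only %d slices available (minimum %d)", nrow(profiles), min_slices)
  }
  out <- colMeans(profiles)
  attr(out, "n_slices") <- nrow(profiles)
  out
}

#' Vessel width at the mid-brightness level
#'
#' Reads the full width of the ensemble cross-section at the level halfway
#' between the local background (mean of the outermost fraction of offsets)
#' and the profile peak. The width is the distance between the
#' linearly-interpolated crossings of that level at the edges of the lobe
#' containing the global peak; if other above-level lobes exist a warning is
#' raised and the peak's lobe is used.
#'
#' @param profile Ensemble profile (from [ensemble_average()]).
#' @param offsets Signed offsets (px) matching the profile.
#' @param pixel_scale Micrometers per pixel.
#' @param vessel_id Identifier carried into the result.
#' @param background_fraction Fraction of offsets (split between the two
#'   flanks) treated as background.
#' @return A `width_result` object: ensemble profile, slice count, width in
#'   pixels and micrometers, and the mid-brightness level used.
#' @export
width_at_midbrightness <- function(profile, offsets, pixel_scale,
                                   vessel_id = NA_character_,
                                   background_fraction = 0.2) {
  n <- length(profile)
  stopifnot(length(offsets) == n, n >= 5, pixel_scale > 0)
  k <- max(1L, floor(n * background_fraction / 2))
  background <- mean(c(profile[seq_len(k)], profile[(n - k + 1):n]))
  peak <- max(profile)
  ipk <- which.max(profile)
  if (peak <= background) stopf("profile not enclosed: no central lobe above background")
  level <- (background + peak) / 2
  above <- profile > level
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lobes <- which(runs$values)
  if (length(lobes) > 1) {
    warnf("multiple lobes above mid-brightness; using the lobe containing the global peak")
  }
  li <- lobes[starts[lobes] <= ipk & ends[lobes] >= ipk]
  a <- starts[li]; b <- ends[li]
  if (a == 1L || b == n) stopf("profile not enclosed: no mid-brightness crossing on one flank")
  xl <- offsets[a - 1] + (level - profile[a - 1]) / (profile[a] - profile[a - 1]) *
    (offsets[a] - offsets[a - 1])
  xr <- offsets[b] + (level - profile[b]) / (profile[b + 1] - profile[b]) *
    (offsets[b + 1] - offsets[b])
  width_px <- xr - xl
  structure(
    list(vessel_id = vessel_id,
         ensemble_profile = data.frame(offset_px = offsets, brightness = as.numeric(profile)),
         n_slices = attr(profile, "n_slices") %||% NA_integer_,
         width_px = width_px,
         width_um = width_px * pixel_scale,
         mid_brightness_level = level,
         background_level = background,
         peak_level = peak),
    class = "width_result"
  )
}

#' @export
print.width_result <- function(x, ...) {
  cat(sprintf("<width_result> vessel=%s width=%.2f px (%.2f um) from %s slices\n",
              x$vessel_id, x$width_px, x$width_um,
              ifelse(is.na(x$n_slices), "?", x$n_slices)))
  invisible(x)
}

#' @export
plot.width_result <- function(x, ...) {
  plot(x$ensemble_profile$offset_px, x$ensemble_profile$brightness,
       type = "l", xlab = "signed offset (px)", ylab = "brightness",
       main = sprintf("vessel %s: %.1f um", x$vessel_id, x$width_um), ...)
  graphics::abline(h = x$mid_brightness_level, lty = 2)
  invisible(x)
}

#' Measure one vessel's caliber
#'
#' Runs the full hybrid algorithm on one traced vessel: thin, thicken,
#' histogram-based brightness normalization, tangents, perpendicular slices,
#' reference-circle clipping, ensemble averaging, and mid-brightness width.
#' Deterministic; errors from any stage are re-raised with the vessel id
#' attached.
#'
#' @param image Numeric matrix (raw brightness; rows y, cols x).
#' @param trace A [vessel_trace()].
#' @param circle A [reference_circle()].
#' @param config A [vessel_config()].
#' @return A `width_result` with the vessel class attached.
#' @export
measure_vessel <- function(image, trace, circle, config = vessel_config()) {
  stopifnot(inherits(trace, "vessel_trace"))
  res <- tryCatch({
    chain <- thin_centerline(trace)
    mask <- dilate_centerline(chain, config$dilate_radius_px, dim(image))
    img <- if (config$dark_vessels) -image else image
    norm <- normalize_brightness(img, mask)
    tangents <- estimate_tangents(chain, config$smooth_halfwin)
    inside <- clip_to_circle(chain, circle)
    sl <- extract_perpendicular_slices(norm$image, chain[inside, , drop = FALSE],
                                       tangents[inside, , drop = FALSE],
                                       config$half_length_px, config$step_px)
    ens <- ensemble_average(sl$profiles, config$min_slices)
    width_at_midbrightness(ens, sl$offsets, circle$pixel_scale,
                           vessel_id = trace$id,
                           background_fraction = config$background_fraction)
  }, error = function(e) {
    stopf("vessel '%s': %s", trace$id, conditionMessage(e))
  })
  res$vessel_class <- trace$class
  res
}

#' Per-retina vessel summary
#'
#' Arithmetic mean width and count per vessel class for one retina. A class
#' with zero traced vessels gets count 0 and an absent (`NA`) mean, never 0.
#'
#' @param results List of `width_result` objects (each with `vessel_class`).
#' @param retina_id Retina identifier.
#' @return Data frame with one row per vessel class.
#' @export
summarize_retina <- function(results, retina_id = NA_character_) {
  if (length(results) == 0) stopf("no vessel results to summarize")
  cls <- vapply(results, function(r) r$vessel_class, character(1))
  wid <- vapply(results, function(r) r$width_um, numeric(1))
  out <- lapply(c("arteriole", "venule"), function(cl) {
    sel <- cls == cl
    data.frame(retina_id = retina_id, class = cl,
               vessel_count = sum(sel),
               mean_width_um = if (any(sel)) mean(wid[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-mouse vessel summary
#'
#' When two retinal preparations are available for a mouse, the per-mouse
#' value of each measure is the mean of the retina-level values.
#'
#' @param retina_summaries Data frame rbind of [summarize_retina()] outputs.
#' @param mouse_id Mouse identifier.
#' @return Data frame with one row per vessel class.
#' @export
summarize_mouse <- function(retina_summaries, mouse_id = NA_character_) {
  stopifnot(is.data.frame(retina_summaries))
  out <- lapply(c("arteriole", "venule"), function(cl) {
    rows <- retina_summaries[retina_summaries$class == cl, , drop = FALSE]
    means <- rows$mean_width_um[!is.na(rows$mean_width_um)]
    data.frame(mouse_id = mouse_id, class = cl,
               vessel_count = if (nrow(rows)) mean(rows$vessel_count) else 0,
               mean_width_um = if (length(means)) mean(means) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Vessel curvature tortuosity
#'
#' Arc-length over chord-length of the traced centerline (dimensionless, at
#' least 1). This is a standard tortuosity index; semi-automated grading
#' packages compute a related but unpublished quantity, so values are not
#' interchangeable with theirs.
#'
#' @param trace A [vessel_trace()] or n x 2 point matrix.
#' @return Numeric tortuosity.
#' @export
tortuosity <- function(trace) {
  pts <- if (inherits(trace, "vessel_trace")) trace$points else as.matrix(trace)
  if (nrow(pts) < 2) stopf("need at least two points")
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord == 0) stopf("zero chord: tortuosity undefined for closed curves")
  polyline_length(pts) / chord
}

#' Box-counting fractal dimension of a vessel mask
#'
#' Least-squares slope of log N(eps) versus log(1/eps) over dyadic box sizes
#' spanning at least four octaves, where N(eps) is the number of grid boxes
#' of side eps containing any foreground pixel.
#'
#' @param mask Logical matrix.
#' @return Numeric estimated dimension.
#' @export
fractal_dimension <- function(mask) {
  mask <- as.matrix(mask)
  if (!any(mask)) stopf("empty mask")
  kmax <- floor(log2(min(dim(mask)) / 2))
  if (kmax < 4) stopf("mask too small for four octaves of box sizes")
  sizes <- 2^(0:kmax)
  counts <- vapply(sizes, function(s) box_count(mask, s), numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[[2]]
}

box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- (seq_len(h) - 1L) %/% s
  ci <- (seq_len(w) - 1L) %/% s
  idx <- which(mask, arr.ind = TRUE)
  length(unique(ri[idx[, 1]] * (max(ci) + 1L) + ci[idx[, 2]]))
}
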