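# Shared fixture builders; everything is generated in code at test time.

# A single straight vessel crossing the image center at a given orientation,
# with the measurement objects needed to run the caliber pipeline on it.
straight_vessel_case <- function(width_px, angle_deg, shape = "rectangular",
                                 scale = 2, n = 200, noise_sd = 0, seed = 1,
                                 peak = 80, bg = 100, gradient = 0,
                                 circle_diameter_um = 240 * scale) {
  th <- angle_deg * pi / 180
  cx <- (n - 1) / 2
  L <- 0.4 * n
  p1 <- c(cx - L * cos(th), cx - L * sin(th)) + 0.5
  p2 <- c(cx + L * cos(th), cx + L * sin(th)) + 0.5
  spec <- synthetic_vessel_spec(
    image_size = c(n, n), pixel_scale = scale,
    vessels = list(list(points = rbind(p1, p2),
                        true_width_um = width_px * scale,
                        class = "venule", peak_brightness = peak,
                        profile_shape = shape)),
    background_level = bg, background_gradient = gradient,
    noise_sd = noise_sd, seed = seed)
  g <- generate_vessel_image(spec)
  list(spec = spec, image = g$image, trace = g$traces[[1]],
       circle = reference_circle(c(cx, cx), circle_diameter_um, scale),
       config = vessel_config(nominal_radius_px = max(4, width_px / 2)))
}

measure_straight_vessel <- function(width_px, angle_deg, ...) {
  cs <- straight_vessel_case(width_px, angle_deg, ...)
  measure_vessel(cs$image, cs$trace, cs$circle, cs$config)
}

# Independent oracle: mid-brightness full width of an analytic cross-section
# profile, from dense sampling and linear interpolation of the level
# crossings (never touches the package's profile machinery).
oracle_midbrightness_width <- function(profile_fun, half_support, level_frac = 0.5) {
  x <- seq(-half_support, half_support, length.out = 200001)
  y <- profile_fun(x)
  lev <- min(y) + level_frac * (max(y) - min(y))
  above <- y > lev
  a <- min(which(above)); b <- max(which(above))
  xl <- x[a - 1] + (lev - y[a - 1]) / (y[a] - y[a - 1]) * (x[a] - x[a - 1])
  xr <- x[b] + (lev - y[b]) / (y[b + 1] - y[b]) * (x[b + 1] - x[b])
  xr - xl
}

# Default ERG ground truth used across the ERG tests.
erg_truth <- list(r_max = 300, t_c = 18, t_d = 4, vmax = 400, k = 0.01,
                  k_log = -2, op_pp = 40)
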