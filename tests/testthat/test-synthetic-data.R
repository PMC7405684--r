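# Generators must be deterministic and carry analytic ground truth.

test_that("noiseless rectangular vessel renders with the stated width", {
  # horizontal vessel, 20 um wide at 2 um/px -> 10 px, centerline on a pixel
  # boundary so the bright run is exactly 10 fully-covered rows
  spec <- synthetic_vessel_spec(
    image_size = c(64, 64), pixel_scale = 2,
    vessels = list(list(points = rbind(c(2, 31.5), c(61, 31.5)),
                        true_width_um = 20, class = "venule",
                        peak_brightness = 100, profile_shape = "rectangular")),
    background_level = 0, noise_sd = 0, seed = 1)
  img <- generate_vessel_image(spec)$image
  for (col in c(10, 32, 50)) {
    bright <- which(img[, col + 1] > 50)
    expect_length(bright, 10)
    expect_true(all(diff(bright) == 1))
    expect_equal(unname(img[bright, col + 1]), rep(100, 10))
  }
})

test_that("identical seeds give bit-identical vessel images", {
  mk <- function() generate_vessel_image(synthetic_vessel_spec(
    image_size = c(48, 48), pixel_scale = 2,
    vessels = list(list(points = rbind(c(4, 24), c(43, 24)),
                        true_width_um = 12, class = "arteriole")),
    noise_sd = 8, seed = 7))$image
  expect_identical(mk(), mk())
  # and the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(3)
  mk()
  set.seed(123); expect_identical(before, rnorm(3))
})

test_that("gaussian cross-section FWHM matches the analytic mid-brightness oracle", {
  fwhm_um <- 24; scale <- 2
  sigma_px <- (fwhm_um / scale) / (2 * sqrt(2 * log(2)))
  oracle <- oracle_midbrightness_width(function(x) exp(-x^2 / (2 * sigma_px^2)), 40)
  expect_equal(oracle * scale, fwhm_um, tolerance = 1e-6)
  cs <- straight_vessel_case(fwhm_um / scale, 20, shape = "gaussian", scale = scale)
  est <- measure_vessel(cs$image, cs$trace, cs$circle, cs$config)
  expect_equal(est$width_um, fwhm_um, tolerance = 0.5 / fwhm_um)
})

test_that("vessel polylines outside the image bounds are rejected", {
  expect_error(synthetic_vessel_spec(
    image_size = c(32, 32), pixel_scale = 2,
    vessels = list(list(points = rbind(c(-4, 10), c(40, 10)),
                        true_width_um = 10, class = "venule"))),
    "bounds")
  expect_error(synthetic_vessel_spec(
    image_size = c(32, 32), pixel_scale = 2,
    vessels = list(list(points = rbind(c(2, 2), c(30, 30)),
                        true_width_um = -1, class = "venule"))),
    "true_width_um")
})

test_that("noiseless ERG trace reproduces the activation-model trough exactly", {
  sp <- synthetic_erg_spec(noise_sd = 0, n_sweeps = 1, op_pp_uv = 0)
  tr <- average_sweeps(generate_erg_sweeps(sp, 1.0))
  a <- measure_a_wave(tr)
  expected <- lamb_pugh_response(sp$a_sat_ms, 10^1.0, sp$r_max, sp$t_c, sp$t_d)
  # the B-wave template is analytically nonzero (though < 1e-6 uV) at the
  # trough, so agreement is to numerical precision, not bitwise
  expect_equal(a$a_amplitude, expected, tolerance = 1e-8)
})

test_that("generated B-wave amplitude hits the Naka-Rushton half-maximum at I = K", {
  sp <- synthetic_erg_spec(noise_sd = 0, n_sweeps = 1)
  tr <- average_sweeps(generate_erg_sweeps(sp, log10(sp$k)))
  b <- measure_b_wave(tr)
  expect_equal(b$b_amplitude, sp$vmax / 2, tolerance = 0.01)
})

test_that("sweep averaging reduces noise like sigma over sqrt(n)", {
  sp <- synthetic_erg_spec(noise_sd = 5, n_sweeps = 20, seed = 1)
  sw <- generate_erg_sweeps(sp, 0.1)
  avg <- average_sweeps(sw)
  rms <- sqrt(mean((avg$voltage - sw$clean)^2))
  expect_equal(rms, 5 / sqrt(20), tolerance = 0.15)
  expect_identical(avg$n_sweeps_averaged, 20L)
})

test_that("the OP packet's spectral energy is confined to the analysis band", {
  sp <- synthetic_erg_spec(noise_sd = 0, n_sweeps = 1)
  t <- seq(0, 400, by = 0.5)
  packet <- retphen:::op_packet(t, 130, sp$op_freq_hz, sp$op_envelope_ms, 40)
  X <- abs(fft(packet))^2
  f <- (seq_along(t) - 1) * 2000 / length(t)
  f <- pmin(f, 2000 - f)
  in_band <- f >= 60 & f <= 235
  expect_gt(sum(X[in_band]) / sum(X), 0.95)
})

test_that("synthetic OCT analytic table equals the depth-function differences", {
  # flat geometry: total 220 at all 8 offsets; shared-boundary additivity
  g <- generate_oct_boundaries(synthetic_oct_spec())
  tot <- g$analytic[g$analytic$layer == "total", "thickness_um"]
  expect_equal(tot, rep(220, 8))
  inner <- g$analytic[g$analytic$layer == "inner", "thickness_um"]
  outer <- g$analytic[g$analytic$layer == "outer", "thickness_um"]
  expect_equal(inner, rep(120, 8))
  expect_equal(inner + outer, tot)
  # quadratic ILM bump: closed form at +300 um
  g2 <- generate_oct_boundaries(synthetic_oct_spec(boundary_offsets = list(
    "ILM" = c(0, 0, -5e-5), "RNFGC/IPL" = 35, "IPL/INL" = 85,
    "OPL" = 120, "ELM" = 190, "RPE" = 220)))
  got <- g2$analytic[g2$analytic$layer == "total" & g2$analytic$offset_um == 300,
                     "thickness_um"]
  expect_equal(got, 220 - (0 - 5e-5 * 300^2))
  expect_equal(layer_thickness(g2$boundaries, "total", 300), got)
})

test_that("crossing synthetic boundaries are rejected", {
  expect_error(generate_oct_boundaries(synthetic_oct_spec(boundary_offsets = list(
    "ILM" = 0, "RNFGC/IPL" = 35, "IPL/INL" = 30, "OPL" = 120,
    "ELM" = 190, "RPE" = 220))), "ordering")
})

test_that("vessel dataset round-trips through TIFF + JSON", {
  dir <- withr::local_tempdir()
  cx <- 31.5
  spec <- synthetic_vessel_spec(
    image_size = c(64, 64), pixel_scale = 2,
    vessels = list(list(points = rbind(c(4, 30), c(59, 34)),
                        true_width_um = 16, class = "venule")),
    background_level = 500, noise_sd = 0, seed = 3,
    reference_circle = reference_circle(c(cx, cx), 200, 2))
  g <- generate_vessel_image(spec)
  paths <- write_vessel_dataset(g, spec, dir, "case")
  img <- read_retinal_image(paths[["image"]])
  expect_equal(dim(img), c(64, 64))
  expect_equal(img, g$image, tolerance = 1)   # 16-bit quantization
  ds <- read_vessel_json(paths[["json"]])
  expect_length(ds$traces, 1)
  expect_equal(ds$traces[[1]]$points, spec$vessels[[1]]$points,
               ignore_attr = TRUE)
  expect_equal(ds$circle$diameter_um, 200)
})

test_that("ERG sweeps round-trip through CSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  sp <- synthetic_erg_spec(intensities = c(-2, 1), noise_sd = 2, n_sweeps = 3)
  sw <- generate_erg_sweeps(sp, 1)
  paths <- write_erg_dataset(sw, dir, "i10")
  back <- read_erg_sweeps(paths[["csv"]])
  expect_equal(back$sweeps, sw$sweeps, ignore_attr = TRUE)
  expect_equal(back$intensity, 1)
  expect_equal(back$flash_onset, sp$flash_onset)
  expect_equal(back$sampling_rate, sp$sampling_rate)
})

test_that("OCT boundaries round-trip through JSON", {
  dir <- withr::local_tempdir()
  g <- generate_oct_boundaries(random_oct_spec(seed = 5))
  path <- file.path(dir, "b.json")
  write_oct_boundaries(g$boundaries, path)
  back <- read_oct_boundaries(path)
  expect_equal(back$depths, g$boundaries$depths, ignore_attr = TRUE)
  expect_equal(thickness_profile(back), thickness_profile(g$boundaries))
})
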