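# Unit and property tests for the caliber pipeline stages.

test_that("centerline thinning rasterizes straight and diagonal polylines", {
  ax <- thin_centerline(vessel_trace("v", "venule", rbind(c(0, 0), c(10, 0))))
  expect_equal(nrow(ax), 11)
  expect_equal(ax[, "x"], 0:10, ignore_attr = TRUE)
  expect_true(all(ax[, "y"] == 0))
  dg <- thin_centerline(vessel_trace("v", "venule", rbind(c(0, 0), c(3, 3))))
  expect_equal(dg, cbind(x = 0:3, y = 0:3), ignore_attr = TRUE)
})

test_that("chain pixels stay within 0.71 px of the continuous polyline", {
  set.seed(42)
  for (rep in 1:5) {
    xs <- seq(0, 60, length.out = 8)
    ys <- 30 + cumsum(rnorm(8, 0, 4))
    pts <- cbind(xs, ys)
    chain <- thin_centerline(vessel_trace("v", "venule", pts))
    d <- retphen:::dist_to_polyline(chain[, 1], chain[, 2], pts)
    expect_lt(max(d), 0.71)
    # 8-connectivity
    expect_true(all(abs(diff(chain[, 1])) <= 1 & abs(diff(chain[, 2])) <= 1))
  }
  expect_error(thin_centerline(rbind(c(3, 3), c(3, 3), c(3, 3))), "degenerate")
})

test_that("dilation covers the analytic tube and radius 0 is the chain itself", {
  chain <- cbind(x = 5L:44L, y = rep(25L, 40))
  m0 <- dilate_centerline(chain, 0, c(50, 50))
  expect_equal(sum(m0), 40)
  expect_true(all(m0[cbind(chain[, 2] + 1, chain[, 1] + 1)]))
  m3 <- dilate_centerline(chain, 3, c(50, 50))
  expect_equal(sum(m3[, 26]), 7)   # disc of radius 3 -> 7 px tall
  # long straight chain: area close to length*2r + pi r^2
  r <- 5
  m5 <- dilate_centerline(chain, r, c(60, 60))
  expect_equal(sum(m5), 39 * 2 * r + pi * r^2, tolerance = 0.1)
})

test_that("brightness normalization maps the two modes to 0 and 1", {
  img <- matrix(10, 30, 30)
  img[14:17, ] <- 200
  mask <- matrix(TRUE, 30, 30)
  nb <- normalize_brightness(img, mask)
  expect_equal(nb$background_level, 10)
  expect_equal(nb$vessel_level, 200)
  expect_equal(sort(unique(as.numeric(nb$image))), c(0, 1))
  # affine invariance: adding a constant leaves the rescaled image unchanged
  nb2 <- normalize_brightness(img + 50, mask)
  expect_equal(nb2$image, nb$image)
  expect_error(normalize_brightness(matrix(7, 10, 10), matrix(TRUE, 10, 10)),
               "contrast")
})

test_that("normalization recovers the generator's background and vessel levels", {
  cs <- straight_vessel_case(10, 30, bg = 100, peak = 80)  # vessel level 180
  chain <- thin_centerline(cs$trace)
  mask <- dilate_centerline(chain, 16, dim(cs$image))
  nb <- normalize_brightness(cs$image, mask)
  expect_equal(nb$background_level, 100, tolerance = 1 / 100)
  expect_equal(nb$vessel_level, 180, tolerance = 1 / 180)
})

test_that("tangent estimates follow straight, circular, and sinusoidal geometry", {
  st <- estimate_tangents(cbind(x = 0:30, y = rep(4L, 31)))
  expect_equal(st, cbind(x = rep(1, 31), y = rep(0, 31)), ignore_attr = TRUE)
  # discretized circle: tangent perpendicular to the radius
  th <- seq(0, 2 * pi, length.out = 600)
  circ <- thin_centerline(vessel_trace("c", "venule",
                                       cbind(60 + 50 * cos(th), 60 + 50 * sin(th))))
  tg <- estimate_tangents(circ)
  rad <- cbind(circ[, 1] - 60, circ[, 2] - 60)
  rad <- rad / sqrt(rowSums(rad^2))
  dots <- abs(rowSums(tg * rad))
  inner <- 6:(nrow(circ) - 5)
  expect_lt(max(dots[inner]), 0.1)
  # sine curve: within 6 degrees of the analytic derivative (the moving-
  # average smoothing biases tangents slightly where curvature is high)
  x <- seq(0, 120, by = 0.5)
  sn <- thin_centerline(vessel_trace("s", "venule", cbind(x, 40 + 10 * sin(x / 20))))
  tg <- estimate_tangents(sn)
  ana <- cbind(1, 0.5 * cos(sn[, 1] / 20))
  ana <- ana / sqrt(rowSums(ana^2))
  ang <- acos(pmin(1, abs(rowSums(tg * ana)))) * 180 / pi
  expect_lt(max(ang[6:(nrow(sn) - 5)]), 6)
})

test_that("perpendicular slices reproduce aligned and rotated rectangular profiles", {
  img <- matrix(0, 80, 80)
  nb <- straight_vessel_case(10, 0)
  chain <- thin_centerline(nb$trace)
  norm <- normalize_brightness(nb$image,
                               dilate_centerline(chain, 16, dim(nb$image)))
  tg <- estimate_tangents(chain)
  sl0 <- extract_perpendicular_slices(norm$image, chain, tg, 15)
  # constant image -> constant profiles
  flat <- extract_perpendicular_slices(matrix(3, 60, 60),
                                       cbind(x = 20L:40L, y = rep(30L, 21)),
                                       cbind(rep(1, 21), rep(0, 21)), 8)
  expect_true(all(abs(flat$profiles - 3) < 1e-12))
  # rotated vessel: ensemble profile matches the unrotated one closely
  rt <- straight_vessel_case(10, 30)
  chain_r <- thin_centerline(rt$trace)
  norm_r <- normalize_brightness(rt$image,
                                 dilate_centerline(chain_r, 16, dim(rt$image)))
  tg_r <- estimate_tangents(chain_r)
  sl1 <- extract_perpendicular_slices(norm_r$image, chain_r, tg_r, 15)
  p0 <- colMeans(sl0$profiles)
  p1 <- colMeans(sl1$profiles)
  expect_lt(max(abs(p0 - p1)), 0.1)
})

test_that("reference-circle clipping keeps strictly-inside points", {
  chain <- cbind(x = 0L:999L, y = rep(500L, 1000))
  circle <- reference_circle(c(500, 500), 1720, 2)  # P6 circle at 2 um/px
  kept <- clip_to_circle(chain, circle)
  expect_true(all(abs(chain[kept, 1] - 500) < 430))
  expect_equal(length(kept), sum(abs(chain[, 1] - 500) < 430))
  # tiny circle through the chain keeps only the nearest point
  tiny <- reference_circle(c(500, 500), 0.5, 2)
  expect_equal(clip_to_circle(chain, tiny), 501)
  # fully outside -> error
  far <- reference_circle(c(500, 50), 100, 2)
  expect_error(clip_to_circle(chain, far), "outside")
  # shrinking the circle never increases the number of kept slices
  ds <- seq(1720, 120, by = -200)
  ns <- vapply(ds, function(d) length(clip_to_circle(
    chain, reference_circle(c(500, 500), d, 2))), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("ensemble averaging is idempotent, linear, and dilutes side branches", {
  prof <- sin(seq(0, pi, length.out = 41))
  m <- matrix(rep(prof, 30), nrow = 30, byrow = TRUE)
  expect_equal(as.numeric(ensemble_average(m)), prof)
  expect_error(ensemble_average(m[1:5, ]), "slices")
  # 5% of slices corrupted by a bright side branch of amplitude 2
  m2 <- m
  branch <- 2 * exp(-(seq(-20, 20) - 12)^2 / 8)
  m2[1:2, ] <- m2[1:2, ] + rep(branch, each = 2)
  dev <- max(abs(ensemble_average(m2) - prof))
  expect_lt(dev, 0.05 * 2 * 2)   # < 5% of branch amplitude (2/40 slices ~ 5%)
  # linearity over sub-populations
  a <- m + 0.2; b <- m - 0.1
  ens <- ensemble_average(rbind(a, b), min_slices = 10)
  expect_equal(as.numeric(ens),
               as.numeric(0.5 * ensemble_average(a, 10) + 0.5 * ensemble_average(b, 10)))
})

test_that("mid-brightness width handles plateaus and interpolated crossings", {
  offs <- -8:8
  prof <- c(0, 0, 0, 0, 0, 0, 0.2, 0.8, 1, 1, 1, 0.8, 0.2, 0, 0, 0, 0)
  w <- width_at_midbrightness(prof, -8:8, pixel_scale = 2)
  expect_equal(w$width_px, 5)
  expect_equal(w$width_um, 10)
  expect_equal(w$mid_brightness_level, 0.5)
  # the worked linear-interpolation case: crossings half-way up the flanks
  prof2 <- c(0, 0, 0, 0.2, 0.8, 1, 1, 0.8, 0.2, 0, 0, 0, 0)
  w2 <- width_at_midbrightness(prof2, seq_along(prof2) - 7, pixel_scale = 1)
  expect_equal(w2$width_px, 4)
  # open flank errors; secondary lobe warns
  expect_error(width_at_midbrightness(c(0, 0.4, 1, 1, 1), 1:5, 1), "enclosed")
  lobed <- c(0, 0.8, 0, 0, 0.3, 1, 1, 0.3, 0, 0)
  expect_warning(wl <- width_at_midbrightness(lobed, 1:10, 1), "lobe")
  expect_lt(wl$width_px, 4)
})

test_that("full pipeline recovers noiseless synthetic widths and is rotation tolerant", {
  r <- measure_straight_vessel(15, 10)
  expect_equal(r$width_um, 30, tolerance = 0.5 / 30)
  r0 <- measure_straight_vessel(12, 0)
  r45 <- measure_straight_vessel(12, 45)
  expect_lt(abs(r45$width_um - r0$width_um) / r0$width_um, 0.02)
  # moderate noise: within 5% of truth (noise at 10% of vessel contrast)
  rn <- measure_straight_vessel(12, 25, noise_sd = 8, seed = 4)
  expect_lt(abs(rn$width_um - 24) / 24, 0.05)
})

test_that("pipeline errors carry the vessel id", {
  cs <- straight_vessel_case(10, 0)
  far <- reference_circle(c(-500, -500), 100, 2)
  expect_error(measure_vessel(cs$image, cs$trace, far, cs$config), "V01")
})

test_that("width scales with pixel_scale but not with pixel geometry", {
  a <- measure_straight_vessel(10, 15, scale = 2)
  b <- measure_straight_vessel(10, 15, scale = 4)   # same px geometry
  expect_equal(a$width_px, b$width_px, tolerance = 1e-10)
  expect_equal(b$width_um, 2 * a$width_um, tolerance = 1e-10)
})

test_that("width estimates are stable under affine intensity transforms", {
  cs <- straight_vessel_case(12, 30)
  r1 <- measure_vessel(cs$image, cs$trace, cs$circle, cs$config)
  r2 <- measure_vessel(2.5 * cs$image + 37, cs$trace, cs$circle, cs$config)
  expect_equal(r1$width_px, r2$width_px, tolerance = 1e-9)
})

test_that("estimated width increases strictly with true Gaussian FWHM", {
  widths <- c(6, 9, 12, 16, 20)
  est <- vapply(widths, function(w)
    measure_straight_vessel(w, 20, shape = "gaussian")$width_px, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("retina and mouse summaries follow the per-class averaging rules", {
  mk <- function(id, cl, w) {
    r <- list(vessel_id = id, width_um = w, vessel_class = cl)
    class(r) <- "width_result"
    r
  }
  s <- summarize_retina(list(mk("a1", "arteriole", 10), mk("a2", "arteriole", 12),
                             mk("v1", "venule", 20)), "R1")
  expect_equal(s$mean_width_um[s$class == "arteriole"], 11)
  expect_equal(s$vessel_count[s$class == "arteriole"], 2)
  expect_equal(s$mean_width_um[s$class == "venule"], 20)
  # empty class: count 0, mean absent
  s2 <- summarize_retina(list(mk("a1", "arteriole", 10)), "R2")
  expect_equal(s2$vessel_count[s2$class == "venule"], 0)
  expect_true(is.na(s2$mean_width_um[s2$class == "venule"]))
  # mouse = mean of retina-level values
  two <- rbind(
    data.frame(retina_id = "R1", class = "venule", vessel_count = 3, mean_width_um = 18),
    data.frame(retina_id = "R2", class = "venule", vessel_count = 5, mean_width_um = 22))
  m <- summarize_mouse(two, "M1")
  expect_equal(m$mean_width_um[m$class == "venule"], 20)
  expect_equal(m$vessel_count[m$class == "venule"], 4)
})

test_that("tortuosity matches closed forms and quadrature", {
  expect_equal(tortuosity(rbind(c(0, 0), c(10, 3))), 1)
  th <- seq(0, pi, length.out = 2000)
  semi <- cbind(cos(th), sin(th))
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-5)
  # sine arc vs numeric quadrature
  x <- seq(0, 40 * pi, length.out = 8000)
  curve <- cbind(x, 10 * sin(x / 20))
  arc <- integrate(function(u) sqrt(1 + (0.5 * cos(u / 20))^2), 0, 40 * pi,
                   subdivisions = 2000)$value
  expect_equal(tortuosity(curve), arc / (40 * pi), tolerance = 0.005)
  expect_error(tortuosity(rbind(c(0, 0), c(1, 1), c(0, 0))), "chord")
})

test_that("box-counting dimension matches line, plane, and a brute-force oracle", {
  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  expect_equal(fractal_dimension(line), 1, tolerance = 0.05)
  square <- matrix(TRUE, 64, 64)
  expect_equal(fractal_dimension(square), 2, tolerance = 0.05)
  expect_error(fractal_dimension(matrix(TRUE, 8, 8)), "octaves")
  # branching tree: compare against an independent dense box counter
  tree <- matrix(FALSE, 128, 128)
  seg <- function(m, x0, y0, x1, y1) {
    n <- 400
    xs <- round(seq(x0, x1, length.out = n)); ys <- round(seq(y0, y1, length.out = n))
    m[cbind(pmax(1, pmin(128, ys)), pmax(1, pmin(128, xs)))] <- TRUE
    m
  }
  tree <- seg(tree, 64, 120, 64, 70)
  tree <- seg(tree, 64, 70, 30, 30); tree <- seg(tree, 64, 70, 98, 30)
  tree <- seg(tree, 30, 30, 12, 8); tree <- seg(tree, 30, 30, 52, 8)
  tree <- seg(tree, 98, 30, 76, 8); tree <- seg(tree, 98, 30, 120, 8)
  oracle <- function(mask) {
    sizes <- 2^(0:6)   # same dyadic ladder the package uses for 128 px
    counts <- vapply(sizes, function(s) {
      idx <- which(mask, arr.ind = TRUE)
      nrow(unique(cbind((idx[, 1] - 1) %/% s, (idx[, 2] - 1) %/% s)))
    }, numeric(1))
    unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
  }
  expect_equal(fractal_dimension(tree), oracle(tree), tolerance = 0.02)
})
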