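# Synthetic ERG sweeps with known ground truth: a Lamb-Pugh A-wave component,
# a Naka-Rushton-scaled unimodal B-wave, a Gabor packet of oscillatory
# potentials on the B-wave rising phase, and seeded white noise per sweep.

#' Specification of a synthetic ERG recording
#'
#' The defaults emulate a dark-adapted mouse Ganzfeld recording: green 1-ms
#' flashes over a log-intensity ladder, sweep averaging, a saturated rod
#' response near 300 uV and a B-wave saturating near 400 uV.
#'
#' @param intensities Flash energies, log10 cd.s/m^2.
#' @param sampling_rate Hz.
#' @param flash_onset ms from sweep start (>= 50 ms of baseline).
#' @param duration Sweep duration, ms.
#' @param r_max,t_c,t_d Lamb-Pugh activation parameters (uV, ms, ms).
#' @param a_sat_ms Time after onset at which the photoreceptor component is
#'   held at its leading-edge value; the activation model describes only the
#'   leading edge, and recovery dynamics are out of scope.
#' @param vmax,k,n_exponent Naka-Rushton parameters; `k` is the linear
#'   semi-saturation energy in cd.s/m^2.
#' @param b_peak_ms,b_width_ms Peak time and FWHM of the B-wave template.
#' @param op_freq_hz,op_envelope_ms,op_pp_uv Gabor OP packet: carrier
#'   frequency, Gaussian envelope SD, and peak-to-peak amplitude.
#' @param noise_sd White Gaussian noise SD per sweep, uV.
#' @param n_sweeps Sweeps per intensity.
#' @param seed Integer RNG seed.
#' @return A `synthetic_erg_spec` object.
#' @export
synthetic_erg_spec <- function(intensities = seq(-4.7, 1.0, by = 0.3),
                               sampling_rate = 2000, flash_onset = 60,
                               duration = 400,
                               r_max = 300, t_c = 18, t_d = 4, a_sat_ms = 20,
                               vmax = 400, k = 0.01, n_exponent = 1,
                               b_peak_ms = 100, b_width_ms = 60,
                               op_freq_hz = 120, op_envelope_ms = 10,
                               op_pp_uv = 40,
                               noise_sd = 5, n_sweeps = 10, seed = 1) {
  stopifnot(length(intensities) >= 1, sampling_rate > 0,
            flash_onset >= 50, duration > flash_onset,
            r_max > 0, t_c > 0, t_d >= 0, a_sat_ms > t_d,
            vmax > 0, k > 0, n_exponent > 0,
            b_peak_ms > 0, b_width_ms > 0,
            op_envelope_ms > 0, op_pp_uv >= 0,
            noise_sd >= 0, n_sweeps >= 1)
  # the OP carrier must sit strictly above the B-template's spectral support
  if (op_pp_uv > 0 && op_freq_hz < 4 * 1000 / b_width_ms) {
    stopf("op_freq_hz too close to the B-wave template band")
  }
  if (sampling_rate <= 2 * op_freq_hz) stopf("sampling_rate below OP Nyquist")
  structure(
    list(intensities = intensities, sampling_rate = sampling_rate,
         flash_onset = flash_onset, duration = duration,
         r_max = r_max, t_c = t_c, t_d = t_d, a_sat_ms = a_sat_ms,
         vmax = vmax, k = k, n_exponent = n_exponent,
         b_peak_ms = b_peak_ms, b_width_ms = b_width_ms,
         op_freq_hz = op_freq_hz, op_envelope_ms = op_envelope_ms,
         op_pp_uv = op_pp_uv, noise_sd = noise_sd,
         n_sweeps = as.integer(n_sweeps), seed = as.integer(seed)),
    class = "synthetic_erg_spec"
  )
}

# Noise-free composite voltage at one intensity on a given time grid.
erg_clean_voltage <- function(spec, intensity_log, time_ms) {
  intensity <- 10^intensity_log
  tt <- time_ms - spec$flash_onset
  # photoreceptor component: Lamb-Pugh leading edge, held past a_sat_ms
  a_comp <- -lamb_pugh_response(pmin(pmax(tt, 0), spec$a_sat_ms), intensity,
                                spec$r_max, spec$t_c, spec$t_d)
  frac <- intensity^spec$n_exponent /
    (intensity^spec$n_exponent + spec$k^spec$n_exponent)
  b_comp <- spec$vmax * frac * b_wave_template(tt, spec$b_peak_ms, spec$b_width_ms)
  op_center <- spec$b_peak_ms - spec$b_width_ms / 2  # B-wave rising phase
  o_comp <- op_packet(tt, op_center, spec$op_freq_hz, spec$op_envelope_ms,
                      spec$op_pp_uv)
  a_comp + b_comp + o_comp
}

#' Generate synthetic ERG sweeps at one intensity
#'
#' Composes voltage(t) = -P3(t) + B(t) + OP(t) + noise: the negative of the
#' Lamb-Pugh activation response (held at its leading-edge value past the
#' trough), the unimodal B-wave template scaled by the Naka-Rushton amplitude
#' at this intensity, a Gabor OP packet on the B-wave rising phase, and
#' independent white Gaussian noise per sweep. Identical spec and seed give
#' bit-identical sweeps.
#'
#' @param spec A [synthetic_erg_spec()].
#' @param intensity_log One of `spec$intensities` (log10 cd.s/m^2).
#' @param seed Optional seed override; defaults to `spec$seed` offset by the
#'   index of the intensity within the spec.
#' @return An `erg_sweeps` object: `time`, `sweeps` matrix (samples x
#'   sweeps), the noise-free `clean` trace, and metadata.
#' @export
generate_erg_sweeps <- function(spec, intensity_log, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_erg_spec"))
  idx <- which(abs(spec$intensities - intensity_log) < 1e-9)
  if (length(idx) == 0) stopf("intensity %.2f not in spec", intensity_log)
  time_ms <- seq(0, spec$duration, by = 1000 / spec$sampling_rate)
  clean <- erg_clean_voltage(spec, intensity_log, time_ms)
  seed <- seed %||% (spec$seed + idx[1])
  nt <- length(time_ms)
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed, matrix(stats::rnorm(nt * spec$n_sweeps, 0, spec$noise_sd),
                           nt, spec$n_sweeps))
  } else {
    matrix(0, nt, spec$n_sweeps)
  }
  structure(
    list(time = time_ms, sweeps = clean + noise, clean = clean,
         intensity = intensity_log, flash_onset = spec$flash_onset,
         sampling_rate = spec$sampling_rate, n_sweeps = spec$n_sweeps),
    class = "erg_sweeps"
  )
}

#' Generate a full synthetic intensity series
#'
#' @param spec A [synthetic_erg_spec()].
#' @return Named list of `erg_sweeps`, one per intensity.
#' @export
generate_erg_series <- function(spec) {
  out <- lapply(spec$intensities, function(i) generate_erg_sweeps(spec, i))
  names(out) <- sprintf("%.1f", spec$intensities)
  out
}

#' Write ERG sweeps as CSV plus JSON sidecar
#'
#' CSV columns are `time_ms, sweep_001, ...`; the sidecar records
#' `intensity_log_cd_s_m2`, `flash_onset_ms`, and `sampling_rate_hz`.
#'
#' @param sweeps An `erg_sweeps` object.
#' @param dir Output directory.
#' @param stem File stem.
#' @return Invisibly, the two paths.
#' @export
write_erg_dataset <- function(sweeps, dir, stem = "erg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  jsn <- file.path(dir, paste0(stem, ".json"))
  m <- as.data.frame(sweeps$sweeps)
  names(m) <- sprintf("sweep_%03d", seq_len(ncol(m)))
  utils::write.csv(cbind(time_ms = sweeps$time, m), csv, row.names = FALSE)
  jsonlite::write_json(
    list(intensity_log_cd_s_m2 = sweeps$intensity,
         flash_onset_ms = sweeps$flash_onset,
         sampling_rate_hz = sweeps$sampling_rate),
    jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = jsn))
}

#' Read ERG sweeps from CSV plus JSON sidecar
#'
#' @param csv_path Sweep CSV path; the sidecar is `<stem>.json` next to it
#'   unless given explicitly.
#' @param json_path Optional sidecar path.
#' @return An `erg_sweeps` object.
#' @export
read_erg_sweeps <- function(csv_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.csv$", ".json", csv_path)
  d <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(
    list(time = d$time_ms,
         sweeps = as.matrix(d[, setdiff(names(d), "time_ms"), drop = FALSE]),
         clean = NULL,
         intensity = meta$intensity_log_cd_s_m2,
         flash_onset = meta$flash_onset_ms,
         sampling_rate = meta$sampling_rate_hz,
         n_sweeps = ncol(d) - 1L),
    class = "erg_sweeps"
  )
}
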