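# ERG waveform feature extraction: sweep averaging, A/B-wave amplitudes and
# peak times, and FFT band separation of the oscillatory potentials.

#' Construct an averaged ERG trace
#'
#' @param time Uniform time grid, ms.
#' @param voltage Sweep-averaged voltage, uV.
#' @param flash_onset Flash onset, ms (must lie in the time range, with at
#'   least 50 ms of prestimulus baseline).
#' @param intensity Flash energy, log10 cd.s/m^2.
#' @param sampling_rate Hz.
#' @param n_sweeps Number of sweeps averaged.
#' @return An `erg_trace` object.
#' @export
erg_trace <- function(time, voltage, flash_onset, intensity = NA_real_,
                      sampling_rate = NULL, n_sweeps = 1L) {
  stopifnot(length(time) == length(voltage), length(time) >= 4)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stopf("time grid is not uniform")
  if (flash_onset <= min(time) || flash_onset >= max(time)) {
    stopf("flash_onset outside the time range")
  }
  if (flash_onset - min(time) < 50) {
    warnf("less than 50 ms of prestimulus baseline")
  }
  structure(
    list(time = as.numeric(time), voltage = as.numeric(voltage),
         flash_onset = flash_onset, intensity = intensity,
         sampling_rate = sampling_rate %||% (1000 / dt[1]),
         n_sweeps_averaged = as.integer(n_sweeps)),
    class = "erg_trace"
  )
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> %.1f log cd.s/m2, %d samples @ %g Hz, %d sweeps averaged\n",
              x$intensity, length(x$time), x$sampling_rate, x$n_sweeps_averaged))
  invisible(x)
}

#' @export
plot.erg_trace <- function(x, ...) {
  plot(x$time, x$voltage, type = "l", xlab = "time (ms)",
       ylab = "voltage (uV)", ...)
  graphics::abline(v = x$flash_onset, lty = 3)
  invisible(x)
}

#' Average sweeps into one trace
#'
#' Pointwise mean over sweeps sharing one time grid.
#'
#' @param sweeps An `erg_sweeps` object, or a list of `erg_trace` objects on
#'   identical grids.
#' @return An `erg_trace` with `n_sweeps_averaged` recorded.
#' @export
average_sweeps <- function(sweeps) {
  if (inherits(sweeps, "erg_sweeps")) {
    return(erg_trace(sweeps$time, rowMeans(sweeps$sweeps), sweeps$flash_onset,
                     sweeps$intensity, sweeps$sampling_rate, ncol(sweeps$sweeps)))
  }
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  t0 <- sweeps[[1]]$time
  for (s in sweeps) {
    if (!isTRUE(all.equal(s$time, t0))) stopf("sweeps have mismatched time grids")
  }
  v <- rowMeans(vapply(sweeps, `[[`, numeric(length(t0)), "voltage"))
  erg_trace(t0, v, sweeps[[1]]$flash_onset, sweeps[[1]]$intensity,
            sweeps[[1]]$sampling_rate, length(sweeps))
}

#' A-wave amplitude and peak time
#'
#' Amplitude is measured from the prestimulus baseline (mean voltage over the
#' `baseline_ms` before flash onset) to the most negative trough inside the
#' post-flash search window, floored at 0 when no negative deflection exists
#' (in which case the peak time is absent). Peak time is measured from flash
#' onset.
#'
#' @param trace An `erg_trace`.
#' @param baseline_ms Baseline window length before onset.
#' @param search_ms Post-flash search window `c(from, to)`, ms.
#' @return List: `a_amplitude`, `a_peak_time` (ms post-flash, `NA` if no
#'   trough), `baseline`, `trough_voltage`, `trough_time` (absolute ms).
#' @export
measure_a_wave <- function(trace, baseline_ms = 50, search_ms = c(5, 60)) {
  t <- trace$time; v <- trace$voltage; on <- trace$flash_onset
  bsel <- t >= on - baseline_ms & t < on
  if (!any(bsel)) stopf("no prestimulus baseline samples")
  baseline <- mean(v[bsel])
  wsel <- which(t >= on + search_ms[1] & t <= on + search_ms[2])
  if (length(wsel) == 0) stopf("A-wave search window outside the trace")
  imin <- wsel[which.min(v[wsel])]
  amp <- baseline - v[imin]
  if (amp <= 0) {
    return(list(a_amplitude = 0, a_peak_time = NA_real_, baseline = baseline,
                trough_voltage = NA_real_, trough_time = NA_real_))
  }
  list(a_amplitude = amp, a_peak_time = t[imin] - on, baseline = baseline,
       trough_voltage = v[imin], trough_time = t[imin])
}

#' B-wave amplitude and peak time
#'
#' Measured from the trough of the A-wave to the most positive peak that
#' follows. For weak flashes without an A-wave trough, the amplitude is
#' measured from the prestimulus baseline (documented fallback) and the
#' search starts at flash onset.
#'
#' @param trace An `erg_trace`.
#' @param a_result Output of [measure_a_wave()] for the same trace.
#' @param window_end_ms End of the peak search window, ms post-flash.
#' @return List: `b_amplitude`, `b_peak_time` (ms post-flash),
#'   `peak_voltage`, `peak_time` (absolute ms), `reference` used.
#' @export
measure_b_wave <- function(trace, a_result = measure_a_wave(trace),
                           window_end_ms = 200) {
  t <- trace$time; v <- trace$voltage; on <- trace$flash_onset
  has_trough <- is.finite(a_result$trough_time)
  start <- if (has_trough) a_result$trough_time else on
  ref <- if (has_trough) a_result$trough_voltage else a_result$baseline
  wsel <- which(t >= start & t <= on + window_end_ms)
  if (length(wsel) == 0) stopf("B-wave search window exhausted")
  imax <- wsel[which.max(v[wsel])]
  list(b_amplitude = max(0, v[imax] - ref), b_peak_time = t[imax] - on,
       peak_voltage = v[imax], peak_time = t[imax],
       reference = if (has_trough) "a_trough" else "baseline")
}

#' Separate oscillatory potentials by FFT band filtering
#'
#' A cosine-tapered copy of the analysis window (flash onset to the B-wave
#' peak plus 50 ms, unless given) is forward transformed, bins outside the
#' two-sided band are zeroed, and the inverse transform gives the OP
#' waveform. The OP magnitude is its most positive peak minus its most
#' negative peak inside the window.
#'
#' @param trace An `erg_trace`.
#' @param band_hz Passband `c(lo, hi)`, Hz; `hi` must be below Nyquist.
#' @param window_ms Optional absolute analysis window `c(from, to)`, ms.
#' @param taper Tukey taper fraction applied to each end of the window.
#' @return List: `time`, `op_waveform`, `op_magnitude`, `band_hz`.
#' @export
extract_ops <- function(trace, band_hz = c(60, 235), window_ms = NULL,
                        taper = 0.3) {
  fs <- trace$sampling_rate
  if (band_hz[2] >= fs / 2) stopf("band upper edge above Nyquist frequency")
  stopifnot(band_hz[1] > 0, band_hz[1] < band_hz[2])
  if (is.null(window_ms)) {
    b <- measure_b_wave(trace)
    window_ms <- c(trace$flash_onset, b$peak_time + 50)
  }
  sel <- which(trace$time >= window_ms[1] & trace$time <= window_ms[2])
  if (length(sel) < 8) stopf("analysis window too short")
  x <- trace$voltage[sel]
  n <- length(x)
  x <- (x - mean(x)) * tukey_window(n, taper)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # two-sided (symmetric) frequency
  X <- stats::fft(x)
  X[f < band_hz[1] | f > band_hz[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  list(time = trace$time[sel], op_waveform = y,
       op_magnitude = max(y) - min(y), band_hz = band_hz)
}

tukey_window <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  w <- rep(1, n)
  k <- floor(alpha * (n - 1) / 2)
  if (k >= 1) {
    i <- 0:k
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (alpha * (n - 1)) - 1)))
    w[i + 1] <- ramp
    w[n - i] <- ramp
  }
  w
}

#' Build a flash stimulus protocol
#'
#' Enumerates the inclusive arithmetic intensity ladder and attaches the
#' interstimulus interval rule: dark-adapted runs use 0.7 s between flashes
#' up to -2.0 log cd.s/m^2 and 10 s above; light-adapted runs use 10 s
#' throughout. More flashes are averaged for dim stimuli (20) than for
#' bright ones (5), within the 5-20 range typical of offline averaging.
#'
#' @param adaptation `"dark"` or `"light"`.
#' @param start,stop First and last intensity, log10 cd.s/m^2.
#' @param step Increment, log10 cd.s/m^2 (> 0).
#' @return A `stimulus_protocol`: data frame of `intensity_log`, `isi_s`,
#'   `n_flashes`, with the adaptation state as an attribute.
#' @export
build_protocol <- function(adaptation = c("dark", "light"), start, stop,
                           step = 0.3) {
  adaptation <- match.arg(adaptation)
  if (step <= 0) stopf("step must be positive")
  if (stop <= start) stopf("stop must exceed start")
  n <- floor((stop - start) / step + 1e-9)
  intensities <- start + step * (0:n)
  isi <- if (adaptation == "dark") {
    ifelse(intensities <= -2.0 + 1e-9, 0.7, 10)
  } else {
    rep(10, length(intensities))
  }
  out <- data.frame(intensity_log = intensities, isi_s = isi,
                    n_flashes = ifelse(isi < 10, 20L, 5L))
  attr(out, "adaptation") <- adaptation
  attr(out, "step") <- step
  class(out) <- c("stimulus_protocol", "data.frame")
  out
}

#' Analyze a full intensity series
#'
#' Extracts A/B-wave features and OP magnitudes per intensity, fits the
#' Naka-Rushton function to the B-wave amplitudes over `nr_range`, and fits
#' the activation model to the A-wave leading edges over `lp_range`.
#'
#' @param traces List of `erg_trace`, one per intensity.
#' @param nr_range Intensity range (log10 cd.s/m^2) for the Naka-Rushton fit.
#' @param lp_range Intensity range for the activation-phase fit.
#' @param op_band OP passband, Hz.
#' @param nr_n_mode `"fixed"` (exponent 1) or `"free"`.
#' @param lp_shared Fit shared (t_c, t_d) across intensities (`TRUE`) or one
#'   fit per intensity (`FALSE`).
#' @return An `erg_series_analysis`: `features` data frame plus
#'   `naka_rushton` and `lamb_pugh` fits (either may be `NULL` when too few
#'   usable intensities fall in the stated range).
#' @export
analyze_intensity_series <- function(traces, nr_range = c(-3.8, 1.0),
                                     lp_range = c(-1.1, 2.2),
                                     op_band = c(60, 235),
                                     nr_n_mode = c("fixed", "free"),
                                     lp_shared = TRUE) {
  nr_n_mode <- match.arg(nr_n_mode)
  if (length(traces) == 0) stopf("empty intensity series")
  rows <- lapply(traces, function(tr) {
    a <- measure_a_wave(tr)
    b <- measure_b_wave(tr, a)
    op <- tryCatch(extract_ops(tr, op_band)$op_magnitude,
                   error = function(e) NA_real_)
    data.frame(intensity_log = tr$intensity,
               a_amplitude_uv = a$a_amplitude, a_peak_ms = a$a_peak_time,
               b_amplitude_uv = b$b_amplitude, b_peak_ms = b$b_peak_time,
               op_magnitude_uv = op)
  })
  features <- do.call(rbind, rows)
  features <- features[order(features$intensity_log), , drop = FALSE]
  rownames(features) <- NULL
  nr_sel <- features$intensity_log >= nr_range[1] - 1e-9 &
    features$intensity_log <= nr_range[2] + 1e-9
  nr_fit <- if (sum(nr_sel) >= 4) {
    tryCatch(fit_naka_rushton(features$intensity_log[nr_sel],
                              features$b_amplitude_uv[nr_sel],
                              n_mode = nr_n_mode),
             error = function(e) { warnf("Naka-Rushton fit failed: %s",
                                         conditionMessage(e)); NULL })
  } else NULL
  ints <- vapply(traces, `[[`, numeric(1), "intensity")
  lp_traces <- traces[ints >= lp_range[1] - 1e-9 & ints <= lp_range[2] + 1e-9]
  lp_fit <- if (length(lp_traces) >= 1) {
    tryCatch(fit_lamb_pugh(lp_traces, shared = lp_shared),
             error = function(e) { warnf("activation-phase fit failed: %s",
                                         conditionMessage(e)); NULL })
  } else NULL
  structure(list(features = features, naka_rushton = nr_fit,
                 lamb_pugh = lp_fit),
            class = "erg_series_analysis")
}

#' @export
print.erg_series_analysis <- function(x, ...) {
  cat("ERG intensity-series analysis\n")
  print(x$features, digits = 4)
  if (!is.null(x$naka_rushton)) print(x$naka_rushton)
  if (!is.null(x$lamb_pugh)) print(x$lamb_pugh)
  invisible(x)
}
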