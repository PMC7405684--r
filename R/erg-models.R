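# Model functions for ERG analysis. Each physiological form is isolated in a
# single function so the parameterization can be swapped without touching the
# fitting or generating code.

#' Phototransduction activation model (Lamb-Pugh form)
#'
#' Delayed, intensity-scaled rising response describing the leading edge of
#' the A-wave:
#' \deqn{R(t; I) = R_{max} (1 - \exp[-\tfrac{1}{2} (I/I_{ref}) ((t - t_d)/t_c)^2])}
#' for t > t_d and 0 otherwise, with I the linear flash energy in
#' cd.s/m^2 (I_ref = 1 cd.s/m^2), t_c the characteristic time constant of
#' transduction (ms) and t_d the response delay (ms).
#'
#' @param t_ms Time after flash onset, ms.
#' @param intensity_cds Flash energy, linear cd.s/m^2.
#' @param r_max Maximal response amplitude, uV.
#' @param t_c Time constant, ms (> 0).
#' @param t_d Delay, ms (>= 0).
#' @return Response in uV (positive-going; the recorded A-wave is its
#'   negative).
#' @export
lamb_pugh_response <- function(t_ms, intensity_cds, r_max, t_c, t_d) {
  stopifnot(t_c > 0, t_d >= 0, r_max > 0)
  out <- numeric(length(t_ms))
  on <- t_ms > t_d
  out[on] <- r_max * (1 - exp(-0.5 * intensity_cds * ((t_ms[on] - t_d) / t_c)^2))
  out
}

#' Naka-Rushton intensity-response function
#'
#' Saturating hyperbolic relation
#' \deqn{V(I) = V_{max} I^n / (I^n + K^n)}
#' with I the linear flash energy; K is the semi-saturation energy at which
#' V = Vmax/2 for any exponent n.
#'
#' @param intensity_cds Linear flash energy, cd.s/m^2.
#' @param vmax Saturated amplitude, uV.
#' @param k Semi-saturation energy, linear cd.s/m^2 (> 0).
#' @param n Hill-type exponent (default 1).
#' @return Response amplitude, uV.
#' @export
naka_rushton_response <- function(intensity_cds, vmax, k, n = 1) {
  stopifnot(vmax > 0, k > 0, n > 0)
  vmax * intensity_cds^n / (intensity_cds^n + k^n)
}

# Unimodal B-wave template: log-normal-shaped bump in time since flash onset,
# peak value 1 at `peak_ms`, full width at half maximum `width_ms`. Smooth,
# positive, spectrally concentrated at low frequency; no claim of
# physiological fidelity.
b_wave_template <- function(t_ms, peak_ms = 100, width_ms = 60) {
  stopifnot(peak_ms > 0, width_ms > 0)
  s <- asinh(width_ms / (2 * peak_ms)) / sqrt(2 * log(2))
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  out[pos] <- exp(-(log(t_ms[pos] / peak_ms))^2 / (2 * s^2))
  out
}

# Gaussian-windowed sinusoid (Gabor packet) emulating oscillatory potentials
# superimposed on the ascending phase of the B-wave. Support is hard-limited
# to +/- 3 envelope widths (99.7% of the Gaussian energy) so the packet stays
# confined to the ascending phase; the packet is rescaled on the supplied
# time grid so its peak-to-peak excursion equals `pp_uv`.
op_packet <- function(t_ms, center_ms, freq_hz, envelope_ms, pp_uv) {
  if (pp_uv == 0) return(numeric(length(t_ms)))
  g <- exp(-(t_ms - center_ms)^2 / (2 * envelope_ms^2)) *
    sin(2 * pi * freq_hz * (t_ms - center_ms) / 1000)
  g[abs(t_ms - center_ms) > 3 * envelope_ms] <- 0
  span <- max(g) - min(g)
  if (span == 0) return(numeric(length(t_ms)))
  g * (pp_uv / span)
}
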