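# Least-squares fits of the intensity-response (Naka-Rushton) and
# activation-phase (Lamb-Pugh) models, with multi-start initialization to
# avoid local minima. Both return classed objects with the usual modelling
# methods.

#' Fit the Naka-Rushton intensity-response function
#'
#' Least-squares fit of V(I) = Vmax I^n / (I^n + K^n) to B-wave amplitudes,
#' with the intensity linearized internally (I = 10^log10-intensity) and K
#' reported back in log10 cd.s/m^2. Vmax is profiled in closed form at each
#' candidate (K, n); K is multi-started on a log-spaced grid across the
#' observed intensity range and polished numerically. In the weak-stimulus
#' limit (I << K, n = 1) the fitted curve is linear in I, recovering the
#' linear range of the amplitude-energy relation.
#'
#' @param intensity_log Flash energies, log10 cd.s/m^2 (>= 4 points spanning
#'   at least 2 log units).
#' @param amplitude_uv Response amplitudes, uV (same length).
#' @param n_mode `"fixed"` (exponent held at `n_value`) or `"free"`.
#' @param n_value Exponent used when `n_mode = "fixed"`.
#' @return A `naka_rushton_fit` with coefficients `vmax_uv`, `k_log`
#'   (log10 cd.s/m^2), `n`, plus `rss` and the intensity range used.
#' @export
fit_naka_rushton <- function(intensity_log, amplitude_uv,
                             n_mode = c("fixed", "free"), n_value = 1) {
  n_mode <- match.arg(n_mode)
  if (is.data.frame(intensity_log)) {
    amplitude_uv <- intensity_log[[2]]
    intensity_log <- intensity_log[[1]]
  }
  stopifnot(length(intensity_log) == length(amplitude_uv))
  ok <- is.finite(intensity_log) & is.finite(amplitude_uv)
  intensity_log <- intensity_log[ok]; amplitude_uv <- amplitude_uv[ok]
  if (length(intensity_log) < 4) stopf("need at least 4 points")
  if (diff(range(intensity_log)) < 2) stopf("points must span at least 2 log units")
  I <- 10^intensity_log
  V <- amplitude_uv

  profile_rss <- function(logk, n) {
    g <- I^n / (I^n + (10^logk)^n)
    vmax <- sum(V * g) / sum(g^2)
    if (!is.finite(vmax) || vmax <= 0) return(list(rss = Inf, vmax = NA_real_))
    list(rss = sum((V - vmax * g)^2), vmax = vmax)
  }

  k_grid <- seq(min(intensity_log) - 1, max(intensity_log) + 1, length.out = 25)
  if (n_mode == "fixed") {
    rss_grid <- vapply(k_grid, function(k) profile_rss(k, n_value)$rss, numeric(1))
    if (all(!is.finite(rss_grid))) stopf("Naka-Rushton fit did not converge (all starts degenerate)")
    k0 <- k_grid[which.min(rss_grid)]
    opt <- stats::optim(k0, function(p) profile_rss(p, n_value)$rss,
                        method = "Brent",
                        lower = min(k_grid) - 2, upper = max(k_grid) + 2,
                        control = list(reltol = 1e-14))
    k_log <- opt$par; n_hat <- n_value
  } else {
    starts <- expand.grid(k = k_grid[seq(1, 25, by = 4)],
                          logn = log(c(0.5, 1, 2)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(c(starts$k[s], starts$logn[s]),
                     function(p) profile_rss(p[1], exp(p[2]))$rss,
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best) || !is.finite(best$value)) {
      stopf("Naka-Rushton fit did not converge after multi-start")
    }
    k_log <- best$par[1]; n_hat <- exp(best$par[2])
  }
  pr <- profile_rss(k_log, n_hat)
  coefs <- c(vmax_uv = pr$vmax, k_log = k_log, n = n_hat)
  g <- I^n_hat / (I^n_hat + (10^k_log)^n_hat)
  structure(
    list(coefficients = coefs, rss = pr$rss,
         fitted.values = pr$vmax * g, residuals = V - pr$vmax * g,
         data = data.frame(intensity_log = intensity_log,
                           amplitude_uv = amplitude_uv),
         n_mode = n_mode,
         intensity_range_used = range(intensity_log)),
    class = "naka_rushton_fit"
  )
}

#' @export
coef.naka_rushton_fit <- function(object, ...) object$coefficients

#' @export
fitted.naka_rushton_fit <- function(object, ...) object$fitted.values

#' @export
residuals.naka_rushton_fit <- function(object, ...) object$residuals

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf(
    "Naka-Rushton fit (n %s): Vmax = %.1f uV, K = %.2f log cd.s/m2, n = %.3g, RSS = %.3g\n",
    x$n_mode, x$coefficients[["vmax_uv"]], x$coefficients[["k_log"]],
    x$coefficients[["n"]], x$rss))
  invisible(x)
}

#' Predict from a Naka-Rushton fit
#'
#' @param object A `naka_rushton_fit`.
#' @param newdata Intensities in log10 cd.s/m^2 (vector, or data frame with
#'   an `intensity_log` column). Defaults to the fitted intensities.
#' @param ... Unused.
#' @return Predicted amplitudes, uV.
#' @export
predict.naka_rushton_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$intensity_log
  else if (is.data.frame(newdata)) newdata$intensity_log
  else newdata
  cf <- object$coefficients
  naka_rushton_response(10^x, cf[["vmax_uv"]], 10^cf[["k_log"]], cf[["n"]])
}

#' @export
plot.naka_rushton_fit <- function(x, ...) {
  d <- x$data
  plot(d$intensity_log, d$amplitude_uv, xlab = "intensity (log cd.s/m2)",
       ylab = "B-wave amplitude (uV)", ...)
  xs <- seq(min(d$intensity_log), max(d$intensity_log), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Fit the activation-phase (Lamb-Pugh) model to A-wave leading edges
#'
#' Fits `R(t; I) = R_max (1 - exp(-(1/2) I ((t - t_d)/t_c)^2))` jointly to the
#' baseline-subtracted, sign-inverted leading edges of the supplied traces,
#' with R_max fixed at the maximal recorded A-wave amplitude (or a supplied
#' value) and (t_c, t_d) shared across intensities and free. Each trace
#' contributes samples from flash onset up to a fraction of its A-trough
#' time. Multi-start least squares over a t_d grid guards against local
#' minima.
#'
#' @param traces List of `erg_trace` objects (traces without a measurable
#'   A-wave trough are skipped).
#' @param r_max `"max_a_wave"` (default policy) or a numeric value in uV.
#' @param edge_fraction Fraction of the A-trough time ending each leading-
#'   edge window.
#' @param td_grid Multi-start grid for the delay, ms.
#' @param shared Fit one shared (t_c, t_d) across intensities (`TRUE`), or
#'   return per-intensity fits (`FALSE`).
#' @return A `lamb_pugh_fit` with coefficients `r_max_uv`, `t_c_ms`,
#'   `t_d_ms`, plus `rss`, the fit windows and intensity range used. With
#'   `shared = FALSE`, a list of per-intensity fits.
#' @export
fit_lamb_pugh <- function(traces, r_max = "max_a_wave", edge_fraction = 0.9,
                          td_grid = seq(0, 15, by = 1.5), shared = TRUE) {
  stopifnot(is.list(traces), length(traces) >= 1)
  if (!shared) {
    fits <- lapply(traces, function(tr) {
      fit_lamb_pugh(list(tr), r_max = r_max, edge_fraction = edge_fraction,
                    td_grid = td_grid, shared = TRUE)
    })
    names(fits) <- vapply(traces, function(tr) sprintf("%.1f", tr$intensity),
                          character(1))
    return(fits)
  }
  edges <- list()
  amps <- numeric(0)
  ints <- numeric(0)
  for (tr in traces) {
    a <- measure_a_wave(tr)
    if (!is.finite(a$trough_time) || a$a_amplitude <= 0) next
    sel <- which(tr$time > tr$flash_onset &
                   tr$time <= tr$flash_onset + edge_fraction * a$a_peak_time)
    if (length(sel) < 5) next
    edges[[length(edges) + 1]] <- list(
      t = tr$time[sel] - tr$flash_onset,
      r = a$baseline - tr$voltage[sel],          # positive-going response
      intensity = 10^tr$intensity,
      trough_ms = a$a_peak_time)
    amps <- c(amps, a$a_amplitude)
    ints <- c(ints, tr$intensity)
  }
  if (length(edges) == 0) stopf("no traces with a usable A-wave leading edge")
  r_max_val <- if (identical(r_max, "max_a_wave")) max(amps) else as.numeric(r_max)
  if (!is.finite(r_max_val) || r_max_val <= 0) stopf("invalid R_max")
  td_max <- min(vapply(edges, `[[`, numeric(1), "trough_ms"))

  rss_fun <- function(p) {
    tc <- p[1]; td <- p[2]
    if (tc <= 0 || td < 0 || td > td_max) return(Inf)
    s <- 0
    for (e in edges) {
      s <- s + sum((e$r - lamb_pugh_response(e$t, e$intensity, r_max_val, tc, td))^2)
    }
    s
  }

  # score the start grid, then polish the best few starts
  starts <- expand.grid(tc = c(2, 5, 10, 20, 40, 80),
                        td = td_grid[td_grid <= td_max])
  starts$rss <- apply(starts[, c("tc", "td")], 1, rss_fun)
  starts <- starts[order(starts$rss), ]
  best <- NULL
  for (s in seq_len(min(3, nrow(starts)))) {
    o <- tryCatch(
      stats::optim(c(starts$tc[s], starts$td[s]), rss_fun,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
          (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stopf("activation-phase fit did not converge after multi-start")
  coefs <- c(r_max_uv = r_max_val, t_c_ms = best$par[1], t_d_ms = best$par[2])
  structure(
    list(coefficients = coefs, rss = best$value, edges = edges,
         fit_window = c(0, edge_fraction),
         intensity_range_used = range(ints),
         r_max_policy = if (identical(r_max, "max_a_wave")) "max_a_wave" else "fixed"),
    class = "lamb_pugh_fit"
  )
}

#' @export
coef.lamb_pugh_fit <- function(object, ...) object$coefficients

#' @export
print.lamb_pugh_fit <- function(x, ...) {
  cat(sprintf(
    "Activation-phase fit: R_max = %.1f uV (%s), t_c = %.2f ms, t_d = %.2f ms, RSS = %.3g\n",
    x$coefficients[["r_max_uv"]], x$r_max_policy,
    x$coefficients[["t_c_ms"]], x$coefficients[["t_d_ms"]], x$rss))
  invisible(x)
}

#' Predict the activation-phase response
#'
#' @param object A `lamb_pugh_fit`.
#' @param t_ms Times after flash onset, ms.
#' @param intensity_log Flash energy, log10 cd.s/m^2.
#' @param ... Unused.
#' @return Predicted positive-going response, uV.
#' @export
predict.lamb_pugh_fit <- function(object, t_ms, intensity_log, ...) {
  cf <- object$coefficients
  lamb_pugh_response(t_ms, 10^intensity_log, cf[["r_max_uv"]],
                     cf[["t_c_ms"]], cf[["t_d_ms"]])
}

#' @export
plot.lamb_pugh_fit <- function(x, ...) {
  allt <- unlist(lapply(x$edges, `[[`, "t"))
  allr <- unlist(lapply(x$edges, `[[`, "r"))
  plot(allt, -allr, xlab = "time after flash (ms)", ylab = "voltage (uV)", ...)
  cf <- x$coefficients
  for (e in x$edges) {
    ts <- seq(0, max(e$t), length.out = 100)
    graphics::lines(ts, -lamb_pugh_response(ts, e$intensity, cf[["r_max_uv"]],
                                            cf[["t_c_ms"]], cf[["t_d_ms"]]))
  }
  invisible(x)
}
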