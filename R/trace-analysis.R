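# shared helper: evaluate code with a local RNG seed, restoring global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

window_idx <- function(trace, from, to) {
  which(trace$time >= from - 1e-9 & trace$time <= to + 1e-9)
}

#' Isolate the transporter current by scaled-tail subtraction
#'
#' The slow K+ current template (recorded under transporter blockade) is
#' scaled to the tail of the combined current — by least squares over a tail
#' window placed after the fast transporter component has decayed — and
#' subtracted, leaving the isolated transporter current.
#'
#' @param combined Combined-current trace (transporter + K+).
#' @param ik_template K-only template trace; must share `dt` and stimulus
#'   alignment with `combined`.
#' @param tail_window Window (ms, relative to the last stimulus) used for
#'   scaling; default `c(50, 400)`.
#' @param method `"least_squares"` (default) or `"ratio_of_means"`.
#'
#' @return The isolated transporter-current trace (condition `"iglut"`),
#'   with attributes `scale` (the fitted factor) and `tail_window`.
#' @export
isolate_transporter_current <- function(combined, ik_template,
                                        tail_window = c(50, 400),
                                        method = c("least_squares",
                                                   "ratio_of_means")) {
  method <- match.arg(method)
  stopifnot(inherits(combined, "ephys_trace"),
            inherits(ik_template, "ephys_trace"))
  if (abs(trace_dt(combined) - trace_dt(ik_template)) >
      1e-9 * trace_dt(combined)) {
    stop("isolate_transporter_current: traces must share dt", call. = FALSE)
  }
  n <- min(nrow(combined), nrow(ik_template))
  stim <- stim_times(combined)
  t_ref <- if (length(stim)) max(stim) else combined$time[1]
  from <- t_ref + tail_window[1]
  to <- t_ref + tail_window[2]
  if (from >= combined$time[n]) {
    stop("isolate_transporter_current: tail window lies outside the record",
         call. = FALSE)
  }
  idx <- window_idx(combined[seq_len(n), ], from, min(to, combined$time[n]))
  cw <- trace_values(combined)[idx]
  tw <- trace_values(ik_template)[idx]
  if (sum(tw^2) < .Machine$double.eps * length(tw)) {
    stop("isolate_transporter_current: template ~ 0 in the tail window; ",
         "scale is ill-conditioned", call. = FALSE)
  }
  s <- switch(method,
              least_squares = sum(cw * tw) / sum(tw^2),
              ratio_of_means = mean(cw) / mean(tw))
  out_vals <- trace_values(combined)[seq_len(n)] -
    s * trace_values(ik_template)[seq_len(n)]
  out <- with_values(combined[seq_len(n), ], out_vals, condition = "iglut")
  attr(out, "scale") <- s
  attr(out, "tail_window") <- c(from, to)
  attr(out, "method") <- method
  out
}

#' Fit a monoexponential decay constant to a current transient
#'
#' Finds the inward (negative) peak, then fits
#' `I(t) = A * exp(-t'/tau) + baseline` by nonlinear least squares over a
#' window from the 90 %-of-peak crossing of the decay (skipping the rounded
#' top, where the rise phase still contaminates a monoexponential) to 95 %
#' recovery, or over a supplied window. The reported `amplitude` is the
#' baseline-subtracted peak magnitude, measured directly.
#'
#' @param trace An `"ephys_trace"` current trace.
#' @param peak `"auto"` (default: most negative sample after the last
#'   stimulus) or a time (ms).
#' @param window `NULL` (auto: 90 %-of-peak crossing to 95 % recovery) or a
#'   `c(from, to)` window (ms).
#' @param baseline `NULL` (the pre-stimulus mean when at least 5 pre-stimulus
#'   samples exist, otherwise a fitted offset) — a number fixes the
#'   asymptote and only `A`, `tau` are fitted.
#' @param tau_bounds Allowed `tau` range (ms); estimates at the bounds are
#'   flagged as non-converged.
#' @param smooth Width (ms) of the running-mean filter used only for
#'   landmark detection (default 1.5, about the rise time of the transporter
#'   transient). Use a smaller value for very fast transients.
#'
#' @return A list of class `"decay_fit"`: `tau` (ms), `amplitude` (pA,
#'   positive magnitude), `baseline`, `window`, `resid_norm` (RMS residual),
#'   `converged`, `t_peak`, `n`.
#' @examples
#' tr <- make_kernel(0.5, 10, peak = 20, dt = 0.1)
#' fit_decay_tau(tr)$tau
#' @export
fit_decay_tau <- function(trace, peak = "auto", window = NULL, baseline = NULL,
                          tau_bounds = c(0.1, 1e4), smooth = 1.5) {
  stopifnot(inherits(trace, "ephys_trace"))
  y <- trace_values(trace)
  tt <- trace$time
  stim <- stim_times(trace)
  t_search <- if (length(stim)) max(stim) else tt[1]
  base_est <- baseline
  fix_base <- !is.null(baseline)
  if (is.null(base_est)) {
    pre <- which(tt < (if (length(stim)) min(stim) else tt[1] + 1e-9))
    if (length(pre) >= 5) {
      base_est <- mean(y[pre])
      fix_base <- TRUE
    } else {
      base_est <- 0
    }
  }
  # landmarks (peak position, window thresholds) are read off a lightly
  # smoothed copy so sample noise does not truncate the fit window; the fit
  # itself uses the raw samples
  w <- max(3L, 2L * floor(smooth / (2 * trace_dt(trace))) + 1L)
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  if (identical(peak, "auto")) {
    cand <- which(tt >= t_search)
    ip <- cand[which.min(ys[cand])]
  } else {
    ip <- which.min(abs(tt - peak))
  }
  if (ys[ip] >= base_est) {
    stop("fit_decay_tau: no inward (negative) peak found", call. = FALSE)
  }
  amp0 <- ys[ip] - base_est
  if (is.null(window)) {
    dec <- which(tt > tt[ip] & (ys - base_est) >= 0.9 * amp0)
    i_from <- if (length(dec)) dec[1] else ip
    rec <- which(tt > tt[ip] & (ys - base_est) >= 0.05 * amp0)
    i_to <- if (length(rec)) rec[1] else length(tt)
    window <- c(tt[i_from], tt[i_to])
  }
  if (window[1] < tt[ip] - 1e-9) window[1] <- tt[ip]
  idx <- window_idx(trace, window[1], window[2])
  if (length(idx) < 5) stop("fit_decay_tau: fit window too short", call. = FALSE)
  df <- data.frame(t = tt[idx] - tt[idx[1]], y = y[idx])
  # log-slope start value
  pos <- df$y - base_est
  ok <- pos < 0.5 * amp0 & pos < 0
  tau0 <- if (sum(ok) > 3) {
    sl <- stats::coef(stats::lm(log(-pos[ok]) ~ df$t[ok]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(window) / 3
  } else diff(window) / 3
  tau0 <- min(max(tau0, tau_bounds[1] * 1.5), tau_bounds[2] / 1.5)
  fit <- NULL
  conv <- FALSE
  if (!fix_base) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C, data = df,
                        start = list(A = amp0, tau = tau0, C = base_est),
                        lower = c(-Inf, tau_bounds[1], -Inf),
                        upper = c(Inf, tau_bounds[2], Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + base_est, data = df,
                        start = list(A = amp0, tau = tau0),
                        lower = c(-Inf, tau_bounds[1]),
                        upper = c(Inf, tau_bounds[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    out <- list(tau = NA_real_, amplitude = NA_real_, baseline = base_est,
                window = window, resid_norm = NA_real_, converged = FALSE,
                t_peak = tt[ip], n = length(idx))
    class(out) <- "decay_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  at_bound <- tau <= tau_bounds[1] * (1 + 1e-6) || tau >= tau_bounds[2] * (1 - 1e-6)
  conv <- isTRUE(fit$convInfo$isConv) && !at_bound
  out <- list(tau = tau,
              amplitude = abs(amp0),
              baseline = if (fix_base) base_est else unname(cf["C"]),
              window = window,
              resid_norm = sqrt(mean(stats::resid(fit)^2)),
              converged = conv, t_peak = tt[ip], n = length(idx))
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau = %.4g ms, amplitude = %.4g pA, baseline = %.4g (window %.4g-%.4g ms, RMS resid %.3g)%s\n",
              x$tau, x$amplitude, x$baseline, x$window[1], x$window[2],
              x$resid_norm, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("tau", "amplitude", "baseline"),
                 estimate = c(x$tau, x$amplitude, x$baseline))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, amplitude = x$amplitude, baseline = x$baseline,
                 resid_norm = x$resid_norm, n = x$n, converged = x$converged,
                 t_peak = x$t_peak,
                 window_from = x$window[1], window_to = x$window[2])
}

#' Peak amplitudes of a 5 x 50 Hz train, normalized to a reference
#'
#' Measures the inward peak of each response in a stimulus train. Because
#' consecutive responses overlap, each peak is measured relative to a
#' baseline: either the monoexponential extrapolation of the preceding
#' compound decay (default) or the value immediately before the stimulus.
#' Amplitudes are normalized by `ref_amplitude` (e.g. the single-stimulus
#' response amplitude).
#'
#' @param trace Current trace with at least 2 stimulus annotations.
#' @param ref_amplitude Reference amplitude (pA, positive magnitude).
#' @param baseline_rule `"extrapolate"` (default) or `"prestim"`.
#' @param search_half_width Half-width (ms) of the peak search window around
#'   the expected latency (the latency of the first response), default 5.
#'
#' @return A tibble of class `"facilitation_profile"` with columns `stim`,
#'   `stim_time`, `peak_time`, `raw_amplitude` (pA), `norm_amplitude`,
#'   `flagged`; attributes `method` and `ref_amplitude`.
#' @export
train_peak_amplitudes <- function(trace, ref_amplitude,
                                  baseline_rule = c("extrapolate", "prestim"),
                                  search_half_width = 5) {
  baseline_rule <- match.arg(baseline_rule)
  stopifnot(inherits(trace, "ephys_trace"))
  stim <- stim_times(trace)
  if (length(stim) < 2) {
    stop("train_peak_amplitudes: need a train (>= 2 stimuli)", call. = FALSE)
  }
  if (min(diff(stim)) <= trace_dt(trace)) {
    stop("train_peak_amplitudes: inter-stimulus interval must exceed dt",
         call. = FALSE)
  }
  y <- trace_values(trace)
  tt <- trace$time
  pre <- which(tt < min(stim))
  rest <- if (length(pre) >= 5) mean(y[pre]) else 0
  isi <- min(diff(stim))
  # latency from the first response (search its full inter-stimulus span)
  i1 <- which(tt >= stim[1] & tt <= stim[1] + isi)
  lat <- tt[i1[which.min(y[i1])]] - stim[1]
  rows <- vector("list", length(stim))
  for (s in seq_along(stim)) {
    lo <- stim[s] + max(lat - search_half_width, 0)
    hi <- min(stim[s] + lat + search_half_width,
              if (s < length(stim)) stim[s + 1] else tt[length(tt)])
    idx <- window_idx(trace, lo, hi)
    ip <- idx[which.min(y[idx])]
    flagged <- FALSE
    # reject flat windows (no local extremum)
    if (length(idx) < 3 || y[ip] >= rest - .Machine$double.eps) flagged <- TRUE
    base <- rest
    if (s > 1) {
      ib <- max(which(tt <= stim[s]))
      if (baseline_rule == "prestim") {
        base <- y[ib]
      } else {
        # fit the tail of the preceding inter-stimulus segment and
        # extrapolate its decay under the current peak; when the preceding
        # response has already returned to rest there is nothing to
        # extrapolate and the pre-stimulus value is used directly
        seg <- window_idx(trace, stim[s] - 0.6 * isi, stim[s] - 0.25)
        segy <- y[seg] - rest
        scale_ref <- max(abs(y - rest))
        if (length(seg) >= 6 && all(segy < -1e-9 * scale_ref)) {
          st <- tt[seg] - tt[seg[1]]
          sl <- stats::coef(stats::lm(log(-segy) ~ st))
          base <- rest - exp(unname(sl[1]) + unname(sl[2]) *
                               (tt[ip] - tt[seg[1]]))
        } else {
          base <- y[ib]
        }
      }
    }
    rows[[s]] <- tibble::tibble(
      stim = s, stim_time = stim[s], peak_time = tt[ip],
      raw_amplitude = abs(y[ip] - base),
      flagged = flagged)
  }
  out <- dplyr::bind_rows(rows)
  out$norm_amplitude <- out$raw_amplitude / ref_amplitude
  class(out) <- c("facilitation_profile", class(out))
  attr(out, "method") <- baseline_rule
  attr(out, "ref_amplitude") <- ref_amplitude
  out
}

#' Slow K+ current amplitude at a fixed delay after the last response
#'
#' Measures the mean current in a window centred `offset` ms after the last
#' response peak, baseline-subtracted (mean before the first stimulus). With
#' the default 200 ms offset the fast transporter component (decay ~6 ms) has
#' decayed by > 30 time constants, so the measure isolates the slow K+
#' current.
#'
#' @param trace Current trace with stimulus annotations.
#' @param offset Delay after the last peak (ms), default 200.
#' @param width Window width (ms), default 20.
#'
#' @return Amplitude (pA, sign preserved; inward negative) with attribute
#'   `window`.
#' @export
measure_k_current <- function(trace, offset = 200, width = 20) {
  stopifnot(inherits(trace, "ephys_trace"))
  y <- trace_values(trace)
  tt <- trace$time
  stim <- stim_times(trace)
  t_last <- if (length(stim)) max(stim) else tt[1]
  pre <- which(tt < (if (length(stim)) min(stim) else tt[1] + 1e-9))
  base <- if (length(pre) >= 2) mean(y[pre]) else 0
  idx_post <- which(tt >= t_last)
  i_peak <- idx_post[which.max(abs(y[idx_post] - base))]
  centre <- tt[i_peak] + offset
  if (centre + width / 2 > tt[length(tt)]) {
    stop("measure_k_current: measurement window extends beyond the record",
         call. = FALSE)
  }
  idx <- window_idx(trace, centre - width / 2, centre + width / 2)
  structure(mean(y[idx]) - base, window = c(centre - width / 2, centre + width / 2))
}

#' Baseline-subtracted inward peak amplitude of a response
#'
#' Measures the raw inward peak relative to the pre-stimulus baseline, with
#' the same direct sample-minimum detector used for train peaks — so that
#' amplitude ratios between traces measured this way are free of systematic
#' detector bias.
#'
#' @param trace An `"ephys_trace"` current trace.
#' @param search Window (ms) to search for the peak; default from the last
#'   stimulus to 50 ms after it.
#'
#' @return Peak amplitude (pA, positive magnitude).
#' @export
peak_amplitude <- function(trace, search = NULL) {
  stopifnot(inherits(trace, "ephys_trace"))
  y <- trace_values(trace)
  tt <- trace$time
  stim <- stim_times(trace)
  t0 <- if (length(stim)) max(stim) else tt[1]
  if (is.null(search)) search <- c(t0, t0 + 50)
  pre <- which(tt < (if (length(stim)) min(stim) else tt[1] + 1e-9))
  base <- if (length(pre) >= 2) mean(y[pre]) else 0
  idx <- window_idx(trace, search[1], search[2])
  if (!length(idx)) stop("peak_amplitude: empty search window", call. = FALSE)
  abs(min(y[idx]) - base)
}
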