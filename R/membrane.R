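#' Nernst potential for K+
#'
#' `E_K = slope * ln(K_out / K_in)`. The default slope of 26.7 mV keeps the
#' membrane model consistent with the transporter voltage slope
#' (53.4 = 2 x 26.7); `slope = NA` uses the physical RT/F at `T_kelvin`.
#'
#' @param K_out,K_in Extra-/intracellular K+ (mM), both > 0. Vectorised.
#' @param slope Nernst slope (mV) or `NA` for RT/F.
#' @param T_kelvin Temperature (K) when `slope = NA`, default 307.
#'
#' @return `E_K` in mV.
#' @examples
#' nernst_potential(2.5, 120)      # ~ -103.4 mV
#' nernst_potential(120, 120)      # 0
#' @export
nernst_potential <- function(K_out, K_in, slope = 26.7, T_kelvin = 307) {
  if (any(K_out <= 0) || any(K_in <= 0)) {
    stop("nernst_potential: concentrations must be > 0", call. = FALSE)
  }
  if (is.na(slope)) slope <- 1000 * 8.314462618 * T_kelvin / 96485.33212
  slope * log(K_out / K_in)
}

kir_k_scale <- function(K_out, params) {
  switch(params$kir_k_factor,
         sqrt = sqrt(K_out / params$K_ref),
         linear = K_out / params$K_ref,
         none = rep_len(1, length(K_out)))
}

#' Kir4.1 current density
#'
#' `I_Kir = G_kir * f([K]o) * (V - NK*E_K - V_A1) /
#'          (1 + exp((V - NK*E_K - V_A2) / V_A3))`
#' in mA cm^-2, inward negative. `f` is the concentration factor selected in
#' [membrane_params()] (`sqrt([K]o/K_ref)` by default). The current is zero
#' exactly at `V = NK*E_K + V_A1` and rectifies (denominator grows) with
#' depolarization.
#'
#' @param V Membrane voltage (mV). Vectorised.
#' @param K_out,K_in K+ concentrations (mM).
#' @param params A [membrane_params()].
#'
#' @return Current density (mA cm^-2).
#' @examples
#' kir_current_density(-85, 2.5, 120, membrane_params())
#' @export
kir_current_density <- function(V, K_out, K_in, params = membrane_params()) {
  ek <- nernst_potential(K_out, K_in, params$nernst_slope, params$T_kelvin)
  drive <- V - params$NK * ek - params$V_A1
  denom <- 1 + exp((V - params$NK * ek - params$V_A2) / params$V_A3)
  # mS/cm2 * mV = uA/cm2 -> mA/cm2
  1e-3 * params$G_kir * kir_k_scale(K_out, params) * drive / denom
}

#' Passive leak current density
#'
#' `I_pas = G_pas * (V - E_pas)` in mA cm^-2; stabilizes the astrocyte
#' membrane potential near `E_pas`.
#'
#' @inheritParams kir_current_density
#' @return Current density (mA cm^-2).
#' @export
leak_current_density <- function(V, params = membrane_params()) {
  1e-3 * params$G_pas * (V - params$E_pas)
}

#' Astrocyte resting potential
#'
#' Solves `I_Kir + I_pas (+ I_GluT) = 0` for `V` by root bracketing on
#' `[-150, 0]` mV. With the transporter included, the ambient glutamate of
#' `ions` is used as-is; at the reversal concentration the transporter
#' contributes zero current and the two solutions coincide.
#'
#' @param K_out Extracellular K+ (mM).
#' @param K_in Intracellular K+ (mM), default 120.
#' @param params A [membrane_params()].
#' @param include_transporter Add the GLT-1 steady-state current to the
#'   balance (default `FALSE`).
#' @param glt1 A [glt1_params()] (used when `include_transporter`).
#' @param ions An [ion_state()] (used when `include_transporter`); its
#'   `K_out`/`K_in` are overridden by the arguments.
#'
#' @return Resting potential (mV) with attribute `current` (residual).
#' @examples
#' resting_potential(2.5)
#' resting_potential(5)
#' @export
resting_potential <- function(K_out, K_in = 120, params = membrane_params(),
                              include_transporter = FALSE,
                              glt1 = glt1_params(), ions = ion_state()) {
  total <- function(V) {
    i <- kir_current_density(V, K_out, K_in, params) +
      leak_current_density(V, params)
    if (include_transporter) {
      io <- ions; io$K_out <- K_out; io$K_in <- K_in
      i <- i + steady_state_current(V, io, glt1)
    }
    i
  }
  lo <- total(-150); hi <- total(0)
  if (sign(lo) == sign(hi)) {
    stop("resting_potential: no zero of the total current on [-150, 0] mV; ",
         "check conductances", call. = FALSE)
  }
  r <- stats::uniroot(total, c(-150, 0), tol = 1e-12)
  structure(r$root, current = total(r$root))
}

#' Voltage response of a single-compartment astrocyte to a K+ schedule
#'
#' Integrates `C_m dV/dt = -(I_Kir + I_pas)` under a stepwise extracellular
#' K+ schedule. The membrane relaxes monotonically to the resting potential
#' of the prevailing `K_out`.
#'
#' @param k_schedule A data frame with columns `time` (ms) and `K_out` (mM):
#'   `K_out` applies from each `time` until the next row.
#' @param params A [membrane_params()].
#' @param K_in Intracellular K+ (mM), default 120.
#' @param t_end End of integration (ms); default 200 ms past the last step.
#' @param dt Step (ms), default 1.
#' @param V0 Initial voltage; default the resting potential of the first
#'   `K_out`.
#'
#' @return A tibble of class `"ephys_trace"` with columns `time` (ms) and
#'   `V` (mV).
#' @examples
#' sched <- tibble::tibble(time = c(0, 500), K_out = c(2.5, 5))
#' tr <- voltage_step_response(sched, t_end = 3000)
#' @export
voltage_step_response <- function(k_schedule, params = membrane_params(),
                                  K_in = 120, t_end = NULL, dt = 1, V0 = NULL) {
  stopifnot(is.data.frame(k_schedule),
            all(c("time", "K_out") %in% names(k_schedule)))
  ks <- dplyr::arrange(k_schedule, .data$time)
  if (is.null(t_end)) t_end <- max(ks$time) + 200
  if (is.null(V0)) V0 <- as.numeric(resting_potential(ks$K_out[1], K_in, params))
  k_at <- stats::approxfun(ks$time, ks$K_out, method = "constant",
                           rule = 2, f = 0)
  n <- ceiling(t_end / dt)
  V <- numeric(n + 1); V[1] <- V0
  t <- 0
  for (i in seq_len(n)) {
    ko <- k_at(t)
    # mA/cm2 / (uF/cm2) = V/s = mV/ms
    dV <- function(v) -(kir_current_density(v, ko, K_in, params) +
                          leak_current_density(v, params)) * 1e3 / params$C_m
    k1 <- dV(V[i]); k2 <- dV(V[i] + dt / 2 * k1)
    k3 <- dV(V[i] + dt / 2 * k2); k4 <- dV(V[i] + dt * k3)
    V[i + 1] <- V[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(V[i + 1]) || abs(V[i + 1]) > 500) {
      stop("voltage_step_response: integration unstable; reduce dt", call. = FALSE)
    }
    t <- t + dt
  }
  new_trace(tibble::tibble(time = dt * (0:n), V = V),
            unit = "mV", value_col = "V",
            stim_times = ks$time[-1], condition = "k_step")
}
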