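#' Voltage factor of charge-moving transitions
#'
#' `u(V, P) = exp(P * V / slope)` scales every transition of the GLT-1 scheme
#' that moves partial charge `P` across the membrane field.
#'
#' @param V Membrane voltage (mV). Vectorised.
#' @param P Charge-partition coefficient (dimensionless).
#' @param slope Voltage slope (mV), default 53.4.
#'
#' @return Dimensionless multiplier, strictly positive.
#' @examples
#' u_factor(0, 0.5)        # 1
#' u_factor(53.4, 1)       # e
#' @export
u_factor <- function(V, P, slope = 53.4) {
  if (any(!is.finite(V)) || any(!is.finite(P))) {
    stop("u_factor: V and P must be finite", call. = FALSE)
  }
  if (slope <= 0) stop("u_factor: slope must be > 0", call. = FALSE)
  exp(P * V / slope)
}

# The eight connected transitions of the ring (1-2-3-4-5-6-1), given scalar or
# vector V and concentrations. Returns a list of the 12 directed rates.
# Rates (per ms):
#   C12 = [Glu]o k12 u(V,P12)   C21 = k21
#   C23 = [Na]o  k23 u(V,P23)   C32 = k32
#   C34 =        k34 u(V,P34)   C43 = k43
#   C45 = k45                   C54 = k54 [Glu]in
#   C56 =        k56 u(V,P56)   C65 = k65 [Na]in
#   C61 = k61 [K]in             C16 = k16 u(V,P16) [K]o
glt1_rates <- function(V, ions, params) {
  k <- params$k; P <- params$P; s <- params$slope
  list(
    r12 = ions$Glu_out * k[["k12"]] * u_factor(V, P[["P12"]], s),
    r21 = rep_len(k[["k21"]], length(V)),
    r23 = ions$Na_out * k[["k23"]] * u_factor(V, P[["P23"]], s),
    r32 = rep_len(k[["k32"]], length(V)),
    r34 = k[["k34"]] * u_factor(V, P[["P34"]], s),
    r43 = rep_len(k[["k43"]], length(V)),
    r45 = rep_len(k[["k45"]], length(V)),
    r54 = rep_len(k[["k54"]] * ions$Glu_in, length(V)),
    r56 = k[["k56"]] * u_factor(V, P[["P56"]], s),
    r65 = rep_len(k[["k65"]] * ions$Na_in, length(V)),
    r61 = rep_len(ions$K_in * k[["k61"]], length(V)),
    r16 = k[["k16"]] * u_factor(V, P[["P16"]], s) * ions$K_out
  )
}

#' Build the 6x6 rate generator of the GLT-1 scheme
#'
#' Assembles the transition-rate matrix (rows-sum-to-zero convention:
#' `Q[i, j]` is the rate of `Ci -> Cj`, `Q[i, i] = -sum of row`) from the
#' membrane voltage, the ion state and the scheme parameters. Only the eight
#' transitions of the ring 1-2-3-4-5-6-1 are nonzero.
#'
#' @param V Membrane voltage (mV).
#' @param ions An [ion_state()].
#' @param params A [glt1_params()].
#'
#' @return A 6x6 matrix of class `"glt1_generator"` with attributes `V` and
#'   `ions`.
#' @examples
#' Q <- build_generator(-85, ion_state(Glu_out = 0.1), glt1_params())
#' rowSums(Q)   # ~ 0
#' @export
build_generator <- function(V, ions, params = glt1_params()) {
  stopifnot(inherits(ions, "ion_state"), inherits(params, "glt1_params"))
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V)) {
    stop("build_generator: V must be a single finite voltage (mV)", call. = FALSE)
  }
  r <- glt1_rates(V, ions, params)
  Q <- matrix(0, 6, 6)
  Q[1, 2] <- r$r12; Q[2, 1] <- r$r21
  Q[2, 3] <- r$r23; Q[3, 2] <- r$r32
  Q[3, 4] <- r$r34; Q[4, 3] <- r$r43
  Q[4, 5] <- r$r45; Q[5, 4] <- r$r54
  Q[5, 6] <- r$r56; Q[6, 5] <- r$r65
  Q[6, 1] <- r$r61; Q[1, 6] <- r$r16
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("glt1_generator", "matrix", "array"),
            V = V, ions = ions)
}

#' Steady-state occupancy of the transporter scheme
#'
#' Solves `p Q = 0`, `sum(p) = 1` as the null space of the transposed
#' generator (via singular-value decomposition). The scheme is an irreducible
#' ring, so the stationary distribution is unique.
#'
#' @param gen A generator from [build_generator()] (or any valid 6x6
#'   rows-sum-to-zero rate matrix).
#'
#' @return Named numeric vector `p1..p6` summing to 1.
#' @examples
#' steady_state(build_generator(-85, ion_state(Glu_out = 1e-4), glt1_params()))
#' @export
steady_state <- function(gen) {
  Q <- unclass(gen)
  if (!is.matrix(Q) || any(dim(Q) != c(6L, 6L))) {
    stop("steady_state: generator must be 6x6", call. = FALSE)
  }
  sv <- svd(t(Q))
  if (sv$d[5] < 1e-12 * max(sv$d[1], 1)) {
    stop("steady_state: degenerate scheme (null space dimension > 1)", call. = FALSE)
  }
  p <- sv$v[, 6]
  p <- p / sum(p)
  if (any(p < -1e-9)) {
    stop("steady_state: negative stationary probability; invalid generator", call. = FALSE)
  }
  p <- pmax(p, 0); p <- p / sum(p)
  res <- max(abs(p %*% Q))
  if (res > 1e-9) {
    stop("steady_state: residual ", format(res), " exceeds 1e-9", call. = FALSE)
  }
  stats::setNames(p, paste0("p", 1:6))
}

#' Integrate the occupancy ODE under a time-varying schedule
#'
#' Fixed-step 4th-order Runge-Kutta integration of `dp/dt = p Q(t)` with the
#' generator rebuilt from `schedule(t)` at every stage. Occupancies are
#' conservation-checked at every step.
#'
#' @param p0 Initial occupancy (named or plain numeric length 6, sums to 1).
#' @param schedule Function of time (ms) returning `list(V = , ions = )`.
#' @param dt Step (ms). Must resolve the fastest rates; 0.01 ms is safe for
#'   the default parameters during glutamate transients.
#' @param t_end End time (ms); integration runs on `[t0, t_end]`.
#' @param params A [glt1_params()].
#' @param t0 Start time (ms), default 0.
#' @param record_every Record every n-th step (default 1).
#'
#' @return A tibble with columns `time`, `p1`..`p6`.
#' @examples
#' sched <- function(t) list(V = -85, ions = ion_state(Glu_out = 0.1))
#' p0 <- steady_state(build_generator(-85, ion_state(), glt1_params()))
#' traj <- integrate_occupancy(p0, sched, dt = 0.01, t_end = 5)
#' @export
integrate_occupancy <- function(p0, schedule, dt, t_end, params = glt1_params(),
                                t0 = 0, record_every = 1L) {
  if (dt <= 0) stop("integrate_occupancy: dt must be > 0", call. = FALSE)
  p <- as.numeric(p0)
  if (length(p) != 6L || abs(sum(p) - 1) > 1e-8 || any(p < -1e-12)) {
    stop("integrate_occupancy: p0 must be a probability vector of length 6",
         call. = FALSE)
  }
  n <- ceiling((t_end - t0) / dt)
  times <- t0 + dt * seq_len(n)
  keep <- seq(0, n, by = record_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 6L)
  out[1, ] <- p
  tvec <- c(t0, times[keep[-1]])
  row <- 2L
  # rebuild the generator only when the schedule output actually changes
  # (piecewise-constant schedules are the common case)
  last_s <- NULL
  last_Q <- NULL
  Qat <- function(t) {
    s <- schedule(t)
    if (!identical(s, last_s)) {
      last_Q <<- unclass(build_generator(s$V, s$ions, params))
      last_s <<- s
    }
    last_Q
  }
  t <- t0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    # evaluate the end stage just inside the step so that piecewise-constant
    # schedules switching on step boundaries are integrated exactly
    Q1 <- Qat(t); Q2 <- Qat(t + h / 2); Q3 <- Qat(t + h * (1 - 1e-9))
    k1 <- p %*% Q1
    k2 <- (p + h / 2 * k1) %*% Q2
    k3 <- (p + h / 2 * k2) %*% Q2
    k4 <- (p + h * k3) %*% Q3
    p <- p + as.numeric(h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    t <- t + h
    if (abs(sum(p) - 1) > 1e-8 || any(p < -1e-6)) {
      stop("integrate_occupancy: step instability at t = ", signif(t, 6),
           " ms; reduce dt (occupancy left the simplex)", call. = FALSE)
    }
    if (i %in% keep) {
      out[row, ] <- p
      row <- row + 1L
    }
  }
  colnames(out) <- paste0("p", 1:6)
  dplyr::bind_cols(tibble::tibble(time = tvec), tibble::as_tibble(out))
}

#' Transporter current density from an occupancy state
#'
#' Evaluates the charge-weighted sum of net transition fluxes
#' `I = -e * density * (pre16*J16 + pre12*J12 + pre23*J23 + pre34*J34 + pre56*J56)`
#' where `Jij` is the net probability flux `i -> j` and the prefactors are the
#' charge weights of [glt1_params()] (`-0.1, 0.5, 0.4, 0.6` for the
#' translocation steps and `p16_prefactor` for the K+ step). Inward uptake
#' current is negative. Linear in `density`.
#'
#' @param p Occupancy vector (length 6).
#' @param V Membrane voltage (mV).
#' @param ions An [ion_state()].
#' @param params A [glt1_params()].
#' @param units `"mA/cm2"` (default) or `"pA/um2"` (1 mA/cm2 = 10 pA/um2).
#'
#' @return Current density (scalar).
#' @examples
#' io <- ion_state(Glu_out = 1e-4)
#' p <- steady_state(build_generator(-85, io, glt1_params()))
#' transporter_current_density(p, -85, io, glt1_params())
#' @export
transporter_current_density <- function(p, V, ions, params = glt1_params(),
                                        units = c("mA/cm2", "pA/um2")) {
  units <- match.arg(units)
  p <- as.numeric(p)
  if (length(p) != 6L) stop("transporter_current_density: p must have length 6", call. = FALSE)
  r <- glt1_rates(V, ions, params)
  flux <- glt1_flux_sum(p, r, params$prefactor)
  # e * density * flux: C * um^-2 * ms^-1 = 1e15 pA um^-2
  i_pa_um2 <- -params$e_charge * params$density * 1e15 * flux
  if (units == "pA/um2") i_pa_um2 else i_pa_um2 / 10
}

# charge-weighted net flux sum; p may be a length-6 vector or an n x 6 matrix
# with rate vectors of length n.
glt1_flux_sum <- function(p, r, pref) {
  if (is.matrix(p)) {
    J16 <- p[, 1] * r$r16 - p[, 6] * r$r61
    J12 <- p[, 1] * r$r12 - p[, 2] * r$r21
    J23 <- p[, 2] * r$r23 - p[, 3] * r$r32
    J34 <- p[, 3] * r$r34 - p[, 4] * r$r43
    J56 <- p[, 5] * r$r56 - p[, 6] * r$r65
  } else {
    J16 <- p[1] * r$r16 - p[6] * r$r61
    J12 <- p[1] * r$r12 - p[2] * r$r21
    J23 <- p[2] * r$r23 - p[3] * r$r32
    J34 <- p[3] * r$r34 - p[4] * r$r43
    J56 <- p[5] * r$r56 - p[6] * r$r65
  }
  pref[["pre16"]] * J16 + pref[["pre12"]] * J12 + pref[["pre23"]] * J23 +
    pref[["pre34"]] * J34 + pref[["pre56"]] * J56
}

#' Steady-state transporter current at given voltage and ions
#'
#' Convenience wrapper: builds the generator, solves the stationary
#' occupancy and evaluates [transporter_current_density()].
#'
#' @inheritParams transporter_current_density
#' @return Current density (scalar).
#' @export
steady_state_current <- function(V, ions, params = glt1_params(),
                                 units = c("mA/cm2", "pA/um2")) {
  p <- steady_state(build_generator(V, ions, params))
  transporter_current_density(p, V, ions, params, units = match.arg(units))
}

#' Zero-current (reversal) extracellular glutamate concentration
#'
#' Finds the ambient `[Glu]o` at which the transport cycle carries zero net
#' steady-state current, for a given extracellular K+. Because the scheme is a
#' single ring, zero current is the detailed-balance (thermodynamic stall)
#' point. The search brackets a sign change of the steady-state current over
#' `[Glu]o` in `bracket` and refines it with Brent's method on `log10[Glu]o`.
#'
#' The voltage at which the condition is evaluated is set by `v_policy`:
#' `"resting"` (default) uses the astrocyte resting potential computed by
#' [resting_potential()] at the given `K_out` (this couples the K+ rise to
#' membrane depolarization); `"fixed"` uses `V_fixed`.
#'
#' @param K_out Extracellular K+ (mM).
#' @param ions Baseline [ion_state()]; `K_out` and `Glu_out` are overridden.
#' @param params A [glt1_params()].
#' @param v_policy `"resting"` or `"fixed"`.
#' @param V_fixed Voltage for the fixed policy (mV), default -85.
#' @param membrane A [membrane_params()] used by the resting policy.
#' @param bracket Search interval for `[Glu]o` (mM), default `c(1e-9, 1)`.
#'
#' @return `[Glu]o` at zero current (mM), with attributes `V` (the voltage
#'   used) and `current` (the residual current at the root).
#' @examples
#' find_reversal_glu(5)
#' find_reversal_glu(2.5, v_policy = "fixed", V_fixed = -85)
#' @export
find_reversal_glu <- function(K_out, ions = ion_state(), params = glt1_params(),
                              v_policy = c("resting", "fixed"), V_fixed = -85,
                              membrane = membrane_params(),
                              bracket = c(1e-9, 1)) {
  v_policy <- match.arg(v_policy)
  V <- if (v_policy == "resting") {
    as.numeric(resting_potential(K_out, ions$K_in, membrane))
  } else {
    V_fixed
  }
  cur_at <- function(lg) {
    io <- ions
    io$K_out <- K_out
    io$Glu_out <- 10^lg
    steady_state_current(V, io, params)
  }
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  f_lo <- cur_at(lo); f_hi <- cur_at(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop("find_reversal_glu: no sign change of steady-state current in bracket [",
         format(bracket[1]), ", ", format(bracket[2]), "] mM; current is ",
         if (f_lo < 0) "inward" else "outward", " throughout", call. = FALSE)
  }
  root <- stats::uniroot(cur_at, c(lo, hi), tol = 1e-13)
  glu <- 10^root$root
  resid <- cur_at(root$root)
  if (abs(resid) > 1e-15 + 1e-9 * abs(f_hi - f_lo)) {
    # refine once with a tighter tolerance if uniroot returned early
    root <- stats::uniroot(cur_at, c(root$root - 1e-6, root$root + 1e-6),
                           tol = .Machine$double.eps^0.75, extendInt = "yes")
    glu <- 10^root$root
    resid <- cur_at(root$root)
  }
  structure(glu, V = V, current = resid)
}
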