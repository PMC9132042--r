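# fast stationary distribution of a valid 6x6 generator (no checks):
# replace one balance equation by the normalization constraint
stationary6 <- function(Q) {
  A <- rbind(t(Q)[1:5, ], rep(1, 6))
  p <- solve(A, c(rep(0, 5), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

# occupancy derivative for an n x 6 matrix P under rate vectors r
occ_deriv <- function(P, r) {
  cbind(-(r$r12 + r$r16) * P[, 1] + r$r21 * P[, 2] + r$r61 * P[, 6],
        r$r12 * P[, 1] - (r$r21 + r$r23) * P[, 2] + r$r32 * P[, 3],
        r$r23 * P[, 2] - (r$r32 + r$r34) * P[, 3] + r$r43 * P[, 4],
        r$r34 * P[, 3] - (r$r43 + r$r45) * P[, 4] + r$r54 * P[, 5],
        r$r45 * P[, 4] - (r$r54 + r$r56) * P[, 5] + r$r65 * P[, 6],
        r$r56 * P[, 5] + r$r16 * P[, 1] - (r$r65 + r$r61) * P[, 6])
}

occ_rk4 <- function(P, r, h) {
  k1 <- occ_deriv(P, r)
  k2 <- occ_deriv(P + h / 2 * k1, r)
  k3 <- occ_deriv(P + h / 2 * k2, r)
  k4 <- occ_deriv(P + h * k3, r)
  P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Coupled multi-compartment hotspot simulation
#'
#' Integrates, per compartment of the reduced astrocyte, the membrane voltage
#' (Kir4.1 + leak + GLT-1 currents with axial cable coupling), intracellular
#' K+ (Kir source term plus longitudinal diffusion with coefficient `D_K`),
#' and the six-state transporter occupancy driven by the local extracellular
#' field of [stimulus_field()]. Ambient extracellular glutamate is pinned to
#' the transporter's zero-current concentration for the local K+ (so that no
#' standing transporter current distorts the resting state) unless the field
#' says `glu_ambient = "zero"`.
#'
#' Time stepping is split: axial voltage coupling and K+ diffusion are
#' implicit (backward Euler with a precomputed dense solve per step size),
#' membrane currents explicit, and the occupancy subcycled with RK4 at
#' `dt_occ` during the slow phase and integrated at `dt_fine` around the
#' glutamate bolus.
#'
#' @param graph An [build_reduced_morphology()] object.
#' @param field A [stimulus_field()].
#' @param glt1 A [glt1_params()].
#' @param mem A [membrane_params()].
#' @param dt_fine Step (ms) during the glutamate bolus window, default 0.01.
#' @param dt_coarse Voltage/K step (ms) during the slow K+ phase, default 0.5.
#' @param dt_occ Occupancy substep (ms) during the slow phase, default 0.1.
#' @param t_end End time (ms); default 50 ms past the end of the Glu bolus.
#' @param clamp_voltage `NULL` (free-running) or a voltage (mV) at which all
#'   compartments are clamped.
#' @param pre_phase `"integrate"` (default: the full K+ phase is integrated
#'   from onset) or `"equilibrate"` (the quasi-stationary state under the K+
#'   field is solved directly and integration starts 5 ms before the bolus;
#'   equivalent for bolus-response read-outs because the transporter pool
#'   re-equilibrates within ~0.1 s, and much faster).
#' @param record_dt Cadence (ms) of the per-compartment records.
#' @param ions Baseline [ion_state()] (Na and internal glutamate; internal K+
#'   is dynamic, initialised from `ions$K_in`).
#' @param D_K Intracellular K+ diffusion coefficient (um^2/ms), default 0.6.
#'
#' @return A list of class `"hotspot_sim"`; see the vignette. Main elements:
#'   `traces` (per-compartment tibble: time, comp, class, V, K_in, i_glut in
#'   pA/um^2, p1..p6), `hotspot` (volume-averaged transporter current density
#'   over the Glu sphere, an `"ephys_trace"`), `kir_charge` (per-compartment
#'   integrated Kir charge and K+ gain, for mass-balance checks), `ambient`
#'   (the ambient glutamate values used), `V_rest`.
#' @export
simulate_coupled <- function(graph, field, glt1 = glt1_params(),
                             mem = membrane_params(),
                             dt_fine = 0.01, dt_coarse = 0.5, dt_occ = 0.1,
                             t_end = NULL, clamp_voltage = NULL,
                             pre_phase = c("integrate", "equilibrate"),
                             record_dt = 5, ions = ion_state(), D_K = 0.6) {
  pre_phase <- match.arg(pre_phase)
  stopifnot(inherits(graph, "astro_morphology"),
            inherits(field, "stimulus_field"))
  if (dt_fine > 0.01 + 1e-12) {
    stop("simulate_coupled: dt_fine must be <= 0.01 ms to resolve the ",
         "fastest transporter rates during the bolus", call. = FALSE)
  }
  if (is.null(field$glu_center)) {
    d_k <- sqrt((graph$x - field$k_center[1])^2 +
                  (graph$y - field$k_center[2])^2 +
                  (graph$z - field$k_center[3])^2)
    ok <- which(d_k + field$glu_diameter / 2 <= field$k_diameter / 2)
    if (!length(ok)) {
      stop("simulate_coupled: no compartment lies inside the K+ sphere to ",
           "host the glutamate bolus", call. = FALSE)
    }
    cm <- ok[which.min(abs(graph$dist_soma[ok] - 4))]
    field$glu_center <- c(graph$x[cm], graph$y[cm], graph$z[cm])
  }
  n <- nrow(graph)
  A <- graph$area
  Vol <- graph$volume
  Cpf <- 0.01 * A                     # pF (1 uF/cm2 = 0.01 pF/um2) x C_m
  Cpf <- Cpf * mem$C_m
  pos <- cbind(graph$x, graph$y, graph$z)
  lap <- morphology_laplacians(graph)
  t_glu0 <- field$glu_onset
  t_glu1 <- field$glu_onset + field$glu_duration
  if (is.null(t_end)) t_end <- t_glu1 + 49
  # ambient glutamate
  amb <- if (field$glu_ambient == "reversal") {
    c(baseline = as.numeric(find_reversal_glu(field$k_baseline, ions, glt1,
                                              membrane = mem)),
      elevated = as.numeric(find_reversal_glu(field$k_amplitude, ions, glt1,
                                              membrane = mem)))
  } else {
    c(baseline = 0, elevated = 0)
  }
  field$ambient_values <- amb
  # geometry weights of the two spheres (positions are fixed)
  wk <- sphere_weight(pos, field$k_center, field$k_diameter / 2,
                      field$skirt_lambda)
  wg <- sphere_weight(pos, field$glu_center, field$glu_diameter / 2,
                      field$skirt_lambda)
  hot <- which(wg >= 0.5)
  if (!length(hot)) {
    stop("simulate_coupled: no compartment lies inside the glutamate sphere",
         call. = FALSE)
  }
  w_hot <- Vol[hot] / sum(Vol[hot])
  fields_at <- function(t) {
    k_on <- t >= field$k_onset && t < field$k_onset + field$k_duration
    K <- field$k_baseline +
      (if (k_on) (field$k_amplitude - field$k_baseline) * wk else 0)
    ambv <- amb[[1]] + (if (k_on) (amb[[2]] - amb[[1]]) * wk else 0)
    glu_on <- t >= t_glu0 && t < t_glu1
    G <- if (glu_on) pmax(ambv, field$glu_peak * wg) else ambv
    list(K_out = K, Glu_out = G)
  }
  e_scale <- -glt1$e_charge * glt1$density * 1e15    # pA/um2 per unit flux
  mem_currents <- function(V, Kin, f, P) {
    r <- glt1_rates(V, list(Na_in = ions$Na_in, Na_out = ions$Na_out,
                            K_in = Kin, K_out = f$K_out,
                            Glu_in = ions$Glu_in, Glu_out = f$Glu_out), glt1)
    ikir <- 10 * kir_current_density(V, f$K_out, Kin, mem)
    ipas <- 10 * leak_current_density(V, mem)
    iglut <- e_scale * glt1_flux_sum(P, r, glt1$prefactor)
    list(r = r, ikir = ikir, ipas = ipas, iglut = iglut)
  }
  V_rest <- as.numeric(resting_potential(field$k_baseline, ions$K_in, mem))
  V <- rep(V_rest, n)
  if (!is.null(clamp_voltage)) V <- rep(clamp_voltage, n)
  Kin <- rep(ions$K_in, n)
  f0 <- list(K_out = rep(field$k_baseline, n),
             Glu_out = rep(amb[[1]], n))
  p_base <- steady_state(build_generator(V[1], local_ions(ions, f0, 1, Kin),
                                         glt1))
  P <- matrix(p_base, n, 6, byrow = TRUE)
  kir_charge <- numeric(n)
  # recorders
  rec_full <- list(); rec_hot_t <- c(); rec_hot_i <- c()
  record_full <- function(t, V, Kin, ig, P) {
    tibble::tibble(time = t, comp = graph$comp, class = graph$class,
                   V = V, K_in = Kin, i_glut = ig,
                   p1 = P[, 1], p2 = P[, 2], p3 = P[, 3],
                   p4 = P[, 4], p5 = P[, 5], p6 = P[, 6])
  }
  solve_M <- function(dt) solve(diag(n) - dt * sweep(lap$G, 1, Cpf, "/"))
  solve_Md <- function(dt) solve(diag(n) - dt * D_K * sweep(lap$Gd, 1, Vol, "/"))
  step_segment <- function(t0, t1, dtV, n_sub, rec_hot_every = NA) {
    M <- if (is.null(clamp_voltage)) solve_M(dtV) else NULL
    Md <- solve_Md(dtV)
    nstep <- max(1L, round((t1 - t0) / dtV))
    t <- t0
    next_rec <- ceiling(t0 / record_dt) * record_dt
    for (s in seq_len(nstep)) {
      f <- fields_at(t)
      mc <- mem_currents(V, Kin, f, P)
      h <- dtV / n_sub
      for (j in seq_len(n_sub)) P <<- occ_rk4(P, mc$r, h)
      drift <- rowSums(P)
      if (any(abs(drift - 1) > 1e-6) || any(P < -1e-5)) {
        stop("simulate_coupled: occupancy left the simplex at t = ",
             signif(t, 6), " ms; reduce dt (stiffness)", call. = FALSE)
      }
      P <<- P / drift
      imem <- mc$ikir + mc$ipas + mc$iglut
      if (is.null(clamp_voltage)) {
        rhs <- V + dtV * (-(imem * A)) / Cpf
        V <<- as.numeric(M %*% rhs)
        if (any(!is.finite(V)) || any(abs(V) > 500)) {
          stop("simulate_coupled: voltage integration unstable; reduce dt",
               call. = FALSE)
        }
      }
      src <- 0.0103642697 * (-(mc$ikir * A)) / Vol   # mM/ms from Kir influx
      Kin <<- as.numeric(Md %*% (Kin + dtV * src))
      kir_charge <<- kir_charge + (-(mc$ikir * A)) * dtV
      t <- t0 + s * dtV
      if (!is.na(rec_hot_every) && s %% rec_hot_every == 0) {
        rec_hot_t <<- c(rec_hot_t, t)
        rec_hot_i <<- c(rec_hot_i, sum(w_hot * mc$iglut[hot]))
      }
      if (t >= next_rec - 1e-9 || s == nstep) {
        rec_full[[length(rec_full) + 1L]] <<-
          record_full(t, V, Kin, mc$iglut, P)
        next_rec <- next_rec + record_dt
      }
    }
    t
  }
  rec_full[[1L]] <- {
    f <- fields_at(0)
    mc0 <- mem_currents(V, Kin, f, P)
    record_full(0, V, Kin, mc0$iglut, P)
  }
  t_fine0 <- max(t_glu0 - 2, 0)
  if (pre_phase == "integrate") {
    step_segment(0, t_fine0, dt_coarse, max(1L, round(dt_coarse / dt_occ)))
  } else {
    # quasi-stationary pre-equilibration under the K+ field: alternate exact
    # stationary occupancy with long implicit (L-stable) voltage steps
    f <- fields_at(min(t_glu0 - 5, field$k_onset + field$k_duration / 2))
    # the transporter near its reversal contributes a large incremental
    # conductance, so the membrane relaxes within milliseconds: alternate
    # stationary-occupancy updates with short voltage relaxation bursts
    M05 <- if (is.null(clamp_voltage)) solve_M(0.5) else NULL
    for (it in 1:12) {
      V_prev <- V
      for (i in seq_len(n)) {
        P[i, ] <- stationary6(unclass(
          build_generator(V[i], local_ions(ions, f, i, Kin), glt1)))
      }
      if (is.null(clamp_voltage)) {
        for (j in 1:20) {
          mc <- mem_currents(V, Kin, f, P)
          rhs <- V + 0.5 * (-((mc$ikir + mc$ipas + mc$iglut) * A)) / Cpf
          V <- as.numeric(M05 %*% rhs)
          if (any(!is.finite(V)) || any(abs(V) > 300)) {
            stop("simulate_coupled: pre-equilibration diverged", call. = FALSE)
          }
        }
        if (it > 2 && max(abs(V - V_prev)) < 1e-4) break
      } else if (it >= 2) break
    }
    step_segment(t_fine0 - 3, t_fine0, 0.1, 1L)
  }
  step_segment(t_fine0, min(t_glu1 + 10, t_end), dt_fine, 1L,
               rec_hot_every = max(1L, round(0.05 / dt_fine)))
  if (t_glu1 + 10 < t_end) {
    step_segment(t_glu1 + 10, t_end, 0.1, 1L)
  }
  hot_tr <- new_trace(tibble::tibble(time = rec_hot_t, current = rec_hot_i),
                      unit = "pA/um2", stim_times = t_glu0,
                      condition = "hotspot")
  structure(list(
    graph = graph, field = field, glt1 = glt1, mem = mem,
    traces = dplyr::bind_rows(rec_full),
    hotspot = hot_tr, hotspot_comps = graph$comp[hot],
    kir_charge = tibble::tibble(
      comp = graph$comp, charge_pA_ms = kir_charge,
      k_gain_mM = Kin - ions$K_in,
      expected_gain_mM = 0.0103642697 * kir_charge / Vol),
    ambient = amb, V_rest = V_rest, clamp = clamp_voltage,
    pre_phase = pre_phase, t_end = t_end,
    dt = c(fine = dt_fine, coarse = dt_coarse, occ = dt_occ),
    D_K = D_K, ions = ions),
    class = "hotspot_sim")
}

local_ions <- function(ions, f, i, Kin) {
  ion_state(Na_in = ions$Na_in, Na_out = ions$Na_out,
            K_in = Kin[i], K_out = f$K_out[i],
            Glu_in = ions$Glu_in, Glu_out = f$Glu_out[i])
}

#' @export
print.hotspot_sim <- function(x, ...) {
  cat(sprintf("<hotspot_sim> %d compartments, t_end %.0f ms, %s%s\n",
              nrow(x$graph), x$t_end,
              if (is.null(x$clamp)) "free voltage"
              else sprintf("clamped at %g mV", x$clamp),
              if (x$pre_phase == "equilibrate") " (equilibrated pre-phase)" else ""))
  hc <- hotspot_current(x)
  cat(sprintf("  hotspot: peak %.4g pA/um2, tau_decay %.3g ms; ambient Glu %0.3g / %0.3g mM\n",
              -hc$amplitude, hc$tau, x$ambient[[1]], x$ambient[[2]]))
  invisible(x)
}

#' @export
glance.hotspot_sim <- function(x, ...) {
  hc <- hotspot_current(x)
  tibble::tibble(n_comp = nrow(x$graph), amplitude = hc$amplitude,
                 tau_decay = hc$tau, baseline = hc$baseline,
                 v_rest = x$V_rest,
                 ambient_baseline = x$ambient[[1]],
                 ambient_elevated = x$ambient[[2]],
                 clamped = !is.null(x$clamp))
}

#' Peak amplitude and decay of the volume-averaged hotspot current
#'
#' Measures the volume-weighted average transporter current density over the
#' glutamate sphere: peak amplitude relative to the pre-bolus baseline and
#' the monoexponential decay constant of the transient.
#'
#' @param result A [simulate_coupled()] result.
#' @param field Unused (kept for call symmetry); the field stored in
#'   `result` is authoritative.
#'
#' @return A list of class `"hotspot_current"`: `amplitude` (pA/um^2,
#'   positive magnitude), `tau` (ms), `baseline`, `peak_time`, `trace`,
#'   `fit` (a `"decay_fit"`).
#' @export
hotspot_current <- function(result, field = NULL) {
  stopifnot(inherits(result, "hotspot_sim"))
  tr <- result$hotspot
  t0 <- result$field$glu_onset
  pre <- window_idx(tr, t0 - 1.5, t0 - 0.02)
  if (length(pre) < 2) pre <- which(tr$time < t0)
  base <- mean(tr$current[pre])
  post <- window_idx(tr, t0, t0 + 15)
  ip <- post[which.min(tr$current[post])]
  amp <- abs(tr$current[ip] - base)
  fit <- tryCatch(fit_decay_tau(tr, baseline = base, smooth = 0.15),
                  error = function(e) NULL)
  structure(list(amplitude = amp, tau = if (is.null(fit)) NA_real_ else fit$tau,
                 baseline = base, peak_time = tr$time[ip], trace = tr,
                 fit = fit),
            class = "hotspot_current")
}

#' @export
print.hotspot_current <- function(x, ...) {
  cat(sprintf("<hotspot_current> amplitude %.4g pA/um2 (peak at %.2f ms), tau_decay %.3g ms, baseline %.3g\n",
              x$amplitude, x$peak_time, x$tau, x$baseline))
  invisible(x)
}

#' @export
tidy.hotspot_current <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "tau_decay", "baseline"),
                 estimate = c(x$amplitude, x$tau, x$baseline))
}

#' Paired baseline / elevated-K hotspot runs and the suppression percentage
#'
#' Runs [simulate_coupled()] twice — once with the K+ bolus disabled
#' (`k_amplitude = k_baseline`) and once as configured — and reports
#' `100 * (1 - elevated peak / baseline peak)` for the volume-averaged
#' hotspot transporter current.
#'
#' @inheritParams simulate_coupled
#' @param ... Passed to [simulate_coupled()].
#'
#' @return A list of class `"hotspot_suppression"`: `suppression_pct`,
#'   `amplitude_baseline`, `amplitude_elevated`, and the two
#'   `"hotspot_sim"` objects (`baseline`, `elevated`).
#' @export
hotspot_suppression <- function(graph, field, glt1 = glt1_params(),
                                mem = membrane_params(), ...) {
  f_base <- field
  f_base$k_amplitude <- field$k_baseline
  sim_b <- simulate_coupled(graph, f_base, glt1, mem, ...)
  sim_e <- simulate_coupled(graph, field, glt1, mem, ...)
  hb <- hotspot_current(sim_b)
  he <- hotspot_current(sim_e)
  structure(list(
    suppression_pct = 100 * (1 - he$amplitude / hb$amplitude),
    amplitude_baseline = hb$amplitude,
    amplitude_elevated = he$amplitude,
    tau_baseline = hb$tau, tau_elevated = he$tau,
    baseline = sim_b, elevated = sim_e),
    class = "hotspot_suppression")
}

#' @export
print.hotspot_suppression <- function(x, ...) {
  cat(sprintf("<hotspot_suppression> peak %.4g -> %.4g pA/um2: %.1f%% suppression (tau %.3g -> %.3g ms)\n",
              x$amplitude_baseline, x$amplitude_elevated, x$suppression_pct,
              x$tau_baseline, x$tau_elevated))
  invisible(x)
}

#' Paired suppression at increasing distances from the soma
#'
#' Places the glutamate bolus at `n_sites` recording sites of increasing
#' somatic distance inside the K+ sphere and, for each site, runs the paired
#' baseline / elevated-K simulation and records the peak transporter current
#' density and the suppression ratio.
#'
#' @inheritParams simulate_coupled
#' @param n_sites Number of sites (default 10).
#' @param sites Optional integer compartment ids to use as sites (overrides
#'   the automatic placement).
#' @param ... Passed to [simulate_coupled()] (e.g. `pre_phase`, step sizes).
#'
#' @return A tibble of class `"distance_profile"`: `site`, `comp`,
#'   `distance` (um from soma), `peak_baseline`, `peak_elevated` (pA/um^2),
#'   `ratio` (elevated/baseline), `suppression_pct`.
#' @export
distance_profile <- function(graph, field, glt1 = glt1_params(),
                             mem = membrane_params(), n_sites = 10,
                             sites = NULL, ...) {
  stopifnot(n_sites >= 2)
  if (is.null(sites)) {
    d_k <- sqrt((graph$x - field$k_center[1])^2 +
                  (graph$y - field$k_center[2])^2 +
                  (graph$z - field$k_center[3])^2)
    inside <- which(d_k <= field$k_diameter / 2 - field$glu_diameter / 2)
    if (length(inside) < n_sites) {
      stop("distance_profile: fewer than n_sites compartments inside the K+ ",
           "sphere", call. = FALSE)
    }
    ord <- inside[order(graph$dist_soma[inside])]
    targets <- seq(min(graph$dist_soma[ord]), max(graph$dist_soma[ord]),
                   length.out = n_sites)
    sites <- purrr::map_int(targets, function(tg) {
      ord[which.min(abs(graph$dist_soma[ord] - tg))]
    })
    sites <- unique(sites)
    while (length(sites) < n_sites) {
      extra <- setdiff(ord, sites)
      if (!length(extra)) break
      sites <- c(sites, extra[1])
    }
  } else {
    d_site <- graph$dist_soma[match(sites, graph$comp)]
    if (anyNA(d_site)) stop("distance_profile: unknown site compartment",
                            call. = FALSE)
  }
  rows <- purrr::map(seq_along(sites), function(i) {
    cm <- sites[i]
    f <- field
    f$glu_center <- c(graph$x[cm], graph$y[cm], graph$z[cm])
    hs <- hotspot_suppression(graph, f, glt1, mem, ...)
    tibble::tibble(site = i, comp = graph$comp[cm],
                   distance = graph$dist_soma[cm],
                   peak_baseline = hs$amplitude_baseline,
                   peak_elevated = hs$amplitude_elevated,
                   ratio = hs$amplitude_elevated / hs$amplitude_baseline,
                   suppression_pct = hs$suppression_pct)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$distance)
  out$site <- seq_len(nrow(out))
  class(out) <- c("distance_profile", class(out))
  out
}
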