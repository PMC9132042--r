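#' Ion concentrations on both faces of the astrocyte membrane
#'
#' Bundles the six concentrations that drive the GLT-1 transport cycle.
#' Defaults are the initial concentrations of the astrocyte model:
#' Na 15/150 mM (in/out), K 120/3 mM, glutamate 0.3/0 mM.
#'
#' @param Na_in,Na_out Intra-/extracellular Na+ (mM).
#' @param K_in,K_out Intra-/extracellular K+ (mM).
#' @param Glu_in,Glu_out Intra-/extracellular glutamate (mM).
#'
#' @return A named list of class `"ion_state"`.
#' @examples
#' ion_state()
#' ion_state(K_out = 5, Glu_out = 1e-4)
#' @export
ion_state <- function(Na_in = 15, Na_out = 150, K_in = 120, K_out = 3,
                      Glu_in = 0.3, Glu_out = 0) {
  x <- list(Na_in = Na_in, Na_out = Na_out, K_in = K_in, K_out = K_out,
            Glu_in = Glu_in, Glu_out = Glu_out)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("ion_state: `", nm, "` must be a single finite concentration >= 0 (mM)",
           call. = FALSE)
    }
  }
  structure(x, class = "ion_state")
}

#' Parameters of the six-state GLT-1 transporter scheme
#'
#' Rate constants, charge-partition coefficients and surface density of the
#' reduced six-state GLT-1 cycle
#' C1 -> C2 -> C3 -> C4 -> C5 -> C6 -> C1 (forward uptake direction).
#' Second-order constants (`k12`, `k23`, `k54`, `k65`, `k16`, `k61`) are per
#' mM per ms; first-order constants are per ms. Charge-moving transitions are
#' scaled by the voltage factor [u_factor()], `u(V, P) = exp(P*V/slope)`.
#'
#' Two sign conventions for the charge-partition coefficients are supported:
#'
#' * `"fitted"` (default): the four translocation-type steps carry their
#'   charge inward, so their rates are accelerated by hyperpolarization
#'   (signed coefficients `P12 = +0.1`, `P23 = -0.5`, `P34 = -0.4`,
#'   `P56 = -0.6`). This is the convention under which depolarization
#'   suppresses and prolongs uptake, the model behaviour that matches
#'   astrocyte recordings.
#' * `"printed"`: the literal signs of the published scheme
#'   (`P12 = -0.1`, `P23 = +0.5`, `P34 = +0.4`, `P56 = +0.6`), under which
#'   depolarization accelerates the forward cycle. Kept for reference and
#'   cross-checks.
#'
#' The K+o-binding step `C16 = k16 * u(V, p16) * [K]o` uses `p16 = 0.6`
#' (the scheme value) by default; `p16 = 0.1` is the published fitted variant
#' that increases the weight of this step. `p16_prefactor` is the charge
#' weight of the 1<->6 flux in the current equation; by default it equals
#' `abs(p16)` (thermodynamically consistent pairing).
#'
#' @param k12,k21,k23,k32,k34,k43,k45,k54,k56,k65,k16,k61 Rate constants.
#' @param p16 Charge coefficient of the K+o-binding step (0.6 or 0.1).
#' @param charge_signs `"fitted"` or `"printed"` (see Details).
#' @param p16_prefactor Charge weight of the 1<->6 term in the current
#'   equation; default `abs(p16)`.
#' @param slope Voltage slope of `u(V, P)` (mV), default 53.4.
#' @param density Transporter surface density (um^-2), default 1e4.
#' @param e_charge Elementary charge (C), default 1.6e-19.
#'
#' @return A list of class `"glt1_params"` with elements `k` (named rates),
#'   `P` (named signed charge coefficients for steps 12, 23, 34, 56, 16),
#'   `prefactor` (charge weights of the current equation), `slope`,
#'   `density`, `e_charge`.
#' @examples
#' glt1_params()
#' glt1_params(p16 = 0.1)                     # published fitted variant
#' glt1_params(charge_signs = "printed")      # literal printed signs
#' @export
glt1_params <- function(k12 = 20, k21 = 0.1, k23 = 0.015, k32 = 0.5,
                        k34 = 0.2, k43 = 0.6, k45 = 4, k54 = 10,
                        k56 = 1, k65 = 0.1, k16 = 0.0016, k61 = 2e-4,
                        p16 = 0.6,
                        charge_signs = c("fitted", "printed"),
                        p16_prefactor = NULL,
                        slope = 53.4, density = 1e4, e_charge = 1.6e-19) {
  charge_signs <- match.arg(charge_signs)
  k <- c(k12 = k12, k21 = k21, k23 = k23, k32 = k32, k34 = k34, k43 = k43,
         k45 = k45, k54 = k54, k56 = k56, k65 = k65, k16 = k16, k61 = k61)
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("glt1_params: all rate constants must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(slope) || slope <= 0) stop("glt1_params: slope must be > 0", call. = FALSE)
  if (!is.finite(density) || density < 0) stop("glt1_params: density must be >= 0", call. = FALSE)
  if (!is.finite(p16)) stop("glt1_params: p16 must be finite", call. = FALSE)
  sgn <- if (charge_signs == "fitted") -1 else +1
  P <- c(P12 = sgn * -0.1, P23 = sgn * 0.5, P34 = sgn * 0.4, P56 = sgn * 0.6,
         P16 = abs(p16))
  if (is.null(p16_prefactor)) p16_prefactor <- abs(p16)
  prefactor <- c(pre16 = p16_prefactor, pre12 = -0.1, pre23 = 0.5,
                 pre34 = 0.4, pre56 = 0.6)
  structure(list(k = k, P = P, prefactor = prefactor,
                 charge_signs = charge_signs, slope = slope,
                 density = density, e_charge = e_charge),
            class = "glt1_params")
}

#' Astrocyte membrane parameters (Kir4.1 + leak)
#'
#' The Kir4.1 current density is
#' `I_Kir = G_kir * f([K]o) * (V - NK*E_K - V_A1) / (1 + exp((V - NK*E_K - V_A2)/V_A3))`
#' with `E_K` the Nernst K+ potential and `f` a concentration factor
#' (`sqrt([K]o/K_ref)` by default). The leak is `I_pas = G_pas * (V - E_pas)`.
#' Conductances are in mS cm^-2, currents in mA cm^-2, inward negative.
#'
#' @param G_kir Kir conductance density (mS cm^-2), default 0.1.
#' @param V_A1,V_A2,V_A3 Kir voltage parameters (mV): -14.83, -105.82, 19.23.
#' @param NK Dimensionless Nernst-scaling factor, default 0.81.
#' @param G_pas Leak conductance density (mS cm^-2), default 0.001.
#' @param E_pas Leak reversal (mV), default -85.
#' @param C_m Specific capacitance (uF cm^-2), default 1.
#' @param T_kelvin Temperature (K), used only when `nernst_slope = NA`.
#' @param K_ref Reference [K]o of the Kir concentration factor (mM), default 3.
#' @param nernst_slope Nernst slope (mV); default 26.7 (= 53.4/2, consistent
#'   with the transporter voltage slope). `NA` uses RT/F at `T_kelvin`.
#' @param kir_k_factor Concentration-factor dialect: `"sqrt"` (default),
#'   `"linear"` or `"none"`.
#'
#' @return A list of class `"membrane_params"`.
#' @examples
#' membrane_params()
#' membrane_params(kir_k_factor = "linear")
#' @export
membrane_params <- function(G_kir = 0.1, V_A1 = -14.83, V_A2 = -105.82,
                            V_A3 = 19.23, NK = 0.81,
                            G_pas = 0.001, E_pas = -85,
                            C_m = 1, T_kelvin = 307, K_ref = 3,
                            nernst_slope = 26.7,
                            kir_k_factor = c("sqrt", "linear", "none")) {
  kir_k_factor <- match.arg(kir_k_factor)
  if (G_kir < 0 || G_pas < 0) stop("membrane_params: conductances must be >= 0", call. = FALSE)
  if (V_A3 == 0) stop("membrane_params: V_A3 must be nonzero", call. = FALSE)
  if (T_kelvin <= 0) stop("membrane_params: T_kelvin must be > 0", call. = FALSE)
  if (C_m <= 0) stop("membrane_params: C_m must be > 0", call. = FALSE)
  structure(list(G_kir = G_kir, V_A1 = V_A1, V_A2 = V_A2, V_A3 = V_A3,
                 NK = NK, G_pas = G_pas, E_pas = E_pas, C_m = C_m,
                 T_kelvin = T_kelvin, K_ref = K_ref,
                 nernst_slope = nernst_slope, kir_k_factor = kir_k_factor),
            class = "membrane_params")
}

#' @export
print.glt1_params <- function(x, ...) {
  cat("<glt1_params> 6-state GLT-1 scheme\n")
  cat("  rates (/ms or /mM/ms):\n   ")
  cat(paste0(names(x$k), "=", signif(x$k, 4)), fill = 70)
  cat("  charge coefficients (", x$charge_signs, " signs): ", sep = "")
  cat(paste0(names(x$P), "=", x$P), sep = ", ")
  cat("\n  slope ", x$slope, " mV; density ", format(x$density),
      " um^-2\n", sep = "")
  invisible(x)
}

#' @export
print.ion_state <- function(x, ...) {
  cat("<ion_state> (mM) ")
  cat(paste0(names(unclass(x)), "=", unlist(x)), sep = "  ")
  cat("\n")
  invisible(x)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params> Kir4.1 + leak\n")
  cat(sprintf("  G_kir %.3g mS/cm2 (%s [K]o factor, K_ref %.3g mM); V_A1 %.4g, V_A2 %.4g, V_A3 %.4g mV; NK %.3g\n",
              x$G_kir, x$kir_k_factor, x$K_ref, x$V_A1, x$V_A2, x$V_A3, x$NK))
  cat(sprintf("  G_pas %.3g mS/cm2 -> E_pas %.4g mV; C_m %.3g uF/cm2; Nernst slope %s mV\n",
              x$G_pas, x$E_pas, x$C_m,
              if (is.na(x$nernst_slope)) sprintf("RT/F @ %g K", x$T_kelvin)
              else format(x$nernst_slope)))
  invisible(x)
}
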