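# Shared fixtures. Heavy simulation objects are cached per session so that
# multiple test files can reuse them.

cache_env <- function() {
  if (!exists(".gluptake_test_cache", envir = globalenv())) {
    assign(".gluptake_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".gluptake_test_cache", envir = globalenv())
}

cached <- function(key, expr) {
  ce <- cache_env()
  if (!exists(key, envir = ce)) assign(key, force(expr), envir = ce)
  get(key, envir = ce)
}

# small reduced cell: enough leaflets around the bolus site, quick to simulate
small_graph <- function() {
  cached("small_graph", build_reduced_morphology(
    morphology_config(n_primary = 4, leaflet_compartments = 90,
                      sv_target = c(1, 16)),
    seed = 11))
}

default_graph <- function() {
  cached("default_graph", build_reduced_morphology(morphology_config(),
                                                   seed = 42))
}

# a deliberately short hotspot protocol for dynamic tests
short_field <- function(...) {
  stimulus_field(k_duration = 250, glu_onset = 200, ...)
}

# closed-form detailed-balance reversal concentration for the ring scheme
# (independent of the package's root solver)
closed_form_reversal <- function(K_out, V, params, ions = ion_state()) {
  P <- params$P
  expo <- P[["P16"]] - P[["P12"]] - P[["P23"]] - P[["P34"]] - P[["P56"]]
  k <- params$k
  kratio <- (k[["k21"]] * k[["k32"]] * k[["k43"]] * k[["k54"]] * k[["k65"]] *
               k[["k16"]]) /
    (k[["k12"]] * k[["k23"]] * k[["k34"]] * k[["k45"]] * k[["k56"]] *
       k[["k61"]])
  kratio * ions$Glu_in * ions$Na_in * K_out / (ions$Na_out * ions$K_in) *
    exp(expo * V / params$slope)
}

# independent cycle-flux formulation of the steady-state current: on a ring
# the net flux is uniform, so I = -e*den*J12*(total charge weight)
cycle_flux_current <- function(p, V, ions, params) {
  Q <- build_generator(V, ions, params)
  J <- p[1] * Q[1, 2] - p[2] * Q[2, 1]
  pr <- params$prefactor
  total <- pr[["pre12"]] + pr[["pre23"]] + pr[["pre34"]] + pr[["pre56"]] -
    pr[["pre16"]]
  unname(-params$e_charge * params$density * 1e15 * J * total / 10)  # mA/cm2
}

# random scheme draws keeping every effective rate (constant x concentration)
# below ~10 per ms so that fixed-step integration stays comfortably stable
random_glt1 <- function() {
  k1 <- stats::runif(6, 0.05, 5)        # first-order constants
  k2 <- stats::runif(6, 5e-4, 0.05)     # second-order constants (per mM)
  glt1_params(k12 = k2[1], k21 = k1[1], k23 = k2[2], k32 = k1[2],
              k34 = k1[3], k43 = k1[4], k45 = k1[5], k54 = k2[3],
              k56 = k1[6], k65 = k2[4], k16 = k2[5], k61 = k2[6])
}

random_ions <- function() {
  ion_state(Na_in = stats::runif(1, 5, 30), Na_out = stats::runif(1, 100, 160),
            K_in = stats::runif(1, 80, 140), K_out = stats::runif(1, 2, 10),
            Glu_in = stats::runif(1, 0.1, 1), Glu_out = stats::runif(1, 0, 0.2))
}
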