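test_that("nernst_potential follows the logarithmic form", {
  expect_equal(nernst_potential(120, 120), 0)
  expect_equal(nernst_potential(2.5, 120), 26.7 * log(2.5 / 120))
  expect_equal(nernst_potential(5, 120) - nernst_potential(2.5, 120),
               26.7 * log(2), tolerance = 1e-12)
  # physical-temperature option
  expect_equal(nernst_potential(2.5, 120, slope = NA, T_kelvin = 307),
               1000 * 8.314462618 * 307 / 96485.33212 * log(2.5 / 120),
               tolerance = 1e-12)
  expect_error(nernst_potential(0, 120), "> 0")
})

test_that("Kir current vanishes exactly at the numerator root and rectifies", {
  mp <- membrane_params()
  for (ko in c(2.5, 3, 5, 20)) {
    v0 <- mp$NK * nernst_potential(ko, 120, mp$nernst_slope) + mp$V_A1
    expect_equal(kir_current_density(v0, ko, 120, mp), 0, tolerance = 1e-18)
    # single zero: sign change around the root only
    v <- seq(-140, 20, by = 1)
    iv <- kir_current_density(v, ko, 120, mp)
    expect_equal(sum(abs(diff(sign(iv)))) / 2, 1)
  }
  # raising K+o at fixed V makes the current more inward
  iks <- sapply(seq(2.5, 10, by = 0.5), function(k)
    kir_current_density(-85, k, 120, mp))
  expect_true(all(diff(iks) < 0))
  # rectification: strong attenuation relative to the ohmic term at +100 mV
  drive <- 100 - mp$NK * nernst_potential(3, 120) - mp$V_A1
  ohmic <- 1e-3 * mp$G_kir * sqrt(3 / mp$K_ref) * drive
  expect_lt(abs(kir_current_density(100, 3, 120, mp)), abs(ohmic) / 100)
})

test_that("concentration-factor dialects scale as documented", {
  v <- -95
  i_sqrt <- kir_current_density(v, 12, 120, membrane_params())
  i_lin <- kir_current_density(v, 12, 120,
                               membrane_params(kir_k_factor = "linear"))
  i_none <- kir_current_density(v, 12, 120,
                                membrane_params(kir_k_factor = "none"))
  expect_equal(i_lin / i_sqrt, sqrt(12 / 3), tolerance = 1e-12)
  expect_equal(i_sqrt / i_none, sqrt(12 / 3), tolerance = 1e-12)
})

test_that("leak current is affine with the printed slope", {
  mp <- membrane_params()
  expect_equal(leak_current_density(-85, mp), 0)
  expect_equal(leak_current_density(-84, mp), 1e-6)  # mA/cm2
  v1 <- -120; v2 <- -40
  expect_equal(leak_current_density(v1, mp) + leak_current_density(v2, mp),
               2 * leak_current_density((v1 + v2) / 2, mp), tolerance = 1e-15)
})

test_that("resting potential: leak-only limit, bounds and K+o monotonicity", {
  expect_equal(as.numeric(resting_potential(3, params = membrane_params(G_kir = 0))),
               -85, tolerance = 1e-9)
  vr <- as.numeric(resting_potential(3))
  mp <- membrane_params()
  kir_null <- mp$NK * nernst_potential(3, 120) + mp$V_A1
  expect_gt(vr, min(kir_null, mp$E_pas))
  expect_lt(vr, max(kir_null, mp$E_pas))
  # stabilization near E_pas = -85 mV at baseline
  expect_lt(abs(vr + 85), 5)
  # monotone, saturating depolarization with K+o over 2.5-20 mM
  ko <- seq(2.5, 20, by = 2.5)
  vs <- sapply(ko, function(k) as.numeric(resting_potential(k)))
  expect_true(all(diff(vs) > 0))
  expect_lt(diff(vs)[length(vs) - 1], diff(vs)[1])
  # residual current at the root is tiny
  expect_lt(abs(attr(resting_potential(5), "current")), 1e-12)
})

test_that("resting potential with the transporter at ambient reversal is unchanged", {
  amb <- as.numeric(find_reversal_glu(3))
  v0 <- as.numeric(resting_potential(3))
  v1 <- as.numeric(resting_potential(3, include_transporter = TRUE,
                                     ions = ion_state(Glu_out = amb)))
  expect_equal(v1, v0, tolerance = 1e-3)
})

test_that("voltage_step_response relaxes to the resting potential of each K+o", {
  sched <- tibble::tibble(time = c(0, 500), K_out = c(2.5, 5))
  tr <- voltage_step_response(sched, t_end = 4000, dt = 1)
  v25 <- as.numeric(resting_potential(2.5))
  v5 <- as.numeric(resting_potential(5))
  expect_equal(tr$V[tr$time == 400], v25, tolerance = 0.01)
  expect_equal(tr$V[nrow(tr)], v5, tolerance = 0.1)
  # monotone depolarizing relaxation after the step
  seg <- tr$V[tr$time >= 500]
  expect_true(all(diff(seg) >= -1e-9))
  # step up then down returns to the initial resting potential
  sched2 <- tibble::tibble(time = c(0, 500, 3500), K_out = c(2.5, 5, 2.5))
  tr2 <- voltage_step_response(sched2, t_end = 9000, dt = 1)
  expect_equal(tr2$V[nrow(tr2)], v25, tolerance = 0.1)
  # constant schedule stays flat
  tr3 <- voltage_step_response(tibble::tibble(time = 0, K_out = 2.5),
                               t_end = 200, dt = 1)
  expect_lt(max(abs(tr3$V - v25)), 1e-6)
})
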