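test_that("u_factor matches its closed form and rejects bad input", {
  expect_equal(u_factor(0, 0.5), 1)
  expect_equal(u_factor(-40, 0), 1)
  expect_equal(u_factor(53.4, 1), exp(1))
  expect_gt(u_factor(-120, -0.6), 0)
  expect_error(u_factor(NA_real_, 0.5), "finite")
  expect_error(u_factor(-85, Inf), "finite")
})

test_that("build_generator assembles the printed rates", {
  # literal printed dialect: entry(2->3) = [Na]o * k23 * exp(0.5*V/53.4)
  Qp <- build_generator(-85, ion_state(), glt1_params(charge_signs = "printed"))
  expect_equal(Qp[2, 3], 150 * 0.015 * exp(0.5 * (-85) / 53.4),
               tolerance = 1e-12)
  # unit concentrations at V = 0: entry(1->2) = k12
  ones <- ion_state(Na_in = 1, Na_out = 1, K_in = 1, K_out = 1,
                    Glu_in = 1, Glu_out = 1)
  Q1 <- build_generator(0, ones, glt1_params())
  expect_equal(Q1[1, 2], 20)
  # zero substrate
  Q0 <- build_generator(-60, ion_state(Glu_out = 0), glt1_params())
  expect_equal(Q0[1, 2], 0)
  # fitted dialect reverses the translocation-step voltage dependence only
  Qf <- build_generator(-85, ion_state(), glt1_params())
  expect_equal(Qf[2, 3], 150 * 0.015 * exp(-0.5 * (-85) / 53.4),
               tolerance = 1e-12)
  expect_equal(Qf[1, 6], Qp[1, 6])  # K+o-binding step is printed in both
  expect_error(build_generator(c(-85, -60), ion_state(), glt1_params()),
               "single finite")
})

test_that("generators are valid for admissible voltages and ions", {
  set.seed(101)
  for (i in 1:25) {
    V <- stats::runif(1, -120, 40)
    Q <- build_generator(V, random_ions(), glt1_params())
    off <- Q[row(Q) != col(Q)]
    expect_true(all(off >= 0))
    expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
    # only the eight ring transitions are nonzero
    allowed <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3),
                     c(4, 5), c(5, 4), c(5, 6), c(6, 5), c(6, 1), c(1, 6))
    nz <- which(Q != 0 & row(Q) != col(Q), arr.ind = TRUE)
    expect_true(all(paste(nz[, 1], nz[, 2]) %in%
                      paste(allowed[, 1], allowed[, 2])))
  }
})

test_that("steady_state solves symmetric and two-state limits exactly", {
  # symmetric ring: all transitions at the same rate -> uniform occupancy
  Q <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    Q[i, j] <- 1; Q[j, i] <- 1
  }
  diag(Q) <- -rowSums(Q)
  expect_equal(unname(steady_state(Q)), rep(1 / 6, 6), tolerance = 1e-10)
  # two-state reduction: only 1<->2 nonzero -> detailed-balance ratio
  Q2 <- matrix(0, 6, 6)
  Q2[1, 2] <- 0.4; Q2[2, 1] <- 0.1
  diag(Q2) <- -rowSums(Q2)
  expect_error(steady_state(Q2), "degenerate")
})

test_that("steady state occupancy sums to one and matches long-time integration", {
  set.seed(202)
  for (i in 1:20) {
    params <- random_glt1()
    ions <- random_ions()
    V <- stats::runif(1, -100, 0)
    Q <- build_generator(V, ions, params)
    p <- steady_state(Q)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0 & p <= 1))
    # oracle: brute-force integration from a different start
    sched <- function(t) list(V = V, ions = ions)
    traj <- integrate_occupancy(rep(1 / 6, 6), sched, dt = 0.05, t_end = 3000,
                                params = params, record_every = 60000L)
    p_end <- as.numeric(traj[nrow(traj), -1])
    expect_equal(p_end, unname(p), tolerance = 1e-6)
  }
})

test_that("integrate_occupancy conserves probability and honours fixed points", {
  io <- ion_state(Glu_out = 0.1)
  params <- glt1_params()
  p0 <- steady_state(build_generator(-85, io, params))
  sched <- function(t) list(V = -85, ions = io)
  traj <- integrate_occupancy(p0, sched, dt = 0.01, t_end = 5,
                              params = params)
  sums <- rowSums(as.matrix(traj[, -1]))
  expect_true(all(abs(sums - 1) < 1e-8))
  drift <- max(abs(as.matrix(traj[nrow(traj), -1]) - matrix(p0, 1)))
  expect_lt(drift, 1e-8)
})

test_that("a glutamate pulse returns to the pre-pulse steady state", {
  io0 <- ion_state()
  io1 <- ion_state(Glu_out = 0.1)
  params <- glt1_params()
  p0 <- steady_state(build_generator(-85, io0, params))
  sched <- function(t) list(V = -85, ions = if (t < 1) io1 else io0)
  traj <- integrate_occupancy(p0, sched, dt = 0.01, t_end = 1500,
                              params = params, record_every = 10000L)
  p_end <- as.numeric(traj[nrow(traj), -1])
  expect_equal(p_end, unname(p0), tolerance = 1e-6)
  # convergence in dt: halving the step changes the end state negligibly
  traj2 <- integrate_occupancy(p0, sched, dt = 0.005, t_end = 20,
                               params = params, record_every = 4000L)
  traj1 <- integrate_occupancy(p0, sched, dt = 0.01, t_end = 20,
                               params = params, record_every = 2000L)
  expect_lt(max(abs(as.numeric(traj2[nrow(traj2), -1]) -
                      as.numeric(traj1[nrow(traj1), -1]))), 1e-6)
})

test_that("transporter current is linear in density and zero without it", {
  io <- ion_state(Glu_out = 0.1)
  params <- glt1_params()
  p <- steady_state(build_generator(-85, io, params))
  expect_identical(
    transporter_current_density(p, -85, io, glt1_params(density = 0)), 0)
  i1 <- transporter_current_density(p, -85, io, params)
  i2 <- transporter_current_density(p, -85, io, glt1_params(density = 2e4))
  expect_equal(i2, 2 * i1, tolerance = 1e-12)
  # unit conversion: 1 mA/cm2 = 10 pA/um2
  expect_equal(transporter_current_density(p, -85, io, params,
                                           units = "pA/um2"), 10 * i1)
})

test_that("steady-state current equals the independent cycle-flux formulation", {
  set.seed(303)
  for (i in 1:15) {
    params <- random_glt1()
    ions <- random_ions()
    V <- stats::runif(1, -100, -20)
    p <- steady_state(build_generator(V, ions, params))
    i_pkg <- transporter_current_density(p, V, ions, params)
    i_cyc <- cycle_flux_current(p, V, ions, params)
    expect_equal(i_pkg, i_cyc, tolerance = 1e-9)
  }
})

test_that("inward uptake current is suppressed by depolarization", {
  io <- ion_state(Glu_out = 0.1)
  i85 <- steady_state_current(-85, io)
  i40 <- steady_state_current(-40, io)
  expect_lt(i85, 0)   # inward
  expect_lt(i40, 0)
  expect_lt(abs(i40), abs(i85))
  # monotone over a grid
  vals <- sapply(seq(-120, -20, by = 20), steady_state_current, ions = io)
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("find_reversal_glu matches the detailed-balance closed form", {
  params <- glt1_params()
  for (ko in c(2.5, 5, 10)) {
    r <- find_reversal_glu(ko, v_policy = "fixed", V_fixed = -85,
                           params = params)
    expect_equal(as.numeric(r), closed_form_reversal(ko, -85, params),
                 tolerance = 1e-6)
    expect_lt(abs(attr(r, "current")), 1e-15)
  }
  # resting policy uses the membrane model's resting potential
  r5 <- find_reversal_glu(5)
  expect_equal(attr(r5, "V"), as.numeric(resting_potential(5)),
               tolerance = 1e-9)
  expect_equal(as.numeric(r5),
               closed_form_reversal(5, attr(r5, "V"), params),
               tolerance = 1e-6)
})

test_that("reversal glutamate rises monotonically with K+o", {
  ko <- seq(1, 10, by = 0.5)
  vals <- sapply(ko, function(k) as.numeric(find_reversal_glu(k)))
  expect_true(all(diff(vals) > 0))
})

test_that("find_reversal_glu reports the current sign when unbracketed", {
  expect_error(find_reversal_glu(5, bracket = c(1e-3, 1)),
               "no sign change.*inward")
})
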