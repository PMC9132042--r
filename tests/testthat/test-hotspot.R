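# dynamic invariants of the coupled simulation, on a small cell and a short
# protocol so each run stays in the seconds range

quiet_field <- function() {
  stimulus_field(k_amplitude = 2.5, k_duration = 250, glu_onset = 200,
                 glu_peak = 0)
}

test_that("an unperturbed simulation stays at rest", {
  g <- small_graph()
  sim <- cached("sim_quiet",
                simulate_coupled(g, quiet_field(), t_end = 260,
                                 record_dt = 20))
  tr <- sim$traces
  expect_lt(max(abs(tr$V - sim$V_rest)), 0.5)
  # the standing Kir/leak exchange moves internal K+ by < 0.01 mM over the run
  expect_lt(max(abs(tr$K_in - 120)), 5e-3)
  expect_lt(max(abs(tr$i_glut)), 1e-5)
  expect_lt(max(abs(sim$hotspot$current)), 1e-5)
  # occupancy conservation at every record
  sums <- tr$p1 + tr$p2 + tr$p3 + tr$p4 + tr$p5 + tr$p6
  expect_lt(max(abs(sums - 1)), 1e-8)
})

test_that("a K+ bolus depolarizes, loads K+ modestly and then dissipates", {
  g <- small_graph()
  f <- stimulus_field(k_duration = 250, glu_onset = 200, glu_peak = 0)
  sim <- cached("sim_kbolus",
                simulate_coupled(g, f, t_end = 1400, record_dt = 20))
  tr <- sim$traces
  inside <- g$comp[g$dist_soma <= 10]
  during <- tr[tr$time == 240 & tr$comp %in% inside, ]
  expect_gt(mean(during$V), sim$V_rest + 0.5)       # depolarized
  rise <- max(tr$K_in[tr$comp %in% inside]) - 120
  expect_gt(rise, 0)
  expect_lt(rise, 1)                                # well under 1 mM
  # post-offset decay of intracellular K+
  k_end <- tr[tr$time == max(tr$time) & tr$comp %in% inside, ]
  k_peak <- stats::aggregate(K_in ~ comp, tr[tr$comp %in% inside, ], max)
  expect_lt(mean(k_end$K_in - 120), 0.9 * mean(k_peak$K_in - 120))
  # charge-to-mass consistency: total K+ gained matches integrated Kir charge
  final <- tr[tr$time == max(tr$time), ]
  gained <- sum((final$K_in - 120) * g$volume[match(final$comp, g$comp)])
  expected <- 0.0103642697 * sum(sim$kir_charge$charge_pA_ms)
  expect_equal(gained, expected, tolerance = 0.01)
})

test_that("identical simulations give identical outputs", {
  g <- small_graph()
  f <- stimulus_field(k_duration = 120, glu_onset = 100)
  s1 <- simulate_coupled(g, f, t_end = 130, pre_phase = "equilibrate")
  s2 <- simulate_coupled(g, f, t_end = 130, pre_phase = "equilibrate")
  expect_identical(s1$hotspot$current, s2$hotspot$current)
  expect_identical(s1$traces, s2$traces)
})

test_that("the hotspot transporter current is linear in density", {
  g <- small_graph()
  f <- stimulus_field(k_duration = 120, glu_onset = 100)
  a1 <- hotspot_current(cached("sim_den1",
    simulate_coupled(g, f, t_end = 130, pre_phase = "equilibrate")))$amplitude
  a2 <- hotspot_current(
    simulate_coupled(g, f, glt1 = glt1_params(density = 2e4), t_end = 130,
                     pre_phase = "equilibrate"))$amplitude
  expect_equal(a2 / a1, 2, tolerance = 0.02)
})

test_that("the volume-weighted hotspot average reproduces its definition", {
  g <- small_graph()
  f <- stimulus_field(k_duration = 120, glu_onset = 100)
  sim <- cached("sim_den1",
                simulate_coupled(g, f, t_end = 130, pre_phase = "equilibrate"))
  hotc <- sim$hotspot_comps
  w <- g$volume[match(hotc, g$comp)]
  w <- w / sum(w)
  t_rec <- 120
  snap <- sim$traces[sim$traces$time == t_rec & sim$traces$comp %in% hotc, ]
  manual <- sum(w[match(snap$comp, hotc)] * snap$i_glut)
  near <- which.min(abs(sim$hotspot$time - t_rec))
  expect_equal(sim$hotspot$current[near], manual, tolerance = 0.02)
})

test_that("equilibrated and fully integrated pre-phases agree", {
  g <- small_graph()
  f <- stimulus_field(k_duration = 400, glu_onset = 350)
  full <- simulate_coupled(g, f, t_end = 380)
  fast <- simulate_coupled(g, f, t_end = 380, pre_phase = "equilibrate")
  expect_equal(hotspot_current(fast)$amplitude,
               hotspot_current(full)$amplitude, tolerance = 0.02)
})

test_that("hotspot geometry errors are reported", {
  g <- small_graph()
  f <- stimulus_field(glu_center = c(200, 0, 0), k_center = c(196, 0, 0),
                      k_duration = 100, glu_onset = 50)
  expect_error(simulate_coupled(g, f, t_end = 60), "glutamate sphere")
})
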