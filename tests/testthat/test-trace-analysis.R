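test_that("scaled-tail subtraction recovers scale and component exactly without noise", {
  cfg <- synth_config(protocol = "single", seed = 4, noise_sd = 0)
  st <- synth_trace(cfg)
  # pure-K case: combined = 2 x template
  pure <- with_values(st$ik, 2 * st$ik$current, condition = "combined")
  iso <- isolate_transporter_current(pure, st$ik)
  expect_lt(max(abs(iso$current)), 1e-9)
  expect_equal(attr(iso, "scale"), 2, tolerance = 1e-12)
  # known transporter + 1.3 x template
  comb <- with_values(st$iglut, st$iglut$current + 1.3 * st$ik$current,
                      condition = "combined")
  # with a late tail window the residual fast component is < 1e-6 of scale
  iso_late <- isolate_transporter_current(comb, st$ik,
                                          tail_window = c(80, 400))
  expect_equal(attr(iso_late, "scale"), 1.3, tolerance = 1e-6)
  iso2 <- isolate_transporter_current(comb, st$ik)
  expect_equal(attr(iso2, "scale"), 1.3, tolerance = 1e-5)
  peak_err <- abs(min(iso2$current) - min(st$iglut$current)) /
    abs(min(st$iglut$current))
  expect_lt(peak_err, 0.02)
  # ill-conditioned template
  flat <- with_values(st$ik, rep(0, nrow(st$ik)))
  expect_error(isolate_transporter_current(comb, flat), "ill-conditioned")
})

test_that("subtraction is linear in the non-template component", {
  cfg <- synth_config(protocol = "single", seed = 6, noise_sd = 0)
  st <- synth_trace(cfg)
  a <- 2.5
  x <- with_values(st$iglut, st$iglut$current + 0.9 * st$ik$current)
  ax <- with_values(st$iglut, a * st$iglut$current + 0.9 * st$ik$current)
  iso_x <- isolate_transporter_current(x, st$ik)
  iso_ax <- isolate_transporter_current(ax, st$ik)
  expect_equal(iso_ax$current, a * iso_x$current, tolerance = 1e-6)
})

test_that("decay fitting is exact on a pure exponential", {
  tt <- seq(0, 120, 0.1)
  y <- -8 * exp(-pmax(tt - 10, 0) / 10) - 1
  y[tt < 10] <- -9   # peak at t = 10
  tr <- new_trace(tibble::tibble(time = tt, current = y), stim_times = 9)
  fit <- fit_decay_tau(tr, baseline = -1)
  expect_equal(fit$tau, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 8, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(tidy(fit)$estimate[1], fit$tau)
  expect_equal(glance(fit)$n, fit$n)
})

test_that("decay recovery from noisy synthetic transients is unbiased", {
  taus <- sapply(1:20, function(s) {
    st <- synth_trace(synth_config(protocol = "single", seed = 400 + s,
                                   noise_sd = 1))
    iso <- isolate_transporter_current(st$combined, st$ik)
    fit_decay_tau(iso)$tau
  })
  expect_lt(abs(mean(taus) - 5.75) / 5.75, 0.05)
})

test_that("a biexponential transient is flagged by its residual norm", {
  tt <- seq(0, 150, 0.1)
  mono <- -10 * exp(-pmax(tt - 5, 0) / 8)
  bi <- -6 * exp(-pmax(tt - 5, 0) / 3) - 6 * exp(-pmax(tt - 5, 0) / 40)
  mono[tt < 5] <- 0; bi[tt < 5] <- 0
  f_mono <- fit_decay_tau(new_trace(tibble::tibble(time = tt, current = mono),
                                    stim_times = 4.9), baseline = 0)
  f_bi <- fit_decay_tau(new_trace(tibble::tibble(time = tt, current = bi),
                                  stim_times = 4.9), baseline = 0)
  expect_lt(f_mono$resid_norm, 1e-6)
  expect_gt(f_bi$resid_norm, 100 * f_mono$resid_norm)
})

test_that("non-convergent fits are reported honestly", {
  tt <- seq(0, 30, 0.1)
  y <- -5 * exp(-pmax(tt - 2, 0) / 1e9)   # effectively constant: tau at bound
  tr <- new_trace(tibble::tibble(time = tt, current = y), stim_times = 1.9)
  fit <- fit_decay_tau(tr, baseline = 0, window = c(2, 30))
  expect_false(fit$converged)
})

test_that("train peaks: identical well-separated responses give a flat profile", {
  dt <- 0.1
  tt <- seq(0, 600, dt)
  y <- numeric(length(tt))
  stim <- 50 + 100 * (0:4)
  k <- make_kernel(0.5, 4, peak = 10, dt = dt, t_end = 80)
  for (s in stim) {
    idx <- which(tt >= s)[seq_len(nrow(k))]
    y[idx] <- y[idx] + k$current
  }
  tr <- new_trace(tibble::tibble(time = tt, current = y), stim_times = stim)
  prof <- train_peak_amplitudes(tr, ref_amplitude = 10)
  expect_equal(prof$norm_amplitude, rep(1, 5), tolerance = 1e-3)
  expect_false(any(prof$flagged))
})

test_that("programmed facilitation is recovered from overlapping trains", {
  fac <- c(1, 1.4, 1.8, 2.1, 2.3)
  cfg <- synth_config(protocol = "train", seed = 12, noise_sd = 0,
                      facilitation_iglut = fac,
                      tau_scale_iglut = rep(1, 5),
                      ik = list(tau_rise = 10, tau_decay = 300, peak = 0))
  st <- synth_trace(cfg)
  ref <- -min(make_kernel(1, 5.75, peak = 10, dt = 0.1)$current)
  prof <- train_peak_amplitudes(st$combined, ref_amplitude = ref,
                                baseline_rule = "extrapolate")
  expect_equal(prof$norm_amplitude, fac, tolerance = 0.05)
  # the extrapolated-decay rule corrects overlap better than prestim
  prof_ps <- train_peak_amplitudes(st$combined, ref_amplitude = ref,
                                   baseline_rule = "prestim")
  err_ex <- max(abs(prof$norm_amplitude - fac) / fac)
  err_ps <- max(abs(prof_ps$norm_amplitude - fac) / fac)
  expect_lte(err_ex, err_ps + 1e-9)
  # normalization linearity
  prof_half <- train_peak_amplitudes(st$combined, ref_amplitude = ref / 2)
  expect_equal(prof_half$norm_amplitude, 2 * prof$norm_amplitude,
               tolerance = 1e-12)
})

test_that("slow K+ current is measured at the configured offset", {
  flat <- new_trace(tibble::tibble(time = seq(0, 500, 0.5),
                                   current = rep(0, 1001)), stim_times = 50)
  expect_equal(as.numeric(measure_k_current(flat)), 0)
  cfg <- synth_config(protocol = "single", seed = 9, noise_sd = 0,
                      iglut = list(tau_rise = 1, tau_decay = 5.75, peak = 0),
                      t_end = 600)
  st <- synth_trace(cfg)
  got <- measure_k_current(st$combined, offset = 200, width = 20)
  w <- attr(got, "window")
  truth <- mean(st$ik$current[st$ik$time >= w[1] & st$ik$time <= w[2]])
  expect_equal(as.numeric(got), truth, tolerance = 1e-9)
  # a pure fast transient has fully decayed 200 ms later
  fast <- synth_trace(synth_config(protocol = "single", seed = 10,
                                   noise_sd = 0, t_end = 600,
                                   iglut = list(tau_rise = 1, tau_decay = 6,
                                                peak = 50),
                                   ik = list(tau_rise = 10, tau_decay = 300,
                                             peak = 0)))
  resid <- as.numeric(measure_k_current(fast$combined))
  expect_lt(abs(resid), 1e-12 * 50)
  expect_error(measure_k_current(st$combined, offset = 1e4), "beyond")
})
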