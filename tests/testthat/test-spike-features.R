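test_that("firing rate averages over all cells including silent ones", {
  expect_equal(firing_rate(10, 1, 2000), 5)
  expect_equal(firing_rate(10, 2, 2000), 2.5)
  expect_equal(firing_rate(0, 5, 2000), 0)
  expect_equal(firing_rate(3, 0, 2000), 0)
  expect_error(firing_rate(1, 1, 0), "duration")
})

test_that("burst fraction follows the 10 ms chaining rule", {
  expect_equal(burst_fraction(list(c(0, 5, 8, 100))), 0.5)
  expect_equal(burst_fraction(list(c(0, 20, 40, 80))), 0)
  expect_equal(burst_fraction(list(c(0, 4))), 1)
  expect_true(is.na(burst_fraction(list(c(5)))))       # < 2 spikes: excluded
  expect_true(is.na(burst_fraction(list(numeric(0)))))
  # mean over eligible neurons only
  expect_equal(burst_fraction(list(c(0, 5, 8, 100), c(3), c(0, 50))), 0.25)
})

test_that("burst fraction matches a brute-force chain enumeration", {
  set.seed(1)
  for (i in 1:20) {
    ts <- sort(runif(sample(2:30, 1), 0, 500))
    expect_equal(burst_fraction(list(ts)), burst_oracle(ts))
  }
})

test_that("circular mean phase matches hand values", {
  expect_equal(mean_phase(c(0, 0)), 0)
  expect_equal(mean_phase(pi / 2), pi / 2)
  expect_equal(mean_phase(c(0, pi / 2)), pi / 4)
  expect_true(is.na(mean_phase(numeric(0))))
})

test_that("PPC matches closed-form examples and the pairwise oracle", {
  expect_equal(ppc(c(0, 0)), 1)
  expect_equal(ppc(c(0, pi)), -1)
  expect_equal(ppc(c(0, pi / 2, pi)), -1 / 3)
  expect_true(is.na(ppc(0)))
  set.seed(2)
  for (i in 1:10) {
    ph <- runif(sample(3:40, 1), -pi, pi)
    expect_equal(ppc(ph), ppc_oracle(ph), tolerance = 1e-10)
  }
})

test_that("PPC is unbiased: uniform phases, rotation, subsampling", {
  set.seed(3)
  vals <- replicate(50, ppc(runif(400, -pi, pi)))
  # E[PPC] = 0 for uniform phases; SE of the mean ~ 1/sqrt(50 * N)
  expect_lt(abs(mean(vals)), 3 / sqrt(50 * 400))
  # global rotation leaves PPC unchanged, shifts the mean phase exactly
  ph <- rnorm(200, 0, 0.5)
  expect_equal(ppc(ph), ppc(ph + 1), tolerance = 1e-10)
  expect_equal(wrap_pi(mean_phase(ph) + 1), mean_phase(wrap_pi(ph + 1)),
               tolerance = 1e-8)
  # subsampled PPC estimates full-set PPC without bias
  set.seed(4)
  big <- oscmotifs:::rvonmises(5000, 0, 1.5)
  full <- ppc(big)
  subs <- replicate(200, ppc(big[sample.int(5000, 500)]))
  expect_lt(abs(mean(subs) - full), 0.01)
})

test_that("PPC of von Mises phases matches the Bessel-ratio closed form", {
  set.seed(5)
  for (kappa in c(0.5, 2)) {
    ph <- oscmotifs:::rvonmises(20000, 0, kappa)
    expected <- (besselI(kappa, 1) / besselI(kappa, 0))^2
    expect_lt(abs(ppc(ph) - expected), 0.01)
  }
})

test_that("instantaneous phase is 0 at peaks, +-pi at troughs of a tone", {
  fs <- 1000
  f <- 10
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * f * t)
  ph <- instantaneous_phase(x, fs, f)
  # sample at the maxima and minima away from the edges
  peak_idx <- which(t %in% (2:15 / f))
  trough_idx <- which(abs((t * f) %% 1 - 0.5) < 1e-9 & t > 0.2 & t < 1.8)
  expect_true(all(abs(ph[peak_idx]) < 0.15))
  expect_true(all(abs(abs(ph[trough_idx]) - pi) < 0.15))
  # phase velocity of the analytic signal matches the tone frequency
  un <- oscmotifs:::unwrap_phase(ph[200:1800])
  slope <- mean(diff(un)) * fs / (2 * pi)
  expect_equal(slope, f, tolerance = 0.05)
  expect_error(instantaneous_phase(x, fs, 600), "Nyquist")
})

test_that("spike summary recovers locking of a synthetic raster", {
  set.seed(6)
  lr <- make_locked_raster(n_cells = 30, rate = 30, f = 10, kappa = 8,
                           duration = 2, fs = 1000)
  ph_trace <- instantaneous_phase(lr$reference, lr$fs, lr$f)
  ph <- oscmotifs:::phase_at_times(ph_trace, lr$fs,
                                   unlist(lr$spike_trains))
  # strongly locked at phase 0
  expect_gt(ppc(ph), 0.5)
  expect_lt(abs(mean_phase(ph)), 0.3)
  # and kappa = 0 gives no locking
  lr0 <- make_locked_raster(n_cells = 30, rate = 30, f = 10, kappa = 0,
                            duration = 2, fs = 1000)
  ph0 <- oscmotifs:::phase_at_times(ph_trace, lr0$fs,
                                    unlist(lr0$spike_trains))
  expect_lt(abs(ppc(ph0)), 3 / sqrt(length(ph0)) + 0.02)
})
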