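test_that("cell parameter sampling matches the stated distributions", {
  cts <- default_cell_types()
  set.seed(1)
  rs <- sample_cell_parameters(cts$RS)
  expect_true(all(rs$a == 0.020))
  expect_true(all(rs$b == 0.20))
  expect_true(all(rs$c >= -65 & rs$c <= -50))
  expect_true(all(rs$d >= 2 & rs$d <= 8))

  fs_spec <- cts$FS; fs_spec$count <- 10000L
  fs <- sample_cell_parameters(fs_spec)
  expect_true(all(fs$a >= 0.10 & fs$a <= 0.18))
  expect_true(all(fs$b >= 0.15 & fs$b <= 0.20))
  expect_true(all(fs$c == -65) && all(fs$d == 2))

  lts_spec <- cts$LTS; lts_spec$count <- 10000L
  lts <- sample_cell_parameters(lts_spec)
  expect_true(all(lts$a >= 0.020 & lts$a <= 0.025))
  expect_true(all(lts$b >= 0.20 & lts$b <= 0.25))

  # RS heterogeneity follows the squared-uniform construction: Beta(0.5, 1)
  # pushes c toward -65 (mean -65 + 15/3 = -60) and d toward 8 (mean 6)
  rs_spec <- cts$RS; rs_spec$count <- 20000L
  set.seed(2)
  rs2 <- sample_cell_parameters(rs_spec)
  expect_equal(mean(rs2$c), -60, tolerance = 0.01)
  expect_equal(mean(rs2$d), 6, tolerance = 0.01)

  empty <- cts$RS; empty$count <- 0L
  p0 <- sample_cell_parameters(empty)
  expect_length(p0$a, 0)
})

test_that("unknown cell type or invalid spec is a configuration error", {
  expect_error(cell_type_spec("PV", 10, list(kind = "constant", value = 1),
                              list(kind = "constant", value = 1),
                              list(kind = "constant", value = 1),
                              list(kind = "constant", value = 1),
                              2, 1, 0.5),
               "unknown cell type")
  cst <- list(kind = "constant", value = 1)
  expect_error(cell_type_spec("FS", 10, cst, cst, cst, cst,
                              tau_syn = 3, weight_mean = 1, weight_sd = 1),
               "inhibitory")
  expect_error(cell_type_spec("RS", 10, cst, cst, cst, cst,
                              tau_syn = 0, weight_mean = 1, weight_sd = 1),
               "tau_syn")
})

test_that("initial conditions follow V0 ~ U(-80, -70) and U0 = b V0 + d", {
  st <- init_state(b = 0.2, d = 2, v0 = -75)
  expect_equal(st$U, -13)
  set.seed(3)
  big <- init_state(b = rep(0.2, 10000), d = rep(2, 10000))
  expect_true(all(big$V >= -80 & big$V <= -70))
  expect_equal(big$U, 0.2 * big$V + 2)
  # the conventional alternative is exposed as a switch
  alt <- init_state(b = 0.2, d = 2, v0 = -75, u0_rule = "bv")
  expect_equal(alt$U, -15)
  nil <- init_state(numeric(0), numeric(0))
  expect_length(nil$V, 0)
})

test_that("Euler step reproduces hand-computed updates and the reset rule", {
  # reset: entering the step above threshold (a = 0 isolates the reset rule)
  prm <- list(a = 0, b = 0.2, c = -65, d = 2)
  st <- izhikevich_step(list(V = 35, U = 5), prm, I = 0, dt = 0.2)
  expect_true(st$spiked)
  expect_equal(st$V, -65)
  expect_equal(st$U, 7)

  # fixed point of the RS nullclines at V = -70, U = bV
  prm2 <- list(a = 0.02, b = 0.2, c = -65, d = 2)
  st2 <- izhikevich_step(list(V = -70, U = -14), prm2, I = 0, dt = 0.2)
  expect_equal(st2$V, -70)
  expect_equal(st2$U, -14)
  expect_false(st2$spiked)

  # one hand-computed Euler step
  st3 <- izhikevich_step(list(V = -60, U = 0), prm2, I = 10, dt = 0.2)
  expect_equal(st3$V, -61.2)
  expect_equal(st3$U, -0.048)

  expect_error(izhikevich_step(list(V = -60, U = 0), prm2, I = NaN, dt = 0.2),
               "non-finite")
})

test_that("after any step all voltages are below threshold", {
  set.seed(4)
  sim <- run_simulation(get_motif("I"), drive_spec(3000, 1000), seed = 11,
                        t_total = 400)
  # the LFP mean can only stay below 30 if every neuron does
  expect_true(all(sim$lfp < 30))
  st <- list(V = runif(50, -80, 40), U = rnorm(50))
  prm <- list(a = rep(0.02, 50), b = rep(0.2, 50), c = rep(-65, 50),
              d = rep(2, 50))
  out <- izhikevich_step(st, prm, I = rnorm(50, 0, 20), dt = 0.2)
  expect_true(max(out$V) < 30)
})

test_that("f-I curves are monotone and LTS activates before FS", {
  rates <- seq(0, 5000, 1000)
  mean_rates <- memo("fi_curves", {
    out <- array(0, c(length(rates), 3, 10),
                 dimnames = list(NULL, c("RS", "FS", "LTS"), NULL))
    cts <- default_cell_types(30, 30, 30)
    for (s in 1:10) {
      prep <- prepare_simulation(isolated_motif(), seed = 100 + s,
                                 cell_types = cts)
      for (i in seq_along(rates)) {
        sim <- execute_simulation(prep, drive_spec(rates[i], rates[i],
                                                   rates[i]),
                                  t_total = 1200, t_burnin = 200)
        win <- analysis_window(sim)
        for (ty in c("RS", "FS", "LTS"))
          out[i, ty, s] <- firing_rate(sum(win$spike_types == ty), 30,
                                       win$t_total)
      }
    }
    apply(out, c(1, 2), mean)
  })
  # non-decreasing in input rate, within Monte-Carlo slack
  for (ty in c("RS", "FS", "LTS"))
    expect_true(all(diff(mean_rates[, ty]) > -0.5))
  # LTS has the lowest activation threshold of the interneurons
  first_active <- function(ty) rates[which(mean_rates[, ty] > 0.1)[1]]
  expect_lt(first_active("LTS"), first_active("FS"))
})

test_that("identical seeds give identical draws and trajectories", {
  set.seed(5); p1 <- sample_cell_parameters(default_cell_types()$RS)
  set.seed(5); p2 <- sample_cell_parameters(default_cell_types()$RS)
  expect_identical(p1, p2)
  s1 <- run_simulation(get_motif("I"), drive_spec(2500, 1000), seed = 9,
                       t_total = 500)
  s2 <- run_simulation(get_motif("I"), drive_spec(2500, 1000), seed = 9,
                       t_total = 500)
  expect_identical(s1$lfp, s2$lfp)
  expect_identical(s1$spike_times, s2$spike_times)
})
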