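# step-by-step R mirror of the compiled loop for a deterministic circuit
# (no drive, no noise, so no RNG is consumed): decay traces, deliver delayed
# spikes, Euler update, reset, LFP with 30 mV clipping
r_loop_mirror <- function(a, b, cc, d, v0, u0, ptr, post, w, tau_pre, type,
                          offset, dt, n_steps, delay_steps) {
  nt <- length(tau_pre); n <- length(a)
  g <- matrix(0, nt, n)
  dec <- exp(-dt / tau_pre)
  V <- v0; U <- u0
  lfp <- numeric(n_steps)
  spike_log <- vector("list", n_steps)
  spike_step <- integer(0); spike_id <- integer(0)
  for (s in seq_len(n_steps)) {
    g <- g * dec
    if (s - delay_steps >= 1) {
      for (j in spike_log[[s - delay_steps]]) {
        if (ptr[j + 2] > ptr[j + 1]) {
          es <- (ptr[j + 1] + 1):ptr[j + 2]
          for (e in es)
            g[type[j + 1] + 1, post[e] + 1] <-
              g[type[j + 1] + 1, post[e] + 1] + w[e]
        }
      }
    }
    I <- colSums(g) + offset
    Vn <- V + dt * (0.04 * V^2 + 5 * V + 140 - U + I)
    Un <- U + dt * (a * (b * V - U))
    sp <- Vn >= 30
    lfp[s] <- mean(ifelse(sp, 30, Vn))
    Un[sp] <- Un[sp] + d[sp]
    Vn[sp] <- cc[sp]
    V <- Vn; U <- Un
    spike_log[[s]] <- which(sp) - 1L
    spike_step <- c(spike_step, rep(s - 1L, sum(sp)))
    spike_id <- c(spike_id, which(sp) - 1L)
  }
  list(lfp = lfp, spike_step = spike_step, spike_id = spike_id)
}

test_that("compiled loop matches the R reference on a toy circuit", {
  # 3 neurons: 0 drives 1 (excitatory), 2 inhibits 1; 0 and 2 self-firing
  a <- c(0.02, 0.02, 0.1); b <- c(0.2, 0.2, 0.15)
  cc <- c(-65, -65, -65); d <- c(2, 2, 2)
  type <- c(0L, 0L, 1L)          # RS, RS, FS
  v0 <- c(-70, -75, -72); u0 <- b * v0 + d
  # CSR: neuron0 -> 1 (w 20), neuron2 -> 1 (w -15)
  ptr <- c(0L, 1L, 1L, 2L); post <- c(1L, 1L); w <- c(20, -15)
  tau_pre <- c(2, 3)
  offset <- c(8, 0, 9)
  n_steps <- 1000L
  res <- oscmotifs:::.sim_core_cpp(
    a, b, cc, d, type, v0, u0, ptr, post, w, tau_pre,
    drive_rate = rep(0, 3), noise_offset = offset, noise_sd = 0,
    tau_drive = 2, dt = 0.2, n_steps = n_steps, delay_steps = 5L,
    seed = 1, schedule = matrix(numeric(0), ncol = 5), lfp_clip = TRUE)
  ref <- r_loop_mirror(a, b, cc, d, v0, u0, ptr, post, w, tau_pre, type,
                       offset, 0.2, n_steps, 5L)
  expect_gt(length(res$spike_step), 5)     # the toy circuit does fire
  expect_equal(res$lfp, ref$lfp, tolerance = 1e-8)
  expect_identical(res$spike_step, ref$spike_step)
  expect_identical(res$spike_id, ref$spike_id)
})

test_that("zero input produces no spikes and a resting LFP", {
  sim <- run_simulation(get_motif("I"), drive_spec(0, 0),
                        noise = noise_spec(0, 0, 0), seed = 1, t_total = 500)
  expect_length(sim$spike_times, 0)
  # settles near the quiescent fixed point of the V nullcline
  expect_true(abs(tail(sim$lfp, 1) + 70) < 5)
  expect_length(sim$lfp, 500 / 0.2)
})

test_that("zeroed weights reproduce isolated-neuron trajectories", {
  prep1 <- prepare_simulation(get_motif("I"), seed = 21)
  prep2 <- prep1
  prep2$csr$w[] <- 0
  prep3 <- prep1
  prep3$conn <- ablate_edges(prep3$conn, get_motif("I")$edges)
  prep3$csr <- oscmotifs:::conn_to_csr(prep3$conn)
  s2 <- execute_simulation(prep2, drive_spec(3000, 2000), t_total = 500)
  s3 <- execute_simulation(prep3, drive_spec(3000, 2000), t_total = 500)
  expect_identical(s2$lfp, s3$lfp)
  expect_identical(s2$spike_times, s3$spike_times)
})

test_that("repeats reuse seeds across conditions and differ across repeats", {
  sims_a <- run_repeats(get_motif("I"), drive_spec(2000, 500),
                        n_repeats = 3, master_seed = 7, t_total = 400)
  sims_b <- run_repeats(get_motif("I"), drive_spec(3000, 1500),
                        n_repeats = 3, master_seed = 7, t_total = 400)
  # same repeat index => same seed => same network
  expect_equal(sims_a[[2]]$seed, sims_b[[2]]$seed)
  p1 <- prepare_simulation(get_motif("I"), seed = sims_a[[2]]$seed)
  p2 <- prepare_simulation(get_motif("I"), seed = sims_b[[2]]$seed)
  expect_identical(p1$conn, p2$conn)
  # repeats differ from each other
  expect_false(identical(sims_a[[1]]$lfp, sims_a[[2]]$lfp))
  expect_length(run_repeats(get_motif("I"), drive_spec(0, 0),
                            n_repeats = 1, master_seed = 1,
                            t_total = 400), 1)
})

test_that("spike bookkeeping and analysis window are consistent", {
  sim <- run_simulation(get_motif("I"), drive_spec(3000, 1000), seed = 3,
                        t_total = 600, t_burnin = 100)
  expect_true(all(sim$spike_times > 0 & sim$spike_times <= 600))
  expect_equal(length(sim$spike_times), length(sim$spike_ids))
  win <- analysis_window(sim)
  expect_length(win$lfp, (600 - 100) / 0.2)
  expect_true(all(win$spike_times > 0 & win$spike_times <= 500))
  expect_equal(win$t_total, 500)
})
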