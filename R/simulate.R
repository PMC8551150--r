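#' Simulate a circuit motif
#'
#' Runs the forward-Euler integration (step 0.2 ms) of an Izhikevich circuit
#' for `t_total` ms: per step, delayed synaptic currents (recursive
#' exponential traces per presynaptic type), Poisson background drive through
#' the AMPA kernel, static-offset plus per-step Gaussian noise, the Euler
#' update with threshold reset at 30 mV, and the LFP sample (mean membrane
#' voltage over all neurons, spiking neurons contributing the 30 mV threshold
#' value at their spike step).
#'
#' The seed controls everything: cell parameters, connectivity, weights,
#' initial conditions and noise offsets are drawn from R's RNG seeded with
#' `seed`, and the per-step drive/noise streams use a compiled RNG seeded
#' with the same value. The same seed therefore reproduces the simulation
#' bit-for-bit, and two drive conditions run with the same seed share their
#' connection pattern and noise.
#'
#' @param motif a [motif_spec()] (or a numeral accepted by [get_motif()]).
#' @param drive a [drive_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param dt Euler step, ms.
#' @param t_total simulated time, ms.
#' @param t_burnin initial window discarded by analysis functions, ms.
#' @param cell_types optional population override (defaults to
#'   [motif_cell_types()]).
#' @param ablate optional character vector of edges removed after network
#'   assembly (see [ablate_edges()]); the rest of the network is untouched.
#' @param lfp_clip clip spiking neurons at the 30 mV threshold in the LFP
#'   sample (default) instead of using the raw pre-reset overshoot.
#' @param u0_rule initial-condition rule for `U` (see [init_state()]).
#' @return object of class `sim_result` with `spike_times` (ms),
#'   `spike_ids`, `spike_types`, `lfp`, `dt`, `t_total`, `t_burnin`, `fs`,
#'   population counts and seed provenance.
#' @export
run_simulation <- function(motif, drive, noise = noise_spec(), seed = 1,
                           dt = 0.2, t_total = 2300, t_burnin = 300,
                           cell_types = NULL, ablate = NULL,
                           lfp_clip = TRUE,
                           u0_rule = c("bv_plus_d", "bv")) {
  prep <- prepare_simulation(motif, seed = seed, dt = dt,
                             cell_types = cell_types, ablate = ablate,
                             noise = noise, u0_rule = u0_rule)
  execute_simulation(prep, drive, t_total = t_total, t_burnin = t_burnin,
                     lfp_clip = lfp_clip)
}

#' Prepare a simulation (network, parameters, initial state)
#'
#' Samples everything that is drive-independent for one (motif, seed) pair.
#' The returned object can be passed to [execute_simulation()] repeatedly
#' with different drives, which reproduces the protocol of scanning input
#' conditions with identical connection patterns and noise.
#'
#' @inheritParams run_simulation
#' @return object of class `sim_prep`.
#' @export
prepare_simulation <- function(motif, seed = 1, dt = 0.2, cell_types = NULL,
                               ablate = NULL, noise = noise_spec(),
                               u0_rule = c("bv_plus_d", "bv")) {
  if (is.character(motif)) motif <- get_motif(motif)
  stopifnot(inherits(motif, "motif_spec"))
  u0_rule <- match.arg(u0_rule)
  seed <- as.integer(seed)
  set.seed(seed)
  cts <- cell_types %||% motif_cell_types(motif)
  params <- lapply(cts, sample_cell_parameters)
  conn <- assemble_network(motif, cts)
  if (!is.null(ablate)) conn <- ablate_edges(conn, ablate)
  a <- unlist(lapply(params, `[[`, "a"), use.names = FALSE)
  b <- unlist(lapply(params, `[[`, "b"), use.names = FALSE)
  cc <- unlist(lapply(params, `[[`, "c"), use.names = FALSE)
  d <- unlist(lapply(params, `[[`, "d"), use.names = FALSE)
  st <- init_state(b, d, u0_rule = u0_rule)
  n <- length(a)
  offsets <- rnorm(n, noise$offset_mean, noise$offset_sd)
  counts <- vapply(cts, `[[`, 0L, "count")
  type_idx <- rep(seq_along(counts) - 1L, counts)
  # tau of the outgoing synapse per type, indexed by type of the PREsynaptic
  # cell inside the core
  tau_pre <- vapply(cts, `[[`, 0, "tau_syn")
  structure(list(motif = motif, seed = seed, dt = dt,
                 cell_types = cts, conn = conn, csr = conn_to_csr(conn),
                 a = a, b = b, c = cc, d = d,
                 v0 = st$V, u0 = st$U, noise_offset = offsets,
                 noise = noise, type_idx = type_idx, tau_pre = tau_pre,
                 type_names = names(counts), counts = counts),
            class = "sim_prep")
}

#' Execute a prepared simulation under a given drive
#'
#' @param prep a `sim_prep` from [prepare_simulation()].
#' @inheritParams run_simulation
#' @export
execute_simulation <- function(prep, drive, t_total = 2300, t_burnin = 300,
                               lfp_clip = TRUE) {
  stopifnot(inherits(prep, "sim_prep"), inherits(drive, "drive_spec"))
  rate_by_type <- c(RS = drive$rate_rs, FS = drive$rate_fs,
                    LTS = drive$rate_lts)[prep$type_names]
  # motifs whose LTS population has no external input receive none even if a
  # nonzero rate_lts is configured
  if ("LTS" %in% prep$type_names &&
      !prep$motif$lts_input_regime %in% c("external_only", "both"))
    rate_by_type[["LTS"]] <- 0
  drive_rate <- rate_by_type[prep$type_idx + 1L]
  n_steps <- round(t_total / prep$dt)
  delay_steps <- round(1 / prep$dt)
  sched <- schedule_matrix(drive$schedule, prep$dt, prep$type_names)
  res <- .sim_core_cpp(prep$a, prep$b, prep$c, prep$d,
                       as.integer(prep$type_idx), prep$v0, prep$u0,
                       prep$csr$ptr, prep$csr$post, prep$csr$w,
                       prep$tau_pre, as.numeric(drive_rate),
                       prep$noise_offset, prep$noise$step_sd,
                       2, prep$dt, as.integer(n_steps),
                       as.integer(delay_steps), prep$seed, sched, lfp_clip)
  ids <- res$spike_id + 1L
  structure(list(spike_times = (res$spike_step + 1) * prep$dt,
                 spike_ids = ids,
                 spike_types = factor(prep$type_names[prep$type_idx[ids] + 1L],
                                      levels = prep$type_names),
                 lfp = res$lfp,
                 dt = prep$dt, fs = 1000 / prep$dt,
                 t_total = t_total, t_burnin = t_burnin,
                 motif_id = prep$motif$motif_id,
                 counts = prep$counts, type_names = prep$type_names,
                 drive = drive, seed = prep$seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> motif %s | %d neurons (%s) | %.0f ms @ dt=%.1f\n",
              x$motif_id, sum(x$counts),
              paste(sprintf("%s:%d", x$type_names, x$counts), collapse = " "),
              x$t_total, x$dt))
  cat(sprintf("  drive RS=%g FS=%g LTS=%g Hz | seed %d | %d spikes\n",
              x$drive$rate_rs, x$drive$rate_fs, x$drive$rate_lts,
              x$seed, length(x$spike_times)))
  invisible(x)
}

#' Repeat a simulation with independent seeds
#'
#' Derives `n_repeats` child seeds from one master seed and runs the motif
#' once per seed. Because the child seeds depend only on the master seed and
#' the repeat index, repeat `r` uses the same connection pattern and noise
#' across different drive conditions.
#'
#' @inheritParams run_simulation
#' @param n_repeats number of repeats (paper protocol: 10).
#' @param master_seed master seed from which per-repeat seeds are derived.
#' @param ... passed on to [run_simulation()].
#' @return list of `sim_result`.
#' @export
run_repeats <- function(motif, drive, n_repeats = 10, master_seed = 1, ...) {
  stopifnot(n_repeats >= 1)
  seeds <- derive_seeds(master_seed, n_repeats)
  lapply(seq_len(n_repeats), function(r)
    run_simulation(motif, drive, seed = seeds[r], ...))
}

#' Restrict a simulation to its analysis window
#'
#' Drops the burn-in (or an arbitrary window) from the LFP and spike data.
#'
#' @param sim a `sim_result`.
#' @param t_start,t_end window in ms; defaults to burn-in end and t_total.
#' @return a `sim_result` covering only the window (times re-zeroed).
#' @export
analysis_window <- function(sim, t_start = sim$t_burnin, t_end = sim$t_total) {
  keep <- sim$spike_times > t_start & sim$spike_times <= t_end
  i0 <- round(t_start / sim$dt)
  i1 <- round(t_end / sim$dt)
  out <- sim
  out$spike_times <- sim$spike_times[keep] - t_start
  out$spike_ids <- sim$spike_ids[keep]
  out$spike_types <- sim$spike_types[keep]
  out$lfp <- sim$lfp[(i0 + 1):i1]
  out$t_total <- t_end - t_start
  out$t_burnin <- 0
  out
}
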