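#' Background-drive specification
#'
#' Each neuron receives an independent Poisson spike train through an AMPA
#' kernel (unit weight, 2 ms decay, 1 ms delay). Rates are given per
#' population; the canonical input grid spans 0-5000 Hz. An optional
#' schedule applies piecewise-constant rate or current offsets to one
#' population (step-current protocols).
#'
#' @param rate_rs,rate_fs,rate_lts Poisson rates, Hz (>= 0). `rate_lts`
#'   defaults to 0 and is only used by motifs whose LTS regime includes
#'   external input.
#' @param schedule optional data.frame with columns `population` ("RS", "FS"
#'   or "LTS"), `t_start`, `t_end` (ms), and `rate_add` (Hz) and/or
#'   `current_add` (dimensionless); segments are half-open `[t_start, t_end)`
#'   and must not overlap within a population.
#' @return object of class `drive_spec`.
#' @export
drive_spec <- function(rate_rs = 0, rate_fs = 0, rate_lts = 0,
                       schedule = NULL) {
  if (rate_rs < 0 || rate_fs < 0 || rate_lts < 0)
    stop_config("drive rates must be >= 0")
  if (!is.null(schedule)) {
    need <- c("population", "t_start", "t_end")
    if (!all(need %in% names(schedule)))
      stop_config("schedule needs columns population, t_start, t_end")
    if (is.null(schedule$rate_add)) schedule$rate_add <- 0
    if (is.null(schedule$current_add)) schedule$current_add <- 0
    if (any(schedule$t_end <= schedule$t_start))
      stop_config("schedule segments must have t_end > t_start")
    for (popn in unique(schedule$population)) {
      seg <- schedule[schedule$population == popn, , drop = FALSE]
      seg <- seg[order(seg$t_start), , drop = FALSE]
      if (nrow(seg) > 1 &&
          any(seg$t_start[-1] < seg$t_end[-nrow(seg)]))
        stop_config("overlapping schedule segments for population %s", popn)
    }
  }
  structure(list(rate_rs = rate_rs, rate_fs = rate_fs, rate_lts = rate_lts,
                 schedule = schedule),
            class = "drive_spec")
}

#' Noise-current specification
#'
#' The noise current is `I_offset + I_t(t)`: a static per-neuron offset drawn
#' from `N(offset_mean, offset_sd^2)` plus an independent `N(0, step_sd^2)`
#' draw at every time step for every neuron.
#'
#' @param offset_mean,offset_sd static offset distribution (dimensionless
#'   current units).
#' @param step_sd SD of the per-step noise (default 1).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(offset_mean = 0, offset_sd = 1, step_sd = 1) {
  if (step_sd < 0 || offset_sd < 0) stop_config("noise SDs must be >= 0")
  structure(list(offset_mean = offset_mean, offset_sd = offset_sd,
                 step_sd = step_sd),
            class = "noise_spec")
}

#' Per-bin Poisson input spike counts
#'
#' Independent Poisson counts per time bin with mean `rate * dt / 1000`
#' (exact at any rate, unlike Bernoulli thinning). Uses R's RNG.
#'
#' @param rate spike rate, Hz.
#' @param duration ms.
#' @param dt bin width, ms.
#' @return integer vector of length `duration / dt`.
#' @export
generate_poisson_drive <- function(rate, duration, dt = 0.2) {
  if (rate < 0) stop_config("rate must be >= 0")
  n <- round(duration / dt)
  if (rate == 0) return(integer(n))
  rpois(n, rate * dt / 1000)
}

#' Synaptic current from input spike counts
#'
#' Convolves per-bin counts with the synaptic kernel
#' `H(t - delay) exp(-(t - delay)/tau)`, implemented with the same recursive
#' exponential update as the simulation core: the trace decays by
#' `exp(-dt/tau)` each step and counts arrive (at unit kernel height,
#' weighted by `w`) after the 1 ms delay.
#'
#' @param counts non-negative per-bin spike counts.
#' @param dt bin width, ms.
#' @param tau decay constant, ms (2 for the AMPA drive kernel).
#' @param delay synaptic delay, ms.
#' @param w synaptic weight.
#' @return numeric current trace, same length as `counts`.
#' @export
drive_current <- function(counts, dt = 0.2, tau = 2, delay = 1, w = 1) {
  if (any(counts < 0)) stop_config("counts must be non-negative")
  n <- length(counts)
  delay_steps <- round(delay / dt)
  dec <- exp(-dt / tau)
  out <- numeric(n)
  g <- 0
  for (s in seq_len(n)) {
    g <- g * dec
    if (s > delay_steps) g <- g + w * counts[s - delay_steps]
    out[s] <- g
  }
  out
}

#' Noise currents for a population
#'
#' Reference implementation of the noise model (the compiled core draws the
#' same quantities internally): per-neuron static offsets plus a per-step,
#' per-neuron Gaussian.
#'
#' @param n_neurons,n_steps dimensions.
#' @param spec a [noise_spec()].
#' @return list with `offset` (length `n_neurons`) and `step` (an
#'   `n_steps` x `n_neurons` matrix).
#' @export
noise_current <- function(n_neurons, n_steps, spec = noise_spec()) {
  if (n_neurons < 0) stop_config("n_neurons must be >= 0")
  list(offset = rnorm(n_neurons, spec$offset_mean, spec$offset_sd),
       step = matrix(rnorm(n_neurons * n_steps, 0, spec$step_sd),
                     nrow = n_steps))
}

# schedule data.frame -> matrix for the compiled core
# columns: population index (0-based), start step, end step, rate_add, current_add
schedule_matrix <- function(schedule, dt, type_names) {
  if (is.null(schedule) || nrow(schedule) == 0)
    return(matrix(numeric(0), ncol = 5))
  pop <- match(schedule$population, type_names) - 1L
  if (any(is.na(pop)))
    stop_config("schedule population not present in this motif")
  cbind(pop, round(schedule$t_start / dt), round(schedule$t_end / dt),
        schedule$rate_add %||% 0, schedule$current_add %||% 0)
}
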