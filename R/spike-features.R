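#' Population firing rate
#'
#' Average number of spikes per second per cell; silent cells count in the
#' denominator.
#'
#' @param n_spikes total number of spikes of the population in the window.
#' @param n_cells population size.
#' @param duration_ms analysis window length, ms.
#' @return rate in Hz (0 for an empty population).
#' @export
firing_rate <- function(n_spikes, n_cells, duration_ms) {
  if (duration_ms <= 0) stop("duration must be positive")
  if (n_cells == 0) return(0)
  n_spikes / n_cells / (duration_ms / 1000)
}

#' Burst fraction of a population
#'
#' Per neuron, consecutive spikes with inter-spike intervals of at most
#' `window` ms are chained into events; events with two or more spikes are
#' bursts, the rest single spikes. The neuron's burst fraction is
#' bursts / (bursts + singles); neurons with fewer than 2 spikes are
#' excluded. The population value is the mean over eligible neurons.
#'
#' @param spike_trains list of per-neuron spike time vectors (ms, sorted).
#' @param window chaining threshold, ms.
#' @return fraction in `[0, 1]`, or `NA` when no neuron is eligible.
#' @export
burst_fraction <- function(spike_trains, window = 10) {
  fr <- vapply(spike_trains, function(ts) {
    if (length(ts) < 2) return(NA_real_)
    chains <- cumsum(c(1, diff(ts) > window))
    sizes <- tabulate(chains)
    bursts <- sum(sizes >= 2)
    singles <- sum(sizes == 1)
    bursts / (bursts + singles)
  }, 0)
  if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
}

#' Instantaneous phase of a band-limited LFP
#'
#' Zero-phase 2nd-order Butterworth band-pass with a `width`-Hz passband
#' centered on `center_freq`, mean correction, Hilbert transform, angle.
#' Phase 0 corresponds to the positive peak of the band-limited signal,
#' +-pi to the trough.
#'
#' @param x LFP trace.
#' @param fs sampling rate, Hz.
#' @param center_freq passband center, Hz.
#' @param width passband width, Hz.
#' @return phase trace in `(-pi, pi]`, same length as `x`.
#' @export
instantaneous_phase <- function(x, fs, center_freq, width = 10) {
  if (center_freq <= 0) stop("center frequency must be positive")
  if (center_freq >= fs / 2) stop("center frequency beyond Nyquist")
  lo <- max(center_freq - width / 2, 0.5)
  hi <- min(center_freq + width / 2, fs / 2 * 0.99)
  y <- butter_bandpass(x, fs, lo, hi, order = 2)
  y <- y - mean(y)
  Arg(hilbert_analytic(y))
}

# phases at spike times by linear interpolation of the unwrapped phase trace
# (sample k sits at time k*dt after the window start)
phase_at_times <- function(phase, fs, times_ms) {
  un <- unwrap_phase(phase)
  idx <- times_ms / 1000 * fs
  idx <- pmin(pmax(idx, 1), length(phase))
  wrap_pi(stats::approx(seq_along(un), un, xout = idx, rule = 2)$y)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  adj <- cumsum(c(0, -2 * pi * round(dp / (2 * pi))))
  p + adj
}

#' Circular mean phase
#'
#' Argument of the resultant vector `sum(exp(i theta))`.
#'
#' @param phases spike phases, radians.
#' @return mean phase in `(-pi, pi]`, or `NA` for no spikes.
#' @export
mean_phase <- function(phases) {
  if (!length(phases)) return(NA_real_)
  Arg(sum(exp(1i * phases)))
}

#' Pairwise phase consistency
#'
#' The unbiased pairwise form `2 / (N (N - 1)) * sum_{i<j} cos(theta_i -
#' theta_j)`, computed through the O(N) identity
#' `(|sum exp(i theta)|^2 - N) / (N (N - 1))`. Zero in expectation for
#' uniform phases, 1 for perfectly aligned spikes.
#'
#' @param phases spike phases, radians.
#' @return value in `[-1, 1]`, or `NA` for fewer than 2 spikes.
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  (Mod(sum(exp(1i * phases)))^2 - n) / (n * (n - 1))
}

#' Spiking summary of a simulation
#'
#' Per cell type: firing rate, burst fraction (10 ms rule), spike phases
#' relative to the LFP filtered around its full-spectrum peak frequency
#' (10 Hz wide band), the circular mean phase and the pairwise phase
#' consistency. For PPC, spikes are subsampled uniformly to at most
#' `max_spikes` to bound cost. The phase trace is computed on the
#' post-burn-in LFP decimated to ~1 kHz and interpolated at spike times.
#'
#' @param sim a `sim_result`.
#' @param summary optional precomputed [spectral_summary()] of the same
#'   simulation (avoids recomputation).
#' @param max_spikes PPC spike cap per type.
#' @param phase_fs target sampling rate for phase extraction, Hz.
#' @return object of class `spike_summary`: lists `rate`, `burst`, `ppc`,
#'   `phase` indexed by type name, plus `peak_freq` used for the phase.
#' @export
spike_summary <- function(sim, summary = NULL, max_spikes = 5000,
                          phase_fs = 1000) {
  stopifnot(inherits(sim, "sim_result"))
  win <- analysis_window(sim)
  duration <- win$t_total
  if (is.null(summary)) summary <- spectral_summary(sim)
  factor <- max(1L, floor(sim$fs / phase_fs))
  fsd <- sim$fs / factor
  xd <- decimate_trace(win$lfp, factor)
  phase_trace <- instantaneous_phase(xd, fsd, summary$peak_freq_full)
  types <- sim$type_names
  out <- list(rate = list(), burst = list(), ppc = list(), phase = list())
  for (ty in types) {
    sel <- win$spike_types == ty
    ts <- win$spike_times[sel]
    ids <- win$spike_ids[sel]
    out$rate[[ty]] <- firing_rate(length(ts), sim$counts[[ty]], duration)
    out$burst[[ty]] <- burst_fraction(split(ts, ids))
    if (length(ts) >= 2) {
      keep <- if (length(ts) > max_spikes) {
        # deterministic given the simulation seed, independent of caller RNG
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        set.seed(sim$seed)
        k <- sort(sample.int(length(ts), max_spikes))
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        k
      } else seq_along(ts)
      ph <- phase_at_times(phase_trace, fsd, ts[keep])
      out$ppc[[ty]] <- ppc(ph)
      out$phase[[ty]] <- mean_phase(ph)
    } else {
      out$ppc[[ty]] <- NA_real_
      out$phase[[ty]] <- if (length(ts) == 1)
        phase_at_times(phase_trace, fsd, ts) else NA_real_
    }
  }
  structure(c(out, list(peak_freq = summary$peak_freq_full,
                        type_names = types)),
            class = "spike_summary")
}
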