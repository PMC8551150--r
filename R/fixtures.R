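#' Amplitude-modulated synthetic LFP
#'
#' A test signal with known phase-amplitude coupling: a low-frequency
#' carrier plus a high-frequency tone whose amplitude is modulated by the
#' carrier's phase,
#' `sin(2 pi f_low t) + (1 - depth + depth (1 + sin(2 pi f_low t)) / 2) *
#' sin(2 pi f_high t) + noise`.
#' Depth 0 gives a constant high-band envelope (no coupling); depth 1 gives
#' full modulation.
#'
#' @param f_low,f_high component frequencies, Hz (`f_low < f_high < fs/2`).
#' @param depth modulation depth in `[0, 1]`.
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd SD of additive white Gaussian noise.
#' @return numeric trace of length `duration * fs`.
#' @export
make_am_signal <- function(f_low = 8, f_high = 45, depth = 1, duration = 2,
                           fs = 500, noise_sd = 0) {
  stopifnot(f_low < f_high, f_high < fs / 2, depth >= 0, depth <= 1)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * f_low * t)
  env <- 1 - depth + depth * (1 + carrier) / 2
  x <- carrier + env * sin(2 * pi * f_high * t)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  x
}

#' Phase-locked synthetic spike raster
#'
#' Spike trains whose phases relative to a sinusoidal reference follow a von
#' Mises distribution centered on phase 0 (the positive peak of the
#' reference `cos(2 pi f t)`). With concentration `kappa`, the expected
#' pairwise phase consistency has the closed form `(I1(kappa)/I0(kappa))^2`;
#' `kappa = 0` gives uniform phases.
#'
#' @param n_cells number of spike trains.
#' @param rate expected spike rate per cell, Hz.
#' @param f reference frequency, Hz.
#' @param kappa von Mises concentration (>= 0).
#' @param duration seconds.
#' @param fs sampling rate of the returned reference trace, Hz.
#' @return list with `spike_trains` (per-cell spike times, ms), `phases`
#'   (the true spike phases), `reference` (trace), `fs`, `f`.
#' @export
make_locked_raster <- function(n_cells = 10, rate = 20, f = 10, kappa = 2,
                               duration = 2, fs = 1000) {
  stopifnot(kappa >= 0, f < fs / 2)
  n_cycles <- floor(duration * f)
  trains <- vector("list", n_cells)
  phases <- list()
  for (i in seq_len(n_cells)) {
    n_sp <- rpois(1, rate * duration)
    th <- rvonmises(n_sp, 0, kappa)
    cyc <- sample.int(max(n_cycles - 2, 1), n_sp, replace = TRUE)
    tt <- (cyc + (th / (2 * pi)) %% 1) / f * 1000
    ord <- order(tt)
    trains[[i]] <- tt[ord]
    phases[[i]] <- th[ord]
  }
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  list(spike_trains = trains, phases = unlist(phases),
       reference = cos(2 * pi * f * t), fs = fs, f = f)
}
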