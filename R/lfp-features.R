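#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-halfbandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix commuting with the concentration problem. Tapers are unit-norm,
#' with the sign convention that symmetric tapers have positive mean and the
#' others a positive first lobe. Results are cached per `(n, nw, k)`.
#'
#' @param n taper length (samples).
#' @param nw time-halfbandwidth product.
#' @param k number of tapers (default `2 nw - 1`).
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .oscmotifs_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (i[-1] * (n - i[-1])) / 2
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), seq_len(n))] <- diag_main
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tj <- tap[, j]
    s <- if (abs(sum(tj)) > 1e-8) sign(sum(tj)) else sign(tj[which.max(abs(tj))[1]])
    tap[, j] <- tj * s / sqrt(sum(tj^2))
  }
  .oscmotifs_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density
#'
#' Averages the periodograms of the DPSS-tapered signal (time-halfbandwidth
#' `nw`, `2 nw - 1` tapers by default) over a single full-length window. The
#' mean is removed first. One-sided PSD in input-units^2 / Hz, so that the
#' integral over frequency matches the signal variance.
#'
#' @param x real trace.
#' @param fs sampling rate, Hz.
#' @inheritParams dpss_tapers
#' @return list with `freq` (Hz) and `psd`.
#' @export
multitaper_psd <- function(x, fs, nw = 3, k = 2 * nw - 1) {
  n <- length(x)
  if (n < fs) stop("trace too short for spectral analysis")
  x <- x - mean(x)
  tap <- dpss_tapers(n, nw, k)
  n_freq <- floor(n / 2) + 1
  acc <- numeric(n_freq)
  for (j in seq_len(k)) {
    ft <- fft(tap[, j] * x)[seq_len(n_freq)]
    acc <- acc + (Mod(ft)^2) / fs
  }
  psd <- acc / k
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_freq] <- 1
  list(freq = (seq_len(n_freq) - 1) * fs / n, psd = psd * dbl)
}

#' Peak frequency and power within a band
#'
#' Argmax of the PSD restricted to `[lo, hi]` (inclusive); ties are broken
#' toward the lowest frequency.
#'
#' @param freq,psd from [multitaper_psd()].
#' @param band numeric `c(lo, hi)`, Hz.
#' @return list with `freq` and `power` at the peak.
#' @export
band_peak <- function(freq, psd, band) {
  sel <- which(freq >= band[1] & freq <= band[2])
  if (!length(sel)) stop("empty frequency band")
  i <- sel[which.max(psd[sel])]
  list(freq = freq[i], power = psd[i])
}

#' Phase-amplitude-coupling eligibility
#'
#' PAC is only meaningful when both band peaks carry real power (at least
#' 1 dB/Hz), the high-band peak lies above 40 Hz, and the high-band peak is
#' not simply the first harmonic of the low-band peak (within a 10% relative
#' tolerance).
#'
#' @param power_low_db,power_high_db band peak powers, dB/Hz
#'   (`10 log10(PSD)`).
#' @param peak_low,peak_high band peak frequencies, Hz.
#' @param power_thresh_db minimum peak power, dB/Hz.
#' @param harmonic_tol relative tolerance for the harmonic exclusion.
#' @return logical.
#' @export
pac_eligible <- function(power_low_db, power_high_db, peak_low, peak_high,
                         power_thresh_db = 1, harmonic_tol = 0.1) {
  isTRUE(power_low_db >= power_thresh_db &&
         power_high_db >= power_thresh_db &&
         peak_high > 40 &&
         abs(peak_high - 2 * peak_low) > harmonic_tol * 2 * peak_low)
}

#' Weighted phase-locking factor (phase-amplitude coupling)
#'
#' Measures how strongly the high-band amplitude envelope locks to the
#' low-band phase: (1) zero-phase 2nd-order Butterworth band-pass in
#' `low_band`, mean-subtract, Hilbert transform, normalize to unit norm; (2)
#' zero-phase 4th-order Butterworth band-pass in `high_band`, mean-subtract,
#' Hilbert transform, take the magnitude and divide by the norm of the
#' analytic signal; (3) absolute inner product of (1) and (2). Bounded in
#' `[0, 1]` by Cauchy-Schwarz.
#'
#' @param x LFP trace.
#' @param fs sampling rate, Hz.
#' @param low_band,high_band band edges, Hz.
#' @return value in `[0, 1]`, or `NA` for a constant trace.
#' @export
wplf_pac <- function(x, fs, low_band = c(2, 30), high_band = c(30, 150)) {
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  if (sd(x) == 0) return(NA_real_)
  lo <- butter_bandpass(x, fs, low_band[1], low_band[2], order = 2)
  lo <- lo - mean(lo)
  ph <- hilbert_analytic(lo)
  nrm <- sqrt(sum(Mod(ph)^2))
  if (nrm == 0) return(NA_real_)
  ph <- ph / nrm
  hi <- butter_bandpass(x, fs, high_band[1], high_band[2], order = 4)
  hi <- hi - mean(hi)
  ha <- hilbert_analytic(hi)
  nrm2 <- sqrt(sum(Mod(ha)^2))
  if (nrm2 == 0) return(NA_real_)
  amp <- Mod(ha) / nrm2
  Mod(sum(Conj(ph) * amp))
}

#' Spectral summary of an LFP trace
#'
#' The full LFP characterization used by the feature pipeline: the
#' post-burn-in trace is low-pass decimated to ~500 Hz (all analysis bands
#' sit below 150 Hz), the multitaper PSD (NW = 3, 5 tapers) is computed, and
#' peak frequency / power are extracted for the full analysis range
#' (2-150 Hz), the low band (2-30 Hz) and the high band (30-150 Hz). When
#' the PAC eligibility rules hold, the weighted phase-locking factor between
#' the two bands is attached.
#'
#' @param sim a `sim_result`, or a numeric trace (then `fs` is required).
#' @param fs sampling rate when `sim` is a bare trace.
#' @param low_band,high_band analysis bands, Hz.
#' @param target_fs decimation target, Hz.
#' @return object of class `spectral_summary`: peak frequencies, peak powers
#'   (raw and dB/Hz), `pac`, `pac_eligible`.
#' @export
spectral_summary <- function(sim, fs = NULL, low_band = c(2, 30),
                             high_band = c(30, 150), target_fs = 500) {
  if (inherits(sim, "sim_result")) {
    win <- analysis_window(sim)
    x <- win$lfp
    fs <- sim$fs
  } else {
    x <- sim
    if (is.null(fs)) stop("fs is required for a bare trace")
  }
  factor <- max(1L, floor(fs / target_fs))
  xd <- decimate_trace(x, factor)
  fsd <- fs / factor
  sp <- multitaper_psd(xd, fsd)
  full <- band_peak(sp$freq, sp$psd, c(low_band[1], high_band[2]))
  lo <- band_peak(sp$freq, sp$psd, low_band)
  hi <- band_peak(sp$freq, sp$psd, high_band)
  to_db <- function(p) 10 * log10(max(p, 1e-20))
  out <- list(peak_freq_full = full$freq, power_full = full$power,
              peak_freq_low = lo$freq, power_low = lo$power,
              peak_freq_high = hi$freq, power_high = hi$power,
              power_full_db = to_db(full$power),
              power_low_db = to_db(lo$power),
              power_high_db = to_db(hi$power),
              freq = sp$freq, psd = sp$psd, fs_psd = fsd)
  out$pac_eligible <- pac_eligible(out$power_low_db, out$power_high_db,
                                   out$peak_freq_low, out$peak_freq_high)
  out$pac <- if (out$pac_eligible)
    wplf_pac(xd, fsd, low_band, high_band) else NA_real_
  structure(out, class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> full %.1f Hz (%.1f dB/Hz) | low %.1f Hz (%.1f) | high %.1f Hz (%.1f)\n",
              x$peak_freq_full, x$power_full_db, x$peak_freq_low,
              x$power_low_db, x$peak_freq_high, x$power_high_db))
  cat(sprintf("  PAC %s (eligible: %s)\n",
              ifelse(is.na(x$pac), "-", sprintf("%.3f", x$pac)),
              x$pac_eligible))
  invisible(x)
}
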