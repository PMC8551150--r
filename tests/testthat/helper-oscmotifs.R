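# Shared helpers for the test suite. Heavy shared computations are memoized
# here so that several test files can reuse one grid run.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# a three-population motif with no internal connections, used for isolated
# neuron (f-I) properties; external regime so the LTS drive is delivered
isolated_motif <- function() {
  motif_spec("isolated", character(0), "external_only")
}

# brute-force convolution with the synaptic kernel H(t - delay) exp(-t/tau),
# sampled at k*dt; independent oracle for the recursive trace implementation
conv_kernel_oracle <- function(counts, dt, tau, delay, w = 1) {
  n <- length(counts)
  kern <- numeric(n)
  delay_steps <- round(delay / dt)
  idx <- seq_len(n) - 1
  kern[idx >= delay_steps] <-
    exp(-(idx[idx >= delay_steps] - delay_steps) * dt / tau)
  out <- numeric(n)
  for (s in seq_len(n)) {
    k <- seq_len(s)
    out[s] <- sum(w * counts[k] * kern[s - k + 1])
  }
  out
}

# O(N^2) pairwise phase consistency, the definitional oracle
ppc_oracle <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + cos(phases[i] - phases[j])
  2 * tot / (n * (n - 1))
}

# burst-fraction oracle: explicit chain enumeration, written independently
# of the package implementation
burst_oracle <- function(ts, window = 10) {
  if (length(ts) < 2) return(NA_real_)
  ts <- sort(ts)
  bursts <- 0; singles <- 0
  size <- 1
  for (i in seq_along(ts)[-1]) {
    if (ts[i] - ts[i - 1] <= window) size <- size + 1
    else {
      if (size >= 2) bursts <- bursts + 1 else singles <- singles + 1
      size <- 1
    }
  }
  if (size >= 2) bursts <- bursts + 1 else singles <- singles + 1
  bursts / (bursts + singles)
}

# Calinski-Harabasz from the definition, term by term
ch_oracle <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); ks <- unique(labels); k <- length(ks)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in ks) {
    xi <- x[labels == g, , drop = FALSE]
    m <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((m - grand)^2)
    for (r in seq_len(nrow(xi))) ssw <- ssw + sum((xi[r, ] - m)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}
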