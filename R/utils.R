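`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("oscmotifs_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Analytic signal via the frequency domain
#'
#' Returns the analytic signal `x + i H(x)` of a real vector, computed by
#' zeroing the negative frequencies of the DFT. Used for instantaneous phase
#' and amplitude-envelope extraction.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @return wrapped angles.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# zero-phase Butterworth band-pass; signal::filtfilt squares the magnitude
# response, so `order` is the order of the underlying one-pass design, as is
# conventional when reporting "second-order zero-phase" filters.
butter_bandpass <- function(x, fs, lo, hi, order) {
  ny <- fs / 2
  if (lo <= 0 || hi >= ny)
    stop("band edges must lie strictly inside (0, fs/2)")
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

# low-pass + subsample, used before spectral estimation (all analysis bands
# are <= 150 Hz, far below the 5 kHz simulation rate)
decimate_trace <- function(x, factor) {
  if (factor <= 1) return(x)
  bf <- signal::butter(4, 0.8 / factor, type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1, length(y), by = factor)]
}

# independent 31-bit child seeds derived from one master seed
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mean mu,
# concentration kappa >= 0
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_pi(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}
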