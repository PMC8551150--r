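#' Cell-type specification
#'
#' Describes one neuron population: its Izhikevich parameter distributions,
#' synaptic decay time constant and outgoing weight distribution. The three
#' built-in types are regular-spiking (RS, pyramidal-like), fast-spiking
#' (FS, PV-like) and low-threshold-spiking (LTS, SOM-like).
#'
#' Parameter distribution descriptors are lists with a `kind` field:
#' `list(kind = "constant", value =)`, `list(kind = "uniform", lo =, hi =)` or
#' `list(kind = "scaled_beta", lo =, hi =, shape1 =, shape2 =)` (a Beta draw
#' rescaled to `[lo, hi]`; with shapes (0.5, 1) this reproduces the classic
#' squared-uniform heterogeneity `lo + (hi - lo) * r^2`).
#'
#' @param name one of "RS", "FS", "LTS".
#' @param count number of neurons (>= 0).
#' @param a_dist,b_dist,c_dist,d_dist distribution descriptors for the
#'   Izhikevich parameters.
#' @param tau_syn decay time constant of outgoing synaptic currents, ms.
#' @param weight_mean,weight_sd normal distribution of outgoing synaptic
#'   weights (dimensionless current units).
#' @return an object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, count, a_dist, b_dist, c_dist, d_dist,
                           tau_syn, weight_mean, weight_sd) {
  if (!name %in% c("RS", "FS", "LTS"))
    stop_config("unknown cell type '%s' (expected RS, FS or LTS)", name)
  if (count < 0) stop_config("count must be >= 0")
  if (tau_syn <= 0) stop_config("tau_syn must be positive")
  if (name == "RS" && weight_mean <= 0)
    stop_config("RS (excitatory) weights must have positive mean")
  if (name != "RS" && weight_mean >= 0)
    stop_config("%s (inhibitory) weights must have negative mean", name)
  for (d in list(a_dist, b_dist, c_dist, d_dist))
    check_dist(d)
  structure(list(name = name, count = as.integer(count),
                 a_dist = a_dist, b_dist = b_dist,
                 c_dist = c_dist, d_dist = d_dist,
                 tau_syn = tau_syn,
                 weight_mean = weight_mean, weight_sd = weight_sd),
            class = "cell_type_spec")
}

check_dist <- function(d) {
  if (!is.list(d) || is.null(d$kind))
    stop_config("parameter distribution must be a list with a 'kind' field")
  switch(d$kind,
    constant = if (is.null(d$value)) stop_config("constant dist needs 'value'"),
    uniform = if (is.null(d$lo) || is.null(d$hi) || d$lo > d$hi)
      stop_config("uniform dist needs lo <= hi"),
    scaled_beta = if (is.null(d$lo) || is.null(d$hi) || is.null(d$shape1) ||
                      is.null(d$shape2))
      stop_config("scaled_beta dist needs lo, hi, shape1, shape2"),
    stop_config("unknown distribution kind '%s'", d$kind))
  invisible(d)
}

dist_constant <- function(value) list(kind = "constant", value = value)
dist_uniform <- function(lo, hi) list(kind = "uniform", lo = lo, hi = hi)
dist_scaled_beta <- function(lo, hi, shape1, shape2)
  list(kind = "scaled_beta", lo = lo, hi = hi, shape1 = shape1, shape2 = shape2)

sample_dist <- function(d, n) {
  if (n == 0L) return(numeric(0))
  switch(d$kind,
    constant = rep(d$value, n),
    uniform = runif(n, d$lo, d$hi),
    scaled_beta = d$lo + (d$hi - d$lo) * rbeta(n, d$shape1, d$shape2))
}

#' Default cell-type specifications
#'
#' The standard population makeup: RS cells with constant `a = 0.020`,
#' `b = 0.20`, heterogeneous `c` in `[-65, -50]` (Beta(0.5, 1), i.e.
#' `-65 + 15 r^2`) and `d` in `[2, 8]` (Beta(1, 0.5), i.e. `8 - 6 r^2`);
#' FS cells with `a ~ U(0.10, 0.18)`, `b ~ U(0.15, 0.20)`, `c = -65`,
#' `d = 2`; LTS cells with `a ~ U(0.020, 0.025)`, `b ~ U(0.20, 0.25)`,
#' `c = -65`, `d = 2`. Synaptic decay constants are 2 / 3 / 6 ms and weight
#' distributions 1 +- 0.5 / -2 +- 1 / -2 +- 1 for RS / FS / LTS.
#'
#' Full three-cell circuits use 800 RS + 100 FS + 100 LTS neurons; two-cell
#' circuits use 800 RS plus 200 of a single interneuron type.
#'
#' @param n_rs,n_fs,n_lts population sizes.
#' @return named list of [cell_type_spec()] objects.
#' @export
default_cell_types <- function(n_rs = 800, n_fs = 100, n_lts = 100) {
  list(
    RS = cell_type_spec("RS", n_rs,
      a_dist = dist_constant(0.020), b_dist = dist_constant(0.20),
      c_dist = dist_scaled_beta(-65, -50, 0.5, 1),
      d_dist = dist_scaled_beta(2, 8, 1, 0.5),
      tau_syn = 2, weight_mean = 1, weight_sd = 0.5),
    FS = cell_type_spec("FS", n_fs,
      a_dist = dist_uniform(0.10, 0.18), b_dist = dist_uniform(0.15, 0.20),
      c_dist = dist_constant(-65), d_dist = dist_constant(2),
      tau_syn = 3, weight_mean = -2, weight_sd = 1),
    LTS = cell_type_spec("LTS", n_lts,
      a_dist = dist_uniform(0.020, 0.025), b_dist = dist_uniform(0.20, 0.25),
      c_dist = dist_constant(-65), d_dist = dist_constant(2),
      tau_syn = 6, weight_mean = -2, weight_sd = 1))
}

#' Sample per-neuron Izhikevich parameters
#'
#' Draws `a`, `b`, `c`, `d` for every neuron of a population from the
#' distributions in its [cell_type_spec()]. Uses R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param spec a [cell_type_spec()].
#' @return list with numeric vectors `a`, `b`, `c`, `d` of length `spec$count`.
#' @export
sample_cell_parameters <- function(spec) {
  stopifnot(inherits(spec, "cell_type_spec"))
  n <- spec$count
  list(a = sample_dist(spec$a_dist, n), b = sample_dist(spec$b_dist, n),
       c = sample_dist(spec$c_dist, n), d = sample_dist(spec$d_dist, n))
}

#' Initialize neuron state
#'
#' Membrane potentials start uniformly in `[-80, -70]` mV; the recovery
#' variable starts at `U0 = b V0 + d` (the model's stated rule; set
#' `u0_rule = "bv"` for the more common `U0 = b V0` convention).
#'
#' @param b,d per-neuron parameter vectors (same length).
#' @param v0 optional membrane-potential override (recycled); when `NULL`,
#'   drawn from `U(-80, -70)`.
#' @param u0_rule `"bv_plus_d"` (default) or `"bv"`.
#' @return list with vectors `V`, `U` and logical `spiked`.
#' @export
init_state <- function(b, d, v0 = NULL, u0_rule = c("bv_plus_d", "bv")) {
  if (length(b) != length(d)) stop("b and d must have the same length")
  u0_rule <- match.arg(u0_rule)
  n <- length(b)
  V <- if (is.null(v0)) runif(n, -80, -70) else rep_len(v0, n)
  U <- if (u0_rule == "bv_plus_d") b * V + d else b * V
  list(V = V, U = U, spiked = rep(FALSE, n))
}

#' One forward-Euler step of the Izhikevich model
#'
#' Advances `dV/dt = 0.04 V^2 + 5 V + 140 - U + I` and `dU/dt = a (b V - U)`
#' by one step of size `dt` (both derivatives evaluated at the pre-step
#' state), then applies the reset: any neuron reaching `V >= 30` mV is marked
#' as spiking, its `V` set to `c` and `U` incremented by `d`. This R
#' implementation is the reference for the compiled simulation loop.
#'
#' @param state list with `V` and `U` vectors (as from [init_state()]).
#' @param params list with per-neuron `a`, `b`, `c`, `d`.
#' @param I per-neuron input current (dimensionless units).
#' @param dt step size, ms.
#' @return updated state; `spiked` flags the neurons that crossed threshold.
#' @export
izhikevich_step <- function(state, params, I, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(I)))
    stop("non-finite input current at neuron(s) ",
         paste(which(!is.finite(I)), collapse = ", "))
  V <- state$V; U <- state$U
  Vn <- V + dt * (0.04 * V^2 + 5 * V + 140 - U + I)
  Un <- U + dt * (params$a * (params$b * V - U))
  sp <- Vn >= 30
  Vn[sp] <- params$c[sp]
  Un[sp] <- Un[sp] + params$d[sp]
  list(V = Vn, U = Un, spiked = sp)
}
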