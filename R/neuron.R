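# LIF output-neuron dynamics on a discrete time grid: spike-response kernel,
# membrane potential as a weighted kernel sum, and first-threshold-crossing
# firing. A single postsynaptic spike is modelled; simulation semantics stop
# at the first crossing.

#' Configure the LIF output neuron and timing constants
#'
#' @param tau Membrane time constant in ms; the kernel peaks at t = tau.
#' @param theta Firing threshold (dimensionless potential). Fixed at 1 by
#'   default; weight initialization scales the first sample's potential to
#'   reach exactly theta at its desired firing time.
#' @param T Presynaptic window in ms (latest input spike).
#' @param deltaT Extension of the observation window in ms, so late
#'   postsynaptic spikes in (T, T + deltaT\] are still captured.
#' @param dt Simulation step in ms. The default 0.01 ms is far below
#'   tau = 0.63 ms and keeps the 0-4 ms grid at 401 points.
#' @param t_b Class boundary in ms: firing before t_b decodes as class-1.
#' @param t_d1,t_d2 Desired firing times (ms) for class-1 and class-2. The
#'   class-1 default sits early on the rising flank of the potential
#'   (t_d1 = 0.5 ms, of the order of tau): inputs arriving after the desired
#'   crossing then keep accumulating potential, so unseen samples with
#'   slightly weaker drive still cross the threshold before the boundary.
#'   Placing t_d1 late (near the potential peak) makes the crossing
#'   tangential and generalizes measurably worse. t_d2 defaults to T.
#' @return An object of class `neuron_config` including the simulation `grid`.
#' @export
neuron_config <- function(tau = 0.63, theta = 1, T = 3, deltaT = 1, dt = 0.01,
                          t_b = 2, t_d1 = 0.5, t_d2 = 3) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(theta, "theta", positive = TRUE)
  check_scalar(T, "T", positive = TRUE)
  check_scalar(deltaT, "deltaT")
  check_scalar(dt, "dt", positive = TRUE)
  if (deltaT < 0) stop("deltaT must be >= 0")
  if (!(0 < t_d1 && t_d1 < t_b && t_b < t_d2 && t_d2 <= T + deltaT)) {
    stop("need 0 < t_d1 < t_b < t_d2 <= T + deltaT")
  }
  grid <- seq(0, T + deltaT, by = dt)
  structure(
    list(tau = tau, theta = theta, T = T, deltaT = deltaT, dt = dt,
         t_b = t_b, t_d1 = t_d1, t_d2 = t_d2,
         grid = grid, n_grid = length(grid)),
    class = "neuron_config"
  )
}

#' LIF spike-response kernel
#'
#' phi(t) = (t / tau) exp(1 - t / tau) for t > 0 and 0 for t <= 0 (causal:
#' an input spike contributes nothing before it occurs). The kernel rises to
#' its maximum of 1 at t = tau and decays exponentially after.
#'
#' @param t Time(s) since the presynaptic spike, ms.
#' @param tau Time constant, ms.
#' @return Kernel value(s).
#' @export
spike_response <- function(t, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau) * exp(1 - t[pos] / tau)
  if (is.matrix(t)) dim(out) <- dim(t)
  out
}

#' Container for time-varying synaptic efficacy functions
#'
#' One signed efficacy function omega_j(t) per presynaptic neuron, stored as
#' its values on the simulation grid (P x n_grid matrix, initially zero).
#' Signs are unconstrained: a synapse may act excitatory at some times and
#' inhibitory at others as Gaussian update bumps accumulate.
#'
#' @param P Number of presynaptic neurons.
#' @param cfg A [neuron_config()] providing the grid.
#' @return An object of class `efficacy_fns` with fields `omega` and `grid`.
#' @export
efficacy_functions <- function(P, cfg) {
  stopifnot(inherits(cfg, "neuron_config"))
  structure(
    list(omega = matrix(0, nrow = P, ncol = cfg$n_grid), grid = cfg$grid),
    class = "efficacy_fns"
  )
}

check_grid <- function(eff, cfg) {
  if (!inherits(eff, "efficacy_fns")) stop("eff must be an efficacy_fns object")
  if (length(eff$grid) != cfg$n_grid || !isTRUE(all.equal(eff$grid, cfg$grid))) {
    stop("efficacy functions and neuron config are on different time grids")
  }
  invisible(TRUE)
}

#' Membrane potential of the output neuron
#'
#' v(t) = sum_j omega_j(st_j) phi(t - st_j): each presynaptic spike
#' contributes a kernel weighted by its synapse's efficacy sampled at the
#' (grid-snapped) spike time. The sum is linear, so potentials superpose.
#'
#' @param pattern A [encode_sample()] spike pattern.
#' @param eff An [efficacy_functions()] object on the same grid.
#' @param cfg A [neuron_config()].
#' @return Numeric potential trace over the grid.
#' @export
membrane_potential <- function(pattern, eff, cfg) {
  stopifnot(inherits(pattern, "spike_pattern"), inherits(cfg, "neuron_config"))
  check_grid(eff, cfg)
  if (pattern$dt != cfg$dt) stop("spike pattern and neuron config use different dt")
  w <- eff$omega[cbind(seq_along(pattern$times), pattern$grid_index)]
  K <- spike_response(outer(cfg$grid, pattern$times, "-"), cfg$tau)
  as.vector(K %*% w)
}

#' First threshold crossing of a potential trace
#'
#' Returns the earliest grid time with v >= theta; the simulation considers a
#' single postsynaptic spike, so nothing after the first crossing matters.
#' If the threshold is never reached within \[0, T + deltaT\], the outcome is
#' `fired = FALSE` with the firing time set to the window end T + deltaT
#' (which decodes as class-2, since it is past the class boundary).
#'
#' @param trace Potential values on the grid of `cfg`.
#' @param cfg A [neuron_config()].
#' @return `list(fired, t_fa, index)`; `index` is the 1-based grid index.
#' @export
find_fire_time <- function(trace, cfg) {
  stopifnot(inherits(cfg, "neuron_config"))
  if (length(trace) != cfg$n_grid) stop("trace length does not match the simulation grid")
  i <- which(trace >= cfg$theta)[1]
  if (is.na(i)) {
    list(fired = FALSE, t_fa = cfg$T + cfg$deltaT, index = cfg$n_grid)
  } else {
    list(fired = TRUE, t_fa = cfg$grid[i], index = i)
  }
}

#' Write a potential trace as two-column text
#'
#' Debug export for plotting: `time_ms potential` per grid point.
#'
#' @param trace Potential values on the grid of `cfg`.
#' @param cfg A [neuron_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, cfg, path) {
  utils::write.table(data.frame(time_ms = cfg$grid, potential = trace),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
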