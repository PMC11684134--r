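# Population encoding: normalized feature values -> presynaptic spike times
# via overlapping Gaussian receptive fields. Each feature drives Q
# receptive-field neurons; stronger activation fires earlier.

#' Build a Gaussian receptive-field bank
#'
#' For Q fields per feature, the centers are mu_l = (2l - 3) / (2(Q - 2)),
#' l = 1..Q (spanning slightly beyond \[0, 1\]) and the shared width is
#' sigma = 1 / (beta (Q - 2)), where beta is the overlap constant controlling
#' how strongly neighbouring fields' tuning curves overlap. The total number
#' of presynaptic neurons is P = n_features * Q.
#'
#' @param Q Receptive-field neurons per feature; at least 3, since the center
#'   and width expressions divide by Q - 2 (Q = 2 would divide by zero).
#' @param beta Overlap constant, > 0.
#' @param n_features Number of features to be encoded.
#' @param T Encoding window in ms: the latest possible presynaptic spike.
#' @return An object of class `rf_bank`.
#' @export
build_bank <- function(Q, beta, n_features, T = 3) {
  if (!is_scalar_number(Q) || Q < 3) {
    stop("Q must be at least 3: centers and widths divide by (Q - 2), which is zero at Q = 2")
  }
  check_scalar(beta, "beta", positive = TRUE)
  check_scalar(n_features, "n_features", positive = TRUE)
  check_scalar(T, "T", positive = TRUE)
  Q <- as.integer(Q)
  l <- seq_len(Q)
  centers <- (2 * l - 3) / (2 * (Q - 2))
  width <- 1 / (beta * (Q - 2))
  structure(
    list(Q = Q, beta = beta, centers = centers, width = width,
         n_features = as.integer(n_features),
         P = as.integer(n_features * Q), T = T),
    class = "rf_bank"
  )
}

#' Firing strength of one receptive field
#'
#' psi = exp(-(x - mu_l)^2 / (2 sigma_l^2)), in (0, 1]; equal to 1 exactly
#' when x sits on the field center. Defined for every real x, so feature
#' values outside \[0, 1\] (max-normalized negative features) simply yield
#' vanishing strength and a spike at the end of the window.
#'
#' @param x Normalized feature value(s).
#' @param bank An [build_bank()] object.
#' @param l Field index in 1..Q.
#' @return Firing strength(s) in (0, 1].
#' @export
firing_strength <- function(x, bank, l) {
  stopifnot(inherits(bank, "rf_bank"))
  if (any(l < 1) || any(l > bank$Q)) stop(sprintf("field index l must be in 1..%d", bank$Q))
  exp(-(x - bank$centers[l])^2 / (2 * bank$width^2))
}

#' Encode one feature vector as presynaptic spike times
#'
#' Each feature m activates its Q receptive fields with strength psi_m^l;
#' presynaptic neuron j = (m - 1) Q + l fires once at t = T (1 - psi), so a
#' perfectly matched field (psi = 1) fires at 0 ms and an unresponsive one at
#' T ms. Times are snapped to the simulation grid (nearest point, ties
#' rounding down) because the learning rule samples efficacy functions at
#' these times.
#'
#' @param x Numeric vector of length `n_features` (normalized values).
#' @param bank An [build_bank()] object.
#' @param dt Simulation step in ms (the grid spacing).
#' @return An object of class `spike_pattern` with fields `times` (ms),
#'   `grid_index` (1-based index into the simulation grid), `neuron`,
#'   `feature`, `field`, `T`, `dt`. Exactly one spike per presynaptic neuron.
#' @export
encode_sample <- function(x, bank, dt = 0.01) {
  stopifnot(inherits(bank, "rf_bank"))
  if (length(x) != bank$n_features) {
    stop(sprintf("feature vector length (%d) does not match bank n_features (%d)",
                 length(x), bank$n_features))
  }
  check_scalar(dt, "dt", positive = TRUE)
  psi <- exp(-outer(x, bank$centers, "-")^2 / (2 * bank$width^2))  # N x Q
  t_raw <- bank$T * (1 - as.vector(t(psi)))  # neuron j = (m-1)Q + l ordering
  idx <- snap_index(t_raw, dt)
  structure(
    list(times = idx * dt, grid_index = idx + 1L,
         neuron = seq_len(bank$P),
         feature = rep(seq_len(bank$n_features), each = bank$Q),
         field = rep(seq_len(bank$Q), bank$n_features),
         T = bank$T, dt = dt),
    class = "spike_pattern"
  )
}

# Encode every row of a (normalized) feature table; internal helper used by
# training and prediction.
encode_table <- function(table, bank, dt) {
  lapply(seq_len(nrow(table$values)), function(i) {
    encode_sample(table$values[i, ], bank, dt)
  })
}

#' Write a spike pattern as two-column text
#'
#' Debug export: one line per presynaptic spike, `neuron_index time_ms`.
#'
#' @param pattern A [encode_sample()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "spike_pattern"))
  utils::write.table(
    data.frame(neuron_index = pattern$neuron, time_ms = pattern$times),
    path, row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}
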