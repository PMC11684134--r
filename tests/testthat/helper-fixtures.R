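# Shared fixtures and independent oracles, built in code at test time.

toy_table <- function() {
  read_feature_table(system.file("extdata", "toy_synthetic.csv", package = "sefron"),
                     id_cols = "sample_id")
}

# Small normalized table for fast training runs.
small_table <- function(n = 40, f = 4, separation = 4, fraction = 0.5, seed = 11) {
  tab <- generate_synthetic(synthetic_spec(n, f, class_fraction = fraction,
                                           separation = separation, seed = seed))
  apply_normalizer(fit_normalizer(tab), tab)
}

# A random spike pattern on the grid (not via the encoder), for oracle tests.
random_pattern <- function(P, cfg, seed) {
  set.seed(seed)
  idx <- sample.int(cfg$n_grid - 1L, P, replace = TRUE) - 1L
  # keep spikes inside the presynaptic window
  idx <- pmin(idx, as.integer(round(cfg$T / cfg$dt)))
  structure(
    list(times = idx * cfg$dt, grid_index = idx + 1L, neuron = seq_len(P),
         feature = rep(1L, P), field = seq_len(P), T = cfg$T, dt = cfg$dt),
    class = "spike_pattern"
  )
}

# Independent naive oracle for the membrane potential: explicit double loop
# over grid points and presynaptic spikes, no matrix algebra.
naive_potential <- function(pattern, eff, cfg) {
  v <- numeric(cfg$n_grid)
  for (g in seq_len(cfg$n_grid)) {
    t <- cfg$grid[g]
    acc <- 0
    for (j in seq_along(pattern$times)) {
      st <- pattern$times[j]
      d <- t - st
      if (d > 0) {
        acc <- acc + eff$omega[j, pattern$grid_index[j]] *
          (d / cfg$tau) * exp(1 - d / cfg$tau)
      }
    }
    v[g] <- acc
  }
  v
}

# Independent metric oracle: MCC via the Pearson correlation of the binary
# indicator vectors (an algebraically different route than the count formula),
# the rest via prevalence-weighted identities on reconstructed label vectors.
oracle_metrics <- function(TP, FP, TN, FN) {
  truth <- c(rep(1, TP + FN), rep(0, TN + FP))
  pred <- c(rep(1, TP), rep(0, FN), rep(0, TN), rep(1, FP))
  sens <- if (TP + FN > 0) mean(pred[truth == 1]) else 0
  spec <- if (TN + FP > 0) mean(1 - pred[truth == 0]) else 0
  mcc <- suppressWarnings(stats::cor(truth, pred))
  list(accuracy = mean(truth == pred), sensitivity = sens, specificity = spec,
       MCC = if (is.na(mcc)) 0 else mcc, Gmean = sqrt(sens * spec))
}
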