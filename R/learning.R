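# SEFRON training: normalized-STDP credit assignment, reference PSP, overall
# strength error, Gaussian-modulated efficacy-function updates, first-sample
# initialization and the online epoch loop.

#' Configure the STDP rule
#'
#' The weight change for a presynaptic-to-postsynaptic delay x is
#' V_plus * exp(-x / tau_plus) for x >= 0 and 0 for x < 0: with a single
#' postsynaptic spike no depression branch is exercised, so the LTD
#' amplitude is fixed at zero. V_plus cancels in the normalization of the
#' fractional contributions, so its scale is immaterial; it defaults to 1.
#'
#' @param V_plus Maximum potentiation amplitude (> 0; cancels downstream).
#' @param tau_plus LTP window in ms: larger values weight early presynaptic
#'   spikes more heavily in the credit assignment.
#' @param sigma_update Efficacy update range in ms: the SD of the Gaussian
#'   bump by which each weight change is spread along the time axis. Small
#'   values keep the efficacy functions sharply time-varying.
#' @return An object of class `stdp_config` (LTD fields fixed at zero).
#' @export
stdp_config <- function(V_plus = 1, tau_plus = 0.45, sigma_update = 0.08) {
  check_scalar(V_plus, "V_plus", positive = TRUE)
  check_scalar(tau_plus, "tau_plus", positive = TRUE)
  check_scalar(sigma_update, "sigma_update", positive = TRUE)
  structure(
    list(V_plus = V_plus, V_minus = 0, tau_plus = tau_plus, tau_minus = NA_real_,
         sigma_update = sigma_update),
    class = "stdp_config"
  )
}

#' Configure the training loop
#'
#' @param mu Learning rate.
#' @param epochs Maximum training epochs.
#' @param shuffle_seed Seed for the per-epoch sample order.
#' @param update_variant `"respective_times"` (default) pairs each overall
#'   strength with the fractional contributions at its own firing time,
#'   mu (lambda_d chi(t_fd) - lambda_a chi(t_fa)): it boosts synapses active
#'   just before the desired time while suppressing those that caused the
#'   actual (wrong-time) firing, and is the form that trains reliably.
#'   `"as_printed"` uses the desired-time contributions in both terms,
#'   mu (lambda_d chi(t_fd) - lambda_a chi(t_fd)) = mu epsilon chi(t_fd);
#'   because epsilon is negative whenever the neuron fires late or not at
#'   all, that variant weakens exactly the synapses that should drive the
#'   desired firing and tends not to converge — it is kept for comparison.
#' @param update_policy When to apply an update. `"mismatch"` (default)
#'   updates a sample only when its decoded class is wrong — the
#'   classification error is the driving signal, and training reaches a
#'   fixed point once every training sample is on the right side of the
#'   boundary, leaving correctly placed early firings untouched.
#'   `"always"` applies the timing-driven update to every sample whose
#'   firing time differs from its desired time (skipping exact hits, where
#'   epsilon = 0); it pursues exact timing at the cost of eroding the
#'   potential margin of samples that already fire early, and is kept for
#'   timing-convergence studies.
#' @param lambda_cap Guard bounding the overall strength lambda = theta/V_PSP
#'   when the reference potential is tiny (late or absent firing).
#' @param early_stop Stop early once training can no longer change: for
#'   `"mismatch"`, an epoch with zero updates; for `"always"`, a training
#'   Gmean of 1 or a mean absolute timing error below one grid step.
#' @return An object of class `learn_config`.
#' @export
learn_config <- function(mu = 0.075, epochs = 100, shuffle_seed = 1,
                         update_variant = c("respective_times", "as_printed"),
                         update_policy = c("mismatch", "always"),
                         lambda_cap = 100, early_stop = TRUE) {
  if (!is_scalar_number(mu) || mu < 0) stop("mu must be a single number >= 0")
  if (!is_scalar_number(epochs) || epochs < 1) stop("epochs must be >= 1")
  check_scalar(lambda_cap, "lambda_cap", positive = TRUE)
  update_variant <- match.arg(update_variant)
  update_policy <- match.arg(update_policy)
  structure(
    list(mu = mu, epochs = as.integer(epochs),
         shuffle_seed = as.integer(shuffle_seed),
         update_variant = update_variant, update_policy = update_policy,
         lambda_cap = lambda_cap, early_stop = isTRUE(early_stop)),
    class = "learn_config"
  )
}

#' Bundle all SEFRON hyperparameters
#'
#' Collects the encoding, neuron, STDP and training settings in one object.
#' The defaults are the operating point used throughout: Q = 6 receptive
#' fields, overlap beta = 0.7, learning rate mu = 0.075, update range
#' sigma = 0.08 ms, LTP window tau_plus = 0.45 ms, membrane constant
#' tau = 0.63 ms, presynaptic window T = 3 ms observed up to 4 ms, class
#' boundary t_b = 2 ms.
#'
#' @param Q Receptive-field neurons per feature.
#' @param beta Overlap constant of the receptive fields.
#' @param neuron A [neuron_config()].
#' @param stdp An [stdp_config()].
#' @param learn A [learn_config()].
#' @return An object of class `sefron_config`.
#' @export
sefron_config <- function(Q = 6, beta = 0.7, neuron = neuron_config(),
                          stdp = stdp_config(), learn = learn_config()) {
  stopifnot(inherits(neuron, "neuron_config"), inherits(stdp, "stdp_config"),
            inherits(learn, "learn_config"))
  if (!is_scalar_number(Q) || Q < 3) stop("Q must be at least 3")
  check_scalar(beta, "beta", positive = TRUE)
  structure(list(Q = as.integer(Q), beta = beta, neuron = neuron,
                 stdp = stdp, learn = learn),
            class = "sefron_config")
}

#' STDP weight change for a given delay
#'
#' @param x Delay(s) in ms between presynaptic and postsynaptic spikes
#'   (positive = presynaptic first).
#' @param cfg An [stdp_config()].
#' @return delta-omega value(s): V_plus exp(-x/tau_plus) for x >= 0, else 0.
#' @export
stdp_delta <- function(x, cfg) {
  stopifnot(inherits(cfg, "stdp_config"))
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- cfg$V_plus * exp(-x[pos] / cfg$tau_plus)
  out
}

#' Fractional contribution of each presynaptic spike
#'
#' chi_j^k(t_f) = delta_omega(t_f - st_j^k) / sum over all spikes of the
#' same: each spike's normalized share of the STDP credit for a postsynaptic
#' firing at t_f. Sums to exactly 1. Spikes after t_f get zero credit.
#'
#' @param pattern A [encode_sample()] spike pattern.
#' @param t_f Postsynaptic firing time in ms.
#' @param cfg An [stdp_config()].
#' @return Numeric vector of contributions, one per presynaptic spike.
#' @export
fractional_contributions <- function(pattern, t_f, cfg) {
  stopifnot(inherits(pattern, "spike_pattern"))
  d <- stdp_delta(t_f - pattern$times, cfg)
  s <- sum(d)
  if (s <= 0) {
    stop(sprintf(
      "degenerate firing time t_f = %g ms: no presynaptic spike at or before it", t_f))
  }
  d / s
}

#' Reference postsynaptic potential at a firing time
#'
#' V_PSP(t_f) = sum chi_j^k(t_f) phi(t_f - st_j^k): the potential the neuron
#' would show at t_f if the weights were replaced by the normalized STDP
#' credit. It serves as the per-sample reference scale for the weights.
#'
#' @param pattern A [encode_sample()] spike pattern.
#' @param t_f Firing time in ms.
#' @param chi Contributions from [fractional_contributions()] at the same t_f.
#' @param tau LIF time constant in ms.
#' @return The scalar reference potential.
#' @export
reference_psp <- function(pattern, t_f, chi, tau) {
  stopifnot(inherits(pattern, "spike_pattern"))
  sum(chi * spike_response(t_f - pattern$times, tau))
}

#' Overall-strength error between desired and actual firing
#'
#' The overall strength at a firing time is lambda = theta / V_PSP, capped at
#' `lambda_cap` to bound updates when the reference potential is tiny. The
#' training error is epsilon = lambda(t_fd) - lambda(t_fa).
#'
#' @param theta Firing threshold.
#' @param Vpsp_d Reference potential at the desired firing time (> 0).
#' @param Vpsp_a Reference potential at the actual firing time.
#' @param lambda_cap Positive guard for the strengths.
#' @return `list(lambda_d, lambda_a, epsilon)`.
#' @export
strength_error <- function(theta, Vpsp_d, Vpsp_a, lambda_cap = 100) {
  if (!is_scalar_number(Vpsp_d) || Vpsp_d <= 0) {
    stop("reference potential at the desired firing time must be positive")
  }
  lambda_d <- min(theta / Vpsp_d, lambda_cap)
  lambda_a <- if (!is_scalar_number(Vpsp_a) || Vpsp_a <= 0) {
    lambda_cap
  } else {
    min(theta / Vpsp_a, lambda_cap)
  }
  list(lambda_d = lambda_d, lambda_a = lambda_a, epsilon = lambda_d - lambda_a)
}

# Add Gaussian bumps to the efficacy functions: row j gains
# dw[j] * exp(-(grid - st_j)^2 / (2 sigma^2)). `basis` may be precomputed.
add_bumps <- function(eff, pattern, dw, sigma, basis = NULL) {
  if (is.null(basis)) {
    basis <- exp(-outer(pattern$times, eff$grid, "-")^2 / (2 * sigma^2))
  }
  eff$omega <- eff$omega + dw * basis
  eff
}

#' One SEFRON efficacy-function update
#'
#' Computes the per-spike scalar weight change from the overall-strength
#' mismatch between the desired firing time `t_fd` and the actual firing
#' time `t_fa`, then spreads each change along the time axis as a Gaussian
#' bump centered on the presynaptic spike (SD `sigma_update`) and adds the
#' bumps to the efficacy functions. The bump peak equals the scalar change
#' exactly, so omega_j(st_j) moves by delta-omega_j.
#'
#' @param eff An [efficacy_functions()] object.
#' @param pattern The sample's spike pattern.
#' @param t_fd Desired firing time (ms).
#' @param t_fa Actual firing time (ms; T + deltaT when the neuron did not
#'   fire).
#' @param neuron_cfg,stdp_cfg,learn_cfg Configuration objects.
#' @param basis Optional precomputed P x n_grid Gaussian bump basis for this
#'   pattern (performance path used by [sefron_train()]).
#' @return `list(eff, context)`: updated efficacies plus the update context
#'   (chi values, reference potentials, strengths, epsilon, delta_omega).
#' @export
efficacy_update <- function(eff, pattern, t_fd, t_fa, neuron_cfg, stdp_cfg,
                            learn_cfg, basis = NULL) {
  stopifnot(inherits(neuron_cfg, "neuron_config"), inherits(stdp_cfg, "stdp_config"),
            inherits(learn_cfg, "learn_config"))
  chi_d <- fractional_contributions(pattern, t_fd, stdp_cfg)
  Vpsp_d <- reference_psp(pattern, t_fd, chi_d, neuron_cfg$tau)
  chi_a <- fractional_contributions(pattern, t_fa, stdp_cfg)
  Vpsp_a <- reference_psp(pattern, t_fa, chi_a, neuron_cfg$tau)
  se <- strength_error(neuron_cfg$theta, Vpsp_d, Vpsp_a, learn_cfg$lambda_cap)
  chi_second <- if (learn_cfg$update_variant == "as_printed") chi_d else chi_a
  dw <- learn_cfg$mu * (se$lambda_d * chi_d - se$lambda_a * chi_second)
  context <- list(chi_d = chi_d, chi_a = chi_a, Vpsp_d = Vpsp_d, Vpsp_a = Vpsp_a,
                  lambda_d = se$lambda_d, lambda_a = se$lambda_a,
                  epsilon = se$epsilon, delta_omega = dw)
  if (any(dw != 0)) {
    eff <- add_bumps(eff, pattern, dw, stdp_cfg$sigma_update, basis)
  }
  list(eff = eff, context = context)
}

#' Initialize efficacy functions from the first training sample
#'
#' The threshold is defined only implicitly (it equals the potential at the
#' firing time), which a free initialization cannot satisfy; fixing
#' theta and constructing the initial weights from one sample resolves it:
#' each synapse receives a Gaussian bump of height
#' lambda_d chi_j(t_fd) with lambda_d = theta / V_PSP(t_fd), which makes that
#' sample's potential equal exactly theta at its desired firing time. The
#' sample then fires within one grid step of t_fd (earlier only if the
#' potential already crosses theta before t_fd).
#'
#' @param eff All-zero [efficacy_functions()].
#' @param pattern The first training sample's spike pattern.
#' @param t_fd The sample's desired firing time (ms).
#' @param neuron_cfg,stdp_cfg Configuration objects.
#' @param basis Optional precomputed bump basis (see [efficacy_update()]).
#' @return The initialized efficacy functions.
#' @export
initialize_from_sample <- function(eff, pattern, t_fd, neuron_cfg, stdp_cfg,
                                   basis = NULL) {
  stopifnot(inherits(eff, "efficacy_fns"))
  if (any(eff$omega != 0)) {
    stop("efficacy functions are already non-zero; initialization must start from zero")
  }
  chi_d <- fractional_contributions(pattern, t_fd, stdp_cfg)  # errors if degenerate
  Vpsp_d <- reference_psp(pattern, t_fd, chi_d, neuron_cfg$tau)
  if (Vpsp_d <= 0) stop("degenerate pattern: zero reference potential at t_fd")
  w <- (neuron_cfg$theta / Vpsp_d) * chi_d
  add_bumps(eff, pattern, w, stdp_cfg$sigma_update, basis)
}

#' Train a SEFRON model
#'
#' Online learning on an already-normalized feature table: the efficacy
#' functions are initialized from the first row, then each epoch presents
#' the samples in a seeded shuffled order, computes the actual firing time,
#' and applies one efficacy update toward the class's desired firing time
#' whenever the sample's update policy demands it (by default on
#' classification mismatch; see [learn_config()]). The per-epoch mean
#' absolute timing error and training Gmean are logged; `early_stop` ends
#' training at the policy's fixed point. Deterministic given the shuffle
#' seed.
#'
#' Single-class tables are accepted (with a message) as a convergence
#' diagnostic; classification use requires both classes.
#'
#' @param table A normalized [feature_table()].
#' @param config A [sefron_config()].
#' @param normalizer Optional fitted [fit_normalizer()] stored with the model
#'   so that [predict.sefron_model()] can accept raw-scale data.
#' @param verbose Print per-epoch progress to stderr.
#' @return An object of class `sefron_model`.
#' @export
sefron_train <- function(table, config = sefron_config(), normalizer = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "sefron_config"))
  ncfg <- config$neuron
  scfg <- config$stdp
  lcfg <- config$learn
  M <- nrow(table$values)
  if (M < 1) stop("empty training table")
  if (length(unique(table$labels)) < 2) {
    message("note: training table holds a single class; treating as a convergence diagnostic run")
  }
  bank <- build_bank(config$Q, config$beta, ncol(table$values), ncfg$T)
  class_map <- c(ncfg$t_d1, ncfg$t_d2)

  patterns <- encode_table(table, bank, ncfg$dt)
  # Per-sample caches: kernel matrix (grid x P) for the potential and the
  # Gaussian bump basis (P x grid) for updates. Encoding is fixed, so these
  # are reused across epochs.
  Ks <- lapply(patterns, function(p) spike_response(outer(ncfg$grid, p$times, "-"), ncfg$tau))
  Bs <- lapply(patterns, function(p) {
    exp(-outer(p$times, ncfg$grid, "-")^2 / (2 * scfg$sigma_update^2))
  })

  eff <- efficacy_functions(bank$P, ncfg)
  eff <- initialize_from_sample(eff, patterns[[1]], class_map[table$labels[1]],
                                ncfg, scfg, basis = Bs[[1]])

  orders <- with_seed(lcfg$shuffle_seed, {
    lapply(seq_len(lcfg$epochs), function(e) sample.int(M))
  })

  log_epoch <- integer(0); log_err <- numeric(0); log_gmean <- numeric(0)
  P_idx <- seq_len(bank$P)
  for (epoch in seq_len(lcfg$epochs)) {
    abs_err <- numeric(M)
    pred <- integer(M)
    n_upd <- 0L
    for (i in orders[[epoch]]) {
      p <- patterns[[i]]
      w <- eff$omega[cbind(P_idx, p$grid_index)]
      trace <- as.vector(Ks[[i]] %*% w)
      fire <- find_fire_time(trace, ncfg)
      t_fd <- class_map[table$labels[i]]
      abs_err[i] <- abs(fire$t_fa - t_fd)
      pred[i] <- if (fire$t_fa < ncfg$t_b) 1L else 2L
      do_update <- if (lcfg$update_policy == "mismatch") {
        pred[i] != table$labels[i]
      } else {
        abs_err[i] > ncfg$dt / 2  # at t_fa == t_fd the error is exactly 0
      }
      if (do_update) {
        upd <- efficacy_update(eff, p, t_fd, fire$t_fa, ncfg, scfg, lcfg,
                               basis = Bs[[i]])
        eff <- upd$eff
        n_upd <- n_upd + 1L
      }
    }
    if (!all(is.finite(eff$omega))) {
      stop(sprintf("non-finite synaptic efficacy after epoch %d; lower mu or raise lambda_cap",
                   epoch))
    }
    cm <- confusion_counts(pred, table$labels)
    gm <- compute_metrics(cm)$Gmean
    log_epoch <- c(log_epoch, epoch)
    log_err <- c(log_err, mean(abs_err))
    log_gmean <- c(log_gmean, gm)
    if (verbose) {
      message(sprintf("epoch %3d: mean |t_fa - t_fd| = %.4f ms, train Gmean = %.4f, updates = %d",
                      epoch, mean(abs_err), gm, n_upd))
    }
    if (lcfg$early_stop) {
      done <- if (lcfg$update_policy == "mismatch") {
        n_upd == 0L
      } else {
        gm >= 1 || mean(abs_err) < ncfg$dt
      }
      if (done) break
    }
  }

  structure(
    list(bank = bank, config = config, efficacies = eff,
         class_map = class_map, normalizer = normalizer,
         training_log = data.frame(epoch = log_epoch, mean_abs_dt = log_err,
                                   train_gmean = log_gmean)),
    class = "sefron_model"
  )
}

#' @export
print.sefron_model <- function(x, ...) {
  n_ep <- nrow(x$training_log)
  cat(sprintf("sefron_model: %d features x Q=%d fields (P=%d synapses), %d training epochs\n",
              x$bank$n_features, x$bank$Q, x$bank$P, n_ep))
  if (n_ep > 0) {
    cat(sprintf("final mean |t_fa - t_fd| = %.4f ms, train Gmean = %.4f\n",
                x$training_log$mean_abs_dt[n_ep], x$training_log$train_gmean[n_ep]))
  }
  invisible(x)
}

#' Save a SEFRON model bundle as JSON
#'
#' Writes configuration, receptive-field bank, class map, normalizer and the
#' full efficacy matrix with full numeric precision; [load_model()] restores
#' an identical model. Byte-identical output for identical models.
#'
#' @param model A [sefron_train()] result.
#' @param path Output path (conventionally `model.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sefron_model"))
  payload <- list(
    format = "sefron-model-1",
    Q = model$config$Q, beta = model$config$beta,
    neuron = unclass(model$config$neuron)[c("tau", "theta", "T", "deltaT", "dt",
                                            "t_b", "t_d1", "t_d2")],
    stdp = unclass(model$config$stdp)[c("V_plus", "tau_plus", "sigma_update")],
    learn = unclass(model$config$learn),
    n_features = model$bank$n_features,
    class_map = model$class_map,
    normalizer = if (is.null(model$normalizer)) NULL else unclass(model$normalizer),
    training_log = model$training_log,
    omega = model$efficacies$omega
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a SEFRON model bundle
#'
#' @param path Path written by [save_model()].
#' @return A `sefron_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "sefron-model-1")) stop("not a sefron model bundle: ", path)
  ncfg <- do.call(neuron_config, as.list(p$neuron))
  scfg <- do.call(stdp_config, as.list(p$stdp))
  lcfg <- do.call(learn_config, as.list(p$learn))
  config <- sefron_config(Q = p$Q, beta = p$beta, neuron = ncfg, stdp = scfg,
                          learn = lcfg)
  bank <- build_bank(p$Q, p$beta, p$n_features, ncfg$T)
  eff <- efficacy_functions(bank$P, ncfg)
  eff$omega <- matrix(as.numeric(p$omega), nrow = bank$P)
  norm <- if (is.null(p$normalizer)) NULL else structure(p$normalizer, class = "normalizer")
  structure(
    list(bank = bank, config = config, efficacies = eff,
         class_map = as.numeric(p$class_map), normalizer = norm,
         training_log = as.data.frame(p$training_log)),
    class = "sefron_model"
  )
}
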