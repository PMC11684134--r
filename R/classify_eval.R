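# Decoding firing times into classes, figures of merit, cross-validation,
# percentage-split evaluation and hyperparameter sweeps.

#' Predict classes with a trained SEFRON model
#'
#' Each sample is encoded, its membrane potential simulated, and the actual
#' firing time t_a decoded by the temporal boundary: class-1 if t_a < t_b,
#' class-2 otherwise (the boundary itself and the no-fire convention
#' t_a = T + deltaT both decode as class-2).
#'
#' @param object A [sefron_train()] model.
#' @param newdata A [feature_table()] or numeric matrix. If the model carries
#'   a normalizer it is applied here (pass raw-scale data); otherwise the
#'   data must already be normalized.
#' @param ... Unused.
#' @return A data.frame of prediction records: `sample_id`, `t_a` (ms),
#'   `fired`, `y` (predicted class), `d` (true class or NA), `mismatch`.
#' @export
predict.sefron_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    newdata <- feature_table(newdata, labels = rep(1L, nrow(newdata)),
                             provenance = "unlabeled matrix")
    truth <- rep(NA_integer_, nrow(newdata$values))
  } else {
    stopifnot(inherits(newdata, "feature_table"))
    truth <- newdata$labels
  }
  if (!is.null(object$normalizer)) {
    newdata <- apply_normalizer(object$normalizer, newdata)
  }
  if (ncol(newdata$values) != object$bank$n_features) {
    stop(sprintf("newdata has %d features but the model was trained on %d",
                 ncol(newdata$values), object$bank$n_features))
  }
  ncfg <- object$config$neuron
  eff <- object$efficacies
  P_idx <- seq_len(object$bank$P)
  n <- nrow(newdata$values)
  t_a <- numeric(n); fired <- logical(n)
  for (i in seq_len(n)) {
    p <- encode_sample(newdata$values[i, ], object$bank, ncfg$dt)
    trace <- membrane_potential(p, eff, ncfg)
    fire <- find_fire_time(trace, ncfg)
    t_a[i] <- fire$t_fa
    fired[i] <- fire$fired
  }
  y <- ifelse(t_a < ncfg$t_b, 1L, 2L)
  data.frame(sample_id = newdata$sample_ids, t_a = t_a, fired = fired,
             y = y, d = truth, mismatch = !is.na(truth) & y != truth,
             stringsAsFactors = FALSE)
}

#' Confusion counts for two-class predictions
#'
#' Class-1 is the positive class (the detection target, e.g. patients).
#'
#' @param pred Predicted classes (1/2).
#' @param truth True classes (1/2).
#' @return An object of class `confusion_counts` with TP, FP, TN, FN.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0) {
    stop("pred and truth must be non-empty vectors of equal length")
  }
  structure(
    list(TP = sum(pred == 1L & truth == 1L),
         FP = sum(pred == 1L & truth == 2L),
         TN = sum(pred == 2L & truth == 2L),
         FN = sum(pred == 2L & truth == 1L)),
    class = "confusion_counts"
  )
}

#' Seven figures of merit from confusion counts
#'
#' Accuracy, sensitivity (recall of class-1), specificity, Matthews
#' correlation coefficient, precision, F1 and Gmean =
#' sqrt(sensitivity * specificity). Any 0/0 ratio is defined as 0 and the
#' affected metric names are recorded in the `"zero_division"` attribute.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `metrics_report` (a named list of the seven
#'   metrics, all in \[0, 1\] except MCC in \[-1, 1\]).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion counts")
  flags <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  sens <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  prec <- ratio(TP, TP + FP, "precision")
  f1 <- ratio(2 * prec * sens, prec + sens, "F1")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) { flags <- c(flags, "MCC"); 0 } else {
    (TP * TN - FP * FN) / mcc_den
  }
  out <- structure(
    list(accuracy = (TP + TN) / total, sensitivity = sens, specificity = spec,
         MCC = mcc, precision = prec, F1 = f1, Gmean = sqrt(sens * spec)),
    class = "metrics_report"
  )
  attr(out, "zero_division") <- unique(flags)
  attr(out, "counts") <- counts
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %.4f | specificity %.4f | MCC %.4f | precision %.4f | F1 %.4f | Gmean %.4f\n",
    x$accuracy, x$sensitivity, x$specificity, x$MCC, x$precision, x$F1, x$Gmean))
  zd <- attr(x, "zero_division")
  if (length(zd)) cat("0/0 conventions applied to:", paste(zd, collapse = ", "), "\n")
  invisible(x)
}

metrics_to_row <- function(m) {
  data.frame(accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity, MCC = m$MCC, precision = m$precision,
             F1 = m$F1, Gmean = m$Gmean)
}

# Evaluate one train/test split: fit the normalizer on the training rows
# (unless a global normalizer is supplied), train, predict, score.
eval_split <- function(table, config, train_idx, test_idx, fold_label,
                       norm_mode, global_norm = NULL) {
  sub <- function(idx) {
    feature_table(table$values[idx, , drop = FALSE], table$labels[idx],
                  feature_names = table$feature_names,
                  sample_ids = table$sample_ids[idx],
                  provenance = table$provenance)
  }
  train_tab <- sub(train_idx)
  if (length(unique(train_tab$labels)) < 2) {
    stop(sprintf("training portion of %s holds a single class; cannot train a classifier",
                 fold_label))
  }
  norm <- if (is.null(global_norm)) {
    fit_normalizer(train_tab, mode = norm_mode, fitted_on = "train_only")
  } else {
    global_norm
  }
  model <- sefron_train(apply_normalizer(norm, train_tab), config)
  pred <- predict(model, apply_normalizer(norm, sub(test_idx)))
  compute_metrics(confusion_counts(pred$y, pred$d))
}

#' K-fold cross-validation of SEFRON
#'
#' Trains and evaluates one model per fold of `plan` and averages each metric
#' arithmetically across folds. By default the normalizer is refit on each
#' fold's training rows (leakage-free); `norm_scope = "global"` instead fits
#' it once on the full table, mirroring a whole-dataset normalization.
#'
#' @param table A raw-scale [feature_table()].
#' @param config A [sefron_config()].
#' @param plan A K-fold [make_split_plan()].
#' @param norm_mode Normalization mode, see [fit_normalizer()].
#' @param norm_scope `"fold"` (refit per training fold) or `"global"`.
#' @return An object of class `cv_result`: `per_fold` metric reports,
#'   `mean_report`, and the plan.
#' @export
cross_validate <- function(table, config = sefron_config(), plan,
                           norm_mode = c("paper_max", "minmax"),
                           norm_scope = c("fold", "global")) {
  stopifnot(inherits(plan, "split_plan"))
  if (plan$kind != "kfold") stop("cross_validate needs a kfold split plan")
  norm_mode <- match.arg(norm_mode)
  norm_scope <- match.arg(norm_scope)
  global_norm <- if (norm_scope == "global") {
    fit_normalizer(table, mode = norm_mode, fitted_on = "full_table")
  } else {
    NULL
  }
  per_fold <- lapply(seq_len(plan$K), function(k) {
    idx <- split_indices(plan, k)
    eval_split(table, config, idx$train, idx$test, sprintf("fold %d", k),
               norm_mode, global_norm)
  })
  fold_rows <- do.call(rbind, lapply(per_fold, metrics_to_row))
  mean_report <- structure(as.list(colMeans(fold_rows)), class = "metrics_report")
  structure(list(per_fold = per_fold, mean_report = mean_report, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\nmean: ", x$plan$K, x$plan$seed))
  print(x$mean_report)
  invisible(x)
}

#' Single percentage-split evaluation
#'
#' Trains on a seeded `train_fraction` split and evaluates on the held-out
#' remainder (training size floor(train_fraction * M), per class when
#' stratified).
#'
#' @param table A raw-scale [feature_table()].
#' @param config A [sefron_config()].
#' @param train_fraction Training proportion in (0, 1).
#' @param seed Split seed.
#' @param stratified Stratify the split by class (default TRUE).
#' @param norm_mode,norm_scope As in [cross_validate()].
#' @return A `metrics_report` for the test portion.
#' @export
percentage_split_eval <- function(table, config = sefron_config(),
                                  train_fraction = 0.9, seed = 1,
                                  stratified = TRUE,
                                  norm_mode = c("paper_max", "minmax"),
                                  norm_scope = c("fold", "global")) {
  norm_mode <- match.arg(norm_mode)
  norm_scope <- match.arg(norm_scope)
  plan <- make_split_plan(table, "percentage", train_fraction = train_fraction,
                          stratified = stratified, seed = seed)
  idx <- split_indices(plan)
  global_norm <- if (norm_scope == "global") {
    fit_normalizer(table, mode = norm_mode, fitted_on = "full_table")
  } else {
    NULL
  }
  out <- eval_split(table, config, idx$train, idx$test, "the percentage split",
                    norm_mode, global_norm)
  attr(out, "plan") <- plan
  out
}

#' Sweep one hyperparameter, holding the others at their defaults
#'
#' Retrains and cross-validates at each value of one tuning parameter while
#' the remaining parameters stay at the values in `config`, and reports the
#' mean Gmean curve — the standard sensitivity analysis for this classifier.
#'
#' @param table A raw-scale [feature_table()].
#' @param config Base [sefron_config()] supplying the fixed parameters.
#' @param param One of `"Q"`, `"beta"`, `"mu"`, `"sigma_update"`,
#'   `"tau_plus"`, `"tau"`.
#' @param values Numeric grid of values to scan (non-empty).
#' @param plan K-fold [make_split_plan()] reused at every value.
#' @return An object of class `sweep_result`: a data.frame with `value` and
#'   `Gmean` plus the parameter name and fixed-parameter snapshot.
#' @export
sweep_parameter <- function(table, config = sefron_config(), param, values, plan) {
  valid <- c("Q", "beta", "mu", "sigma_update", "tau_plus", "tau")
  if (length(param) != 1 || !param %in% valid) {
    stop(sprintf("param must be one of: %s", paste(valid, collapse = ", ")))
  }
  if (length(values) == 0) stop("empty value grid")
  set_param <- function(cfg, v) {
    switch(param,
      Q = { cfg$Q <- as.integer(v); cfg },
      beta = { cfg$beta <- v; cfg },
      mu = { cfg$learn$mu <- v; cfg },
      sigma_update = { cfg$stdp$sigma_update <- v; cfg },
      tau_plus = { cfg$stdp$tau_plus <- v; cfg },
      tau = { cfg$neuron$tau <- v; cfg })
  }
  gmean <- vapply(values, function(v) {
    cv <- cross_validate(table, set_param(config, v), plan)
    cv$mean_report$Gmean
  }, numeric(1))
  structure(
    list(param = param, curve = data.frame(value = values, Gmean = gmean),
         fixed = list(Q = config$Q, beta = config$beta, mu = config$learn$mu,
                      sigma_update = config$stdp$sigma_update,
                      tau_plus = config$stdp$tau_plus, tau = config$neuron$tau)),
    class = "sweep_result"
  )
}

#' Write a CV result (or single metrics report) as CSV
#'
#' One row per fold plus a `mean` row, columns in the standard reporting
#' order (accuracy through Gmean).
#'
#' @param x A `cv_result` or `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  if (inherits(x, "cv_result")) {
    rows <- do.call(rbind, lapply(x$per_fold, metrics_to_row))
    rows <- rbind(rows, metrics_to_row(x$mean_report))
    rows <- cbind(fold = c(as.character(seq_len(nrow(rows) - 1)), "mean"), rows)
  } else if (inherits(x, "metrics_report")) {
    rows <- cbind(fold = "test", metrics_to_row(x))
  } else {
    stop("x must be a cv_result or metrics_report")
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
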