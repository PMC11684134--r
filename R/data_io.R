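# Tabular data handling: labeled feature tables, max-normalization,
# synthetic-data generation and reproducible train/test splitting.

#' Construct a labeled feature table
#'
#' The basic container for a two-class tabular dataset: an M x N numeric
#' matrix of feature values plus a binary class label per sample. Labels are
#' coded as integers: 1 for class-1 (the positive class, e.g. patients) and
#' 2 for class-2 (e.g. healthy controls).
#'
#' @param values Numeric matrix, M samples x N features; no missing entries.
#' @param labels Integer vector of length M with values in \{1, 2\}.
#' @param feature_names Character vector of N feature names (defaults to the
#'   column names of `values`, or `f1..fN`).
#' @param sample_ids Character vector of M sample identifiers.
#' @param provenance Free-text note on where the data came from and how the
#'   raw labels were mapped.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = colnames(values),
                          sample_ids = rownames(values), provenance = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("feature values contain a missing entry at row %d, column %d",
                 bad[1], bad[2]))
  }
  M <- nrow(values)
  labels <- as.integer(labels)
  if (length(labels) != M) {
    stop(sprintf("labels length (%d) does not match number of samples (%d)",
                 length(labels), M))
  }
  if (anyNA(labels) || !all(labels %in% c(1L, 2L))) {
    stop("labels must be coded 1 (class-1) or 2 (class-2) with no missing values")
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(M))
  dimnames(values) <- list(NULL, feature_names)
  structure(
    list(values = values, labels = labels,
         feature_names = as.character(feature_names),
         sample_ids = as.character(sample_ids),
         provenance = provenance),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (class-1: %d, class-2: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a labeled feature table from CSV
#'
#' Expects a comma-separated file with a header row, a label column holding
#' exactly two distinct values, and numeric feature columns. Identifier
#' columns (e.g. a subject `name` column) can be excluded from the feature
#' matrix; the first one is used as the sample id.
#'
#' @param path Path to the CSV file.
#' @param label_col Name of the label column (default `"status"`).
#' @param id_cols Character vector of columns to treat as identifiers.
#' @param drop_cols Character vector of additional columns to discard.
#' @param class1_value Raw label value mapped to class-1 (positive class).
#'   Defaults to `1` when present among the label values, mirroring the
#'   clinical convention that 1 codes the patient group.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_col = "status", id_cols = NULL,
                               drop_cols = NULL, class1_value = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s (columns: %s)",
                 label_col, path, paste(names(df), collapse = ", ")))
  }
  raw <- df[[label_col]]
  vals <- sort(unique(raw))
  if (length(vals) != 2L) {
    stop(sprintf("label column '%s' must hold exactly two distinct values, found %d (%s)",
                 label_col, length(vals), paste(vals, collapse = ", ")))
  }
  if (is.null(class1_value)) {
    if (any(vals == 1)) {
      class1_value <- vals[vals == 1][1]
    } else {
      stop(sprintf(
        "label column '%s' holds values {%s}; none equals 1, so pass class1_value explicitly",
        label_col, paste(vals, collapse = ", ")))
    }
  }
  if (!class1_value %in% vals) {
    stop(sprintf("class1_value '%s' does not occur in label column '%s'",
                 class1_value, label_col))
  }
  labels <- ifelse(raw == class1_value, 1L, 2L)

  sample_ids <- if (!is.null(id_cols) && id_cols[1] %in% names(df)) {
    as.character(df[[id_cols[1]]])
  } else {
    paste0("s", seq_len(nrow(df)))
  }
  feat_cols <- setdiff(names(df), c(label_col, id_cols, drop_cols))
  if (length(feat_cols) == 0L) stop("no feature columns left after exclusions")
  for (cn in feat_cols) {
    if (!is.numeric(df[[cn]])) {
      first_bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("feature column '%s' is not numeric (first offending row: %s)",
                   cn, ifelse(is.na(first_bad), "header", first_bad)))
    }
  }
  feature_table(
    values = as.matrix(df[feat_cols]),
    labels = labels,
    feature_names = feat_cols,
    sample_ids = sample_ids,
    provenance = sprintf("read from %s; label '%s': raw value '%s' -> class-1",
                         basename(path), label_col, class1_value)
  )
}

#' Write a feature table to CSV
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces every double exactly. Labels are written as 1/2 in the
#' label column; sample ids go in a `sample_id` column.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param label_col Name for the label column (default `"status"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, label_col = "status") {
  stopifnot(inherits(table, "feature_table"))
  chr <- apply(table$values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = 1)
  df <- data.frame(sample_id = table$sample_ids, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", table$feature_names)
  df[[label_col]] <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Fit a per-feature normalizer
#'
#' In `paper_max` mode each feature is later divided by its maximum over the
#' fitting rows, x' = x / max_b; note that features with negative values
#' (e.g. the nonlinear `spread1` voice measure, which is strictly negative)
#' then map outside \[0, 1\] — the encoding stage tolerates this, assigning
#' such values vanishing receptive-field activation. `minmax` mode maps the
#' fitted \[min, max\] range linearly to \[0, 1\] instead.
#'
#' @param table A [feature_table()] holding the fitting rows (pass only the
#'   training rows for leakage-free evaluation).
#' @param mode `"paper_max"` (divide by column max) or `"minmax"`.
#' @param fitted_on Metadata tag recording whether the constants came from
#'   training rows only or from the full table.
#' @return An object of class `normalizer` storing the per-feature constants.
#' @export
fit_normalizer <- function(table, mode = c("paper_max", "minmax"),
                           fitted_on = c("train_only", "full_table")) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  fitted_on <- match.arg(fitted_on)
  v <- table$values
  if (mode == "paper_max") {
    mx <- apply(v, 2, max)
    zero <- which(mx == 0)
    if (length(zero)) {
      stop(sprintf("feature '%s' has a zero column maximum; max-normalization is undefined",
                   table$feature_names[zero[1]]))
    }
    structure(list(mode = mode, fitted_on = fitted_on,
                   per_feature_max = mx, feature_names = table$feature_names),
              class = "normalizer")
  } else {
    lo <- apply(v, 2, min)
    hi <- apply(v, 2, max)
    flat <- which(hi == lo)
    if (length(flat)) {
      stop(sprintf("feature '%s' is constant; min-max normalization is undefined",
                   table$feature_names[flat[1]]))
    }
    structure(list(mode = mode, fitted_on = fitted_on,
                   low = lo, high = hi, feature_names = table$feature_names),
              class = "normalizer")
  }
}

#' Apply a fitted normalizer
#'
#' Uses the constants stored at fit time (applying twice rescales twice; it
#' is not a refit).
#'
#' @param norm A `normalizer` from [fit_normalizer()].
#' @param table A [feature_table()] with the same feature set.
#' @return A normalized [feature_table()].
#' @export
apply_normalizer <- function(norm, table) {
  stopifnot(inherits(norm, "normalizer"), inherits(table, "feature_table"))
  if (!identical(norm$feature_names, table$feature_names)) {
    stop("feature names of the table do not match those the normalizer was fitted on")
  }
  v <- if (norm$mode == "paper_max") {
    sweep(table$values, 2, norm$per_feature_max, "/")
  } else {
    sweep(sweep(table$values, 2, norm$low, "-"), 2, norm$high - norm$low, "/")
  }
  out <- table
  out$values <- v
  out$provenance <- paste0(table$provenance, sprintf(" | normalized (%s, %s)",
                                                    norm$mode, norm$fitted_on))
  out
}

#' Specify a synthetic two-class dataset
#'
#' Describes a generator that emulates the structure of clinical voice-feature
#' tables: bounded continuous features (possibly strictly negative via
#' `value_range`), a binary label with controllable imbalance, optional
#' equicorrelated feature blocks (voice perturbation measures are strongly
#' inter-correlated), and optional replicated recordings per subject.
#'
#' @param n_samples Total number of rows.
#' @param n_features Number of feature columns; all are informative.
#' @param class_fraction Proportion of class-1 samples (0 < fraction < 1).
#' @param separation Inter-class mean distance per feature, in units of the
#'   within-class standard deviation.
#' @param correlation_block_size Features per equicorrelated block (1 = none).
#' @param correlation_rho Common within-block correlation, in \[0, 1).
#' @param replicates_per_subject Recordings per subject; >1 adds a shared
#'   subject-level random effect across replicates.
#' @param value_range Length-2 numeric `c(low, high)` applied to every
#'   feature, or a 2 x n_features matrix for per-feature ranges; generated
#'   values are clipped into the range.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_features, class_fraction = 0.5,
                           separation = 2, correlation_block_size = 1,
                           correlation_rho = 0, replicates_per_subject = 1,
                           value_range = c(0, 1), seed = 1) {
  check_scalar(n_samples, "n_samples")
  check_scalar(n_features, "n_features", positive = TRUE)
  check_scalar(class_fraction, "class_fraction")
  if (class_fraction <= 0 || class_fraction >= 1) {
    stop("class_fraction must lie strictly between 0 and 1")
  }
  check_scalar(separation, "separation")
  if (separation < 0) stop("separation must be >= 0")
  if (correlation_rho < 0 || correlation_rho >= 1) {
    stop("correlation_rho must lie in [0, 1)")
  }
  if (correlation_block_size < 1) stop("correlation_block_size must be >= 1")
  if (replicates_per_subject < 1) stop("replicates_per_subject must be >= 1")
  if (is.matrix(value_range)) {
    if (nrow(value_range) != 2 || ncol(value_range) != n_features) {
      stop("value_range matrix must be 2 x n_features")
    }
  } else {
    if (length(value_range) != 2) stop("value_range must be c(low, high)")
    value_range <- matrix(rep(value_range, n_features), nrow = 2)
  }
  if (any(value_range[2, ] <= value_range[1, ])) {
    stop("value_range high must exceed low for every feature")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
         class_fraction = class_fraction, separation = separation,
         correlation_block_size = as.integer(correlation_block_size),
         correlation_rho = correlation_rho,
         replicates_per_subject = as.integer(replicates_per_subject),
         value_range = value_range, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic two-class feature table
#'
#' Draws two multivariate-Gaussian classes whose per-feature means are offset
#' by `separation` within-class standard deviations, symmetric about the
#' middle of each feature's range. The within-class SD is fixed at 10% of the
#' range width, a scale at which `separation = 3` gives well-separated but
#' overlapping classes. Equicorrelated blocks are induced by a Cholesky
#' factor; with replicated recordings, 70% of the within-class variance is a
#' shared subject effect and 30% is replicate noise. Values are clipped into
#' the feature range.
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_table()]; class-1 count is `round(class_fraction * n)`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  if (n < 4) stop("degenerate spec: n_samples must be at least 4")
  n1 <- as.integer(round(spec$class_fraction * n))
  n2 <- n - n1
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf(
      "degenerate spec: class counts %d/%d cannot guarantee both classes (need >= 2 each)",
      n1, n2))
  }
  N <- spec$n_features
  lo <- spec$value_range[1, ]
  hi <- spec$value_range[2, ]
  s <- 0.1 * (hi - lo)                       # within-class SD per feature
  mid <- (lo + hi) / 2
  mu1 <- mid + spec$separation * s / 2
  mu2 <- mid - spec$separation * s / 2

  # Cholesky factor of the equicorrelated block structure (identity if b=1).
  b <- spec$correlation_block_size
  rho <- spec$correlation_rho
  mix <- diag(N)
  if (b > 1 && rho > 0) {
    starts <- seq(1, N, by = b)
    for (st in starts) {
      idx <- st:min(st + b - 1, N)
      k <- length(idx)
      if (k > 1) {
        Sigma <- matrix(rho, k, k); diag(Sigma) <- 1
        mix[idx, idx] <- chol(Sigma)
      }
    }
  }

  r <- spec$replicates_per_subject
  draw_class <- function(n_c, mu, class_tag) {
    if (r == 1L) {
      z <- matrix(stats::rnorm(n_c * N), n_c, N) %*% mix
      subj <- seq_len(n_c)
      rep_id <- rep(1L, n_c)
    } else {
      n_subj <- ceiling(n_c / r)
      subj <- rep(seq_len(n_subj), each = r)[seq_len(n_c)]
      rep_id <- unlist(lapply(table(subj), seq_len), use.names = FALSE)
      z_subj <- sqrt(0.7) * matrix(stats::rnorm(n_subj * N), n_subj, N) %*% mix
      z_rep <- sqrt(0.3) * matrix(stats::rnorm(n_c * N), n_c, N) %*% mix
      z <- z_subj[subj, , drop = FALSE] + z_rep
    }
    vals <- sweep(sweep(z, 2, s, "*"), 2, mu, "+")
    vals <- pmin(pmax(vals, matrix(lo, nrow(vals), N, byrow = TRUE)),
                 matrix(hi, nrow(vals), N, byrow = TRUE))
    list(values = vals,
         ids = sprintf("c%d_s%03d_r%d", class_tag, subj, rep_id))
  }

  out <- with_seed(spec$seed, {
    a <- draw_class(n1, mu1, 1L)
    b2 <- draw_class(n2, mu2, 2L)
    list(values = rbind(a$values, b2$values),
         labels = c(rep(1L, n1), rep(2L, n2)),
         ids = c(a$ids, b2$ids))
  })
  feature_table(
    values = out$values, labels = out$labels,
    feature_names = paste0("f", seq_len(N)),
    sample_ids = out$ids,
    provenance = sprintf("synthetic (seed %d, separation %g, fraction %g)",
                         spec$seed, spec$separation, spec$class_fraction)
  )
}

#' Build a reproducible train/test split plan
#'
#' Either a K-fold partition or a single percentage split, optionally
#' stratified by class (the default: each fold's per-class count is within
#' one sample of an even allocation). Percentage splits take
#' `floor(train_fraction * M)` training samples (applied per class when
#' stratified), the remainder going to the test set.
#'
#' @param table A [feature_table()] (only its labels are used).
#' @param kind `"kfold"` or `"percentage"`.
#' @param K Number of folds (kfold only), at least 2 and, when stratified,
#'   at most the minority-class count.
#' @param train_fraction Training proportion in (0, 1) (percentage only).
#' @param stratified Stratify by class? Default `TRUE`.
#' @param seed Integer seed controlling the random assignment.
#' @return An object of class `split_plan` with per-sample `fold_assignments`
#'   (fold index for kfold; 1 = train, 2 = test for percentage).
#' @export
make_split_plan <- function(table, kind = c("kfold", "percentage"), K = NULL,
                            train_fraction = NULL, stratified = TRUE, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  kind <- match.arg(kind)
  labels <- table$labels
  M <- length(labels)
  assignments <- integer(M)

  if (kind == "kfold") {
    if (is.null(K) || K < 2) stop("K must be an integer >= 2")
    K <- as.integer(K)
    if (stratified) {
      min_class <- min(tabulate(labels, nbins = 2L))
      if (K > min_class) {
        stop(sprintf("stratified K=%d exceeds the minority class count (%d)",
                     K, min_class))
      }
    } else if (K > M) {
      stop(sprintf("K=%d exceeds the number of samples (%d)", K, M))
    }
    with_seed(seed, {
      if (stratified) {
        for (cl in c(1L, 2L)) {
          idx <- which(labels == cl)
          perm <- sample(idx)
          assignments[perm] <- rep_len(seq_len(K), length(idx))
        }
      } else {
        perm <- sample.int(M)
        assignments[perm] <- rep_len(seq_len(K), M)
      }
    })
    n_folds <- K
  } else {
    if (is.null(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
      stop("train_fraction must lie strictly between 0 and 1 (1.0 leaves an empty test set)")
    }
    with_seed(seed, {
      if (stratified) {
        for (cl in c(1L, 2L)) {
          idx <- which(labels == cl)
          n_tr <- floor(train_fraction * length(idx))
          if (n_tr < 1 || n_tr >= length(idx)) {
            stop(sprintf("train_fraction %g leaves class %d without both train and test samples",
                         train_fraction, cl))
          }
          perm <- sample(idx)
          assignments[perm] <- c(rep(1L, n_tr), rep(2L, length(idx) - n_tr))
        }
      } else {
        n_tr <- floor(train_fraction * M)
        if (n_tr < 1 || n_tr >= M) stop("train_fraction leaves an empty train or test set")
        perm <- sample.int(M)
        assignments[perm] <- c(rep(1L, n_tr), rep(2L, M - n_tr))
      }
    })
    n_folds <- 1L
  }

  structure(
    list(kind = kind, K = if (kind == "kfold") K else NULL,
         train_fraction = if (kind == "percentage") train_fraction else NULL,
         stratified = stratified, seed = as.integer(seed),
         fold_assignments = assignments, n_folds = n_folds),
    class = "split_plan"
  )
}

#' Train/test indices for one fold of a split plan
#'
#' @param plan A [make_split_plan()] result.
#' @param fold Fold number (ignored for percentage plans).
#' @return `list(train = ..., test = ...)` of integer row indices.
#' @export
split_indices <- function(plan, fold = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  if (plan$kind == "kfold") {
    if (fold < 1 || fold > plan$K) stop(sprintf("fold must be in 1..%d", plan$K))
    test <- which(plan$fold_assignments == fold)
    list(train = which(plan$fold_assignments != fold), test = test)
  } else {
    list(train = which(plan$fold_assignments == 1L),
         test = which(plan$fold_assignments == 2L))
  }
}

#' Serialize a split plan to JSON
#'
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
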