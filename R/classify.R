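#' Feature table for texture classification
#'
#' Assembles multiscale-profile feature vectors and class labels into the
#' table consumed by the classification harness.  Rows containing any
#' undefined (NA) feature are excluded up front and counted — imputing a
#' missing entropy would manufacture texture information.
#'
#' @param features Numeric matrix (rows = samples, columns = features,
#'   e.g. one column per scale factor) or a list of
#'   [multiscale_profile()] objects.
#' @param labels Class labels, one per row; coerced to factor.  At least
#'   2 classes with at least 2 samples each must remain after exclusion.
#' @param ids Optional sample identifiers (default `sample_1..N`).
#' @return A `feature_table`: list with `features`, `labels`, `ids`,
#'   `n_excluded`.
#' @export
feature_table <- function(features, labels, ids = NULL) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features)) {
    stopifnot(all(vapply(features, inherits, logical(1), "multiscale_profile")))
    features <- do.call(rbind, lapply(features, `[[`, "values"))
    colnames(features) <- paste0("tau_", seq_len(ncol(features)))
  }
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop("`labels` must have one entry per feature row", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(features)))
  keep <- stats::complete.cases(features)
  n_excluded <- sum(!keep)
  features <- features[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  ids <- ids[keep]
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 samples (after excluding rows with ",
         "undefined features)", call. = FALSE)
  }
  structure(list(features = features, labels = labels, ids = ids,
                 n_excluded = n_excluded),
            class = "feature_table")
}

#' Repeated stratified train/test splits
#'
#' Draws `n_repeats` independent random splits of the samples into
#' training and test sets, stratified by class so every split preserves
#' the class proportions.  The total training size is
#' `round(train_frac * N)`; per-class training counts are apportioned by
#' largest fractional remainder (each class keeps at least one sample on
#' each side).
#'
#' @param table A [feature_table()], or a label vector.
#' @param train_frac Training fraction in `(0, 1)` (default 0.75).
#' @param n_repeats Number of splits (default 5).
#' @param seed Integer seed; the same seed reproduces the same splits.
#' @return A list of `n_repeats` lists, each with integer vectors `train`
#'   and `test` (disjoint, exhaustive).
#' @export
make_splits <- function(table, train_frac = 0.75, n_repeats = 5L, seed = 1L) {
  labels <- if (inherits(table, "feature_table")) table$labels else factor(table)
  ids <- if (inherits(table, "feature_table")) table$ids else NULL
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("stratification requires at least 2 samples per class", call. = FALSE)
  }
  # per-class training counts by largest remainder, clamped to [1, n_c - 1]
  target <- round(train_frac * n)
  exact <- train_frac * as.numeric(tab)
  base <- pmin(pmax(floor(exact), 1L), as.numeric(tab) - 1L)
  short <- target - sum(base)
  if (short > 0) {
    ord <- order(exact - floor(exact), decreasing = TRUE)
    for (k in ord) {
      if (short <= 0) break
      if (base[k] < tab[k] - 1L) { base[k] <- base[k] + 1L; short <- short - 1L }
    }
  }
  n_train <- base
  names(n_train) <- names(tab)
  if (n - sum(n_train) < 1L) stop("test set would be empty", call. = FALSE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_repeats), function(rep) {
    train <- integer(0)
    for (cls in names(tab)) {
      idx <- which(labels == cls)
      # canonical within-class order (by sample id) makes the drawn split
      # invariant to the row order of the table
      if (!is.null(ids)) idx <- idx[order(ids[idx])]
      train <- c(train, sample(idx, n_train[[cls]]))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Evaluate classification accuracy over repeated splits
#'
#' For each split, standardizes the features using training-set statistics
#' only, fits a support vector machine on the training rows and predicts
#' the test rows.  Accuracy is `100 * correct / total` per split; the
#' report carries every split's accuracy and their arithmetic mean.
#'
#' @param table A [feature_table()].
#' @param splits Splits from [make_splits()].
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param cost SVM regularization constant (default 1).
#' @return A `classification_report`: `accuracies` (per split, percent),
#'   `mean_accuracy`, `classifier` (settings string), `n_excluded`
#'   carried over from the table.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' x[11:20, ] <- x[11:20, ] + 4
#' tab <- feature_table(x, rep(c("a", "b"), each = 10))
#' evaluate_splits(tab, make_splits(tab, seed = 2))
#' @export
evaluate_splits <- function(table, splits, kernel = c("radial", "linear"),
                            cost = 1) {
  stopifnot(inherits(table, "feature_table"))
  kernel <- match.arg(kernel)
  x <- table$features
  y <- table$labels
  acc <- vapply(splits, function(sp) {
    if (length(unique(y[sp$train])) < 2L) {
      stop("degenerate split: training fold contains a single class",
           call. = FALSE)
    }
    mu <- colMeans(x[sp$train, , drop = FALSE])
    sigma <- apply(x[sp$train, , drop = FALSE], 2L, sd)
    sigma[sigma == 0] <- 1  # constant feature: leave centered, unscaled
    xs <- sweep(sweep(x, 2L, mu), 2L, sigma, `/`)
    fit <- e1071::svm(xs[sp$train, , drop = FALSE], y[sp$train],
                      kernel = kernel, cost = cost, scale = FALSE)
    pred <- predict(fit, xs[sp$test, , drop = FALSE])
    100 * mean(pred == y[sp$test])
  }, numeric(1))
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 classifier = sprintf(
                   "svm (libsvm via e1071), kernel=%s, cost=%g, gamma=1/d, features standardized on train folds",
                   kernel, cost),
                 n_excluded = table$n_excluded),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  cat("  classifier:", x$classifier, "\n")
  cat("  split accuracies (%):", paste(sprintf("%.2f", x$accuracies),
                                       collapse = ", "), "\n")
  cat(sprintf("  mean accuracy: %.2f%%\n", x$mean_accuracy))
  if (x$n_excluded > 0) {
    cat("  rows excluded for undefined features:", x$n_excluded, "\n")
  }
  invisible(x)
}
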