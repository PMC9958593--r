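# RBF-kernel support vector machine, least-squares formulation (LS-SVM,
# Suykens & Vandewalle 1999), one-vs-rest for multi-class. The dual solve
# (K + I/C) alpha = y needs only base linear algebra, is deterministic, and
# behaves like a standard soft-margin RBF SVM on these feature scales.

#' Train an RBF least-squares SVM
#'
#' @param x numeric matrix, rows = samples (already standardized by callers).
#' @param y class labels (any atomic type); at least two classes.
#' @param C regularization constant (default 1).
#' @param gamma RBF width; default `1 / (ncol(x) * mean(column variances))`.
#' @return object of class `lssvm`.
#' @export
lssvm_train <- function(x, y, C = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stopf("training data contains a single class")
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, var))
    gamma <- 1 / (ncol(x) * max(v, .Machine$double.eps))
  }
  K <- rbf_kernel(x, x, gamma)
  diag(K) <- diag(K) + 1 / C
  targets <- vapply(classes, function(cl) ifelse(y == cl, 1, -1),
                    numeric(length(y)))
  alpha <- solve(K, targets)
  structure(list(x = x, classes = classes, alpha = alpha, gamma = gamma, C = C),
            class = "lssvm")
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Predict classes with a trained [lssvm_train()] model
#'
#' @param object an `lssvm` model.
#' @param newdata numeric matrix with the same columns as the training data.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$x, object$gamma)
  scores <- K %*% object$alpha
  object$classes[max.col(scores, ties.method = "first")]
}

#' Pooled train/validation/test split specification
#'
#' @param fractions named or positional `(train, validation, test)`
#'   fractions; must be positive and sum to 1. Default 60/20/20.
#' @param seed RNG seed for the shuffle.
#' @param stratified draw per class (default) so class proportions are
#'   preserved within each split.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                       seed = 1L, stratified = TRUE) {
  if (length(fractions) != 3 || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be three positive numbers summing to 1")
  }
  names(fractions) <- c("train", "validation", "test")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into parts proportional to fractions.
apportion <- function(n, fractions) {
  ideal <- fractions * n
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Split a feature table into train/validation/test index sets
#'
#' Disjoint, exhaustive and deterministic given the seed. Under
#' stratification, sizes per class follow largest-remainder rounding of the
#' fractions, so per-class proportions are within one sample of the global
#' fractions; an error names any class too small to appear in every split.
#'
#' @param features feature table (needs a `label` column), or a vector of
#'   labels.
#' @param spec a [split_spec].
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(features, spec = split_spec()) {
  labels <- if (is.data.frame(features)) features$label else features
  n <- length(labels)
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(spec$seed, {
    if (spec$stratified) {
      for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        sizes <- apportion(length(idx), spec$fractions)
        if (any(sizes == 0)) {
          stopf("class %s has too few samples (%d) for a stratified split", cl, length(idx))
        }
        cuts <- cumsum(sizes)
        sets$train <- c(sets$train, idx[seq_len(cuts[1])])
        sets$validation <- c(sets$validation, idx[(cuts[1] + 1):cuts[2]])
        sets$test <- c(sets$test, idx[(cuts[2] + 1):cuts[3]])
      }
    } else {
      idx <- sample(n)
      sizes <- apportion(n, spec$fractions)
      cuts <- cumsum(sizes)
      sets$train <- idx[seq_len(cuts[1])]
      sets$validation <- idx[(cuts[1] + 1):cuts[2]]
      sets$test <- idx[(cuts[2] + 1):cuts[3]]
    }
  })
  lapply(sets, sort)
}

# z-score columns with statistics fit on the training rows only; constant
# columns are centred and left unscaled.
standardizer <- function(train_x) {
  mu <- colMeans(train_x)
  sdev <- apply(train_x, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  function(x) sweep(sweep(as.matrix(x), 2, mu), 2, sdev, "/")
}

#' Train and evaluate an SVM on a pooled split
#'
#' Standardizes the selected columns on the training rows, trains the
#' RBF-kernel SVM, and reports accuracy (%) on all three splits.
#'
#' @param features feature table.
#' @param columns feature column names to use (default all).
#' @param spec a [split_spec] (or a precomputed split list via `split`).
#' @param split optional precomputed result of [split_dataset()].
#' @param C,gamma SVM hyperparameters (see [lssvm_train()]).
#' @return list with `model`, `split`, and `accuracy` (named vector
#'   train/validation/test in %).
#' @export
train_and_eval <- function(features, columns = feature_columns(features),
                           spec = split_spec(), split = NULL, C = 1, gamma = NULL) {
  if (is.null(split)) split <- split_dataset(features, spec)
  x <- as.matrix(features[, columns, drop = FALSE])
  y <- features$label
  std <- standardizer(x[split$train, , drop = FALSE])
  model <- lssvm_train(std(x[split$train, , drop = FALSE]), y[split$train],
                       C = C, gamma = gamma)
  acc <- vapply(split, function(idx) {
    pred <- predict(model, std(x[idx, , drop = FALSE]))
    100 * mean(pred == as.character(y[idx]))
  }, numeric(1))
  list(model = model, split = split, accuracy = acc)
}

#' Subject-level cross-session evaluation
#'
#' For every subject, trains on that subject's session-1 epochs and tests on
#' the session-2 epochs (standardization fit on the training session),
#' measuring within-subject cross-session generalization.
#'
#' @param features feature table with `subject_id` and `session_id` columns.
#' @param columns feature column names to use.
#' @param train_session,test_session session ids (defaults 1 and 2).
#' @param C,gamma SVM hyperparameters.
#' @return data.frame with columns `subject` and `accuracy` (%).
#' @export
subject_holdout_eval <- function(features, columns = feature_columns(features),
                                 train_session = 1L, test_session = 2L,
                                 C = 1, gamma = NULL) {
  subjects <- unique(features$subject_id)
  acc <- vapply(subjects, function(s) {
    tr <- features$subject_id == s & features$session_id == train_session
    te <- features$subject_id == s & features$session_id == test_session
    if (!any(tr) || !any(te)) stopf("subject %s is missing a session", s)
    x <- as.matrix(features[, columns, drop = FALSE])
    std <- standardizer(x[tr, , drop = FALSE])
    model <- lssvm_train(std(x[tr, , drop = FALSE]), features$label[tr],
                         C = C, gamma = gamma)
    pred <- predict(model, std(x[te, , drop = FALSE]))
    100 * mean(pred == as.character(features$label[te]))
  }, numeric(1))
  data.frame(subject = subjects, accuracy = unname(acc))
}
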