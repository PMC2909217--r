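# Supervised baseline: RBF-kernel support vector machine with (C, gamma)
# chosen by grid search under stratified cross-validation. The quadratic
# program is delegated to libsvm (via e1071); this module owns the grid
# protocol, tie-breaking and the monotone score mapping.

#' Hyperparameter grid for the SVM baseline
#'
#' Geometric ladders for the soft-margin cost C and the RBF width gamma.
#' Defaults: C in 2^-5 .. 2^15 and gamma in 2^-15 .. 2^3, geometric step 4.
#'
#' @param C_values Positive cost ladder.
#' @param gamma_values Positive kernel-width ladder.
#' @param folds Cross-validation folds for the grid search (>= 2).
#' @return List of class `svm_grid`.
#' @export
svm_grid <- function(C_values = 2^seq(-5, 15, by = 2),
                     gamma_values = 2^seq(-15, 3, by = 2),
                     folds = 3L) {
  stopifnot(length(C_values) > 0, all(C_values > 0),
            length(gamma_values) > 0, all(gamma_values > 0), folds >= 2)
  structure(list(C_values = sort(C_values), gamma_values = sort(gamma_values),
                 folds = as.integer(folds)), class = "svm_grid")
}

# stratified fold assignment, reproducible under seed
.stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  rng <- .seeded_rng(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[rng$sample_perm(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# small seeded RNG scope that restores the caller's RNG state
.seeded_rng <- function(seed) {
  list(
    sample_perm = function(n) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      sample.int(n)
    }
  )
}

#' Grid-searched RBF SVM
#'
#' Evaluates every (C, gamma) combination by stratified n-fold
#' cross-validation accuracy on the labelled pairs, picks the maximiser
#' (ties broken by smallest C, then smallest gamma) and refits on all
#' labelled data. Features are z-scored with parameters estimated from the
#' training set.
#'
#' @param features Labelled pair feature table (data.frame with a `label`
#'   column) or numeric matrix.
#' @param labels Optional 0/1 vector when `features` is a matrix.
#' @param grid An [svm_grid()].
#' @param seed Integer seed controlling the inner CV fold assignment.
#' @return List of class `svm_model`: fitted e1071 model, chosen `C` and
#'   `gamma`, the CV accuracy table, and the standardization parameters.
#' @export
train_grid <- function(features, labels = NULL, grid = svm_grid(), seed = 1L) {
  X <- .feature_matrix(features)
  if (is.null(labels)) {
    stopifnot(is.data.frame(features), "label" %in% names(features))
    labels <- features$label
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd); sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  y <- factor(labels, levels = c(0L, 1L))
  n_folds <- min(grid$folds, min(table(y)))
  fold <- .stratified_folds(labels, n_folds, seed)
  combos <- expand.grid(gamma = grid$gamma_values, C = grid$C_values)
  acc <- vapply(seq_len(nrow(combos)), function(r) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "radial", cost = combos$C[r],
                      gamma = combos$gamma[r], scale = FALSE)
      pred <- stats::predict(m, Xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  # ties -> smallest C, then smallest gamma (combos are ordered that way
  # within C blocks; order by C then gamma for the tie scan)
  ord <- order(combos$C, combos$gamma)
  best <- ord[which.max(acc[ord])]
  model <- e1071::svm(Xs, y, type = "C-classification", kernel = "radial",
                      cost = combos$C[best], gamma = combos$gamma[best],
                      scale = FALSE)
  structure(list(model = model, C = combos$C[best], gamma = combos$gamma[best],
                 cv_accuracy = cbind(combos, accuracy = acc),
                 center = mu, scale = sdv),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat("svm_model: RBF, C =", x$C, ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Predict SGI scores with a trained SVM
#'
#' Raw decision values are mapped to \[0, 1\] by the logistic function (a
#' strictly monotone map, so ROC ordering is preserved); the hard label is
#' score >= 0.5, i.e. the sign of the decision value.
#'
#' @param model An `svm_model` from [train_grid()].
#' @param features Pair feature table or matrix with the training columns.
#' @return data.frame with `score` and `hard_label` (plus `from`/`to` when
#'   present in `features`).
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "svm_model"))
  X <- .feature_matrix(features)
  if (ncol(X) != length(model$center))
    stop("feature dimension mismatch: expected ", length(model$center),
         ", got ", ncol(X), call. = FALSE)
  Xs <- scale(X, center = model$center, scale = model$scale)
  pred <- stats::predict(model$model, Xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value toward the first label in the
  # "a/b" column name; flip so positive means class "1"
  pos_first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  d <- if (identical(pos_first, "1")) dv[, 1L] else -dv[, 1L]
  out <- data.frame(score = stats::plogis(d), hard_label = as.integer(d > 0))
  if (is.data.frame(features) && all(c("from", "to") %in% names(features)))
    out <- cbind(features[, c("from", "to")], out)
  out
}
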