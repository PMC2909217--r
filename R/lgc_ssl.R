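# Graph-based semi-supervised classification of gene pairs by label
# propagation with local and global consistency: a Gaussian affinity graph
# over the pair feature vectors, symmetric normalisation, and either the
# closed-form solve F* = (I - alpha S)^-1 Y or the equivalent iteration
# F(t+1) = alpha S F(t) + (1 - alpha) Y.

#' Configuration for the label-propagation classifier
#'
#' @param alpha Spreading coefficient in (0, 1); default 0.99 (neighbour
#'   information dominates the clamp to the initial labels).
#' @param sigma Gaussian affinity length scale; `"median"` (default) uses the
#'   median pairwise Euclidean distance of the standardized features.
#' @param tol Convergence threshold (max-norm of successive iterates, on the
#'   closed-form scale) for the iterative solver.
#' @param max_iter Iteration cap for the iterative solver.
#' @param solver `"closed_form"` (default) or `"iterative"`.
#' @return List of class `ssl_config`.
#' @export
ssl_config <- function(alpha = 0.99, sigma = "median", tol = 1e-9,
                       max_iter = 10000L, solver = c("closed_form", "iterative")) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.numeric(sigma)) stopifnot(sigma > 0)
  structure(list(alpha = alpha, sigma = sigma, tol = tol,
                 max_iter = as.integer(max_iter), solver = match.arg(solver)),
            class = "ssl_config")
}

#' Gaussian affinity matrix
#'
#' W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)) for i != j, with zero diagonal
#' (no self-reinforcement).
#'
#' @param points Numeric matrix, one row per point.
#' @param sigma Positive length scale.
#' @return Symmetric matrix with entries in \[0, 1\] and zero diagonal.
#' @export
affinity_matrix <- function(points, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  sq <- rowSums(points^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  W <- exp(-d2 / (2 * sigma^2))
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Symmetric normalisation S = D^{-1/2} W D^{-1/2}
#'
#' D is the diagonal of row sums of W. Zero-sum rows (isolated points) get an
#' epsilon self-degree so the normalisation is defined; this is logged.
#' All eigenvalues of S lie in \[-1, 1\].
#'
#' @param W Symmetric nonnegative affinity matrix.
#' @return Symmetric matrix S.
#' @export
normalize_affinity <- function(W) {
  d <- rowSums(W)
  zero <- d <= 0
  if (any(zero)) {
    message("normalize_affinity: ", sum(zero), " isolated point(s) given epsilon degree")
    d[zero] <- 1e-12
  }
  s <- 1 / sqrt(d)
  S <- W * outer(s, s)
  (S + t(S)) / 2
}

#' Build the one-hot label matrix
#'
#' @param labels Integer vector with entries 0 (non-SGI), 1 (SGI) or `NA`
#'   (unlabelled).
#' @return n x 2 matrix; labelled rows one-hot (columns non-SGI, SGI),
#'   unlabelled rows zero.
#' @export
label_matrix <- function(labels) {
  Y <- matrix(0, length(labels), 2L,
              dimnames = list(NULL, c("nonSGI", "SGI")))
  Y[which(labels == 0L), 1L] <- 1
  Y[which(labels == 1L), 2L] <- 1
  Y
}

#' Label propagation by fixed-point iteration
#'
#' Iterates F(t+1) = alpha S F(t) + (1 - alpha) Y from F(0) = Y until the
#' max-norm of successive iterates drops below `tol`. The fixed point of
#' this iteration is (1 - alpha) (I - alpha S)^-1 Y; the returned matrix is
#' rescaled by 1/(1 - alpha) so it lies on the same scale as
#' [propagate_closed_form()] (the scalar does not affect classification).
#'
#' @param S Normalised affinity matrix.
#' @param Y Label matrix from [label_matrix()].
#' @param alpha Spreading coefficient in (0, 1).
#' @param tol Convergence threshold, applied on the rescaled (closed-form)
#'   scale.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return Score matrix F with the same shape as Y.
#' @export
propagate_iterative <- function(S, Y, alpha, tol = 1e-9, max_iter = 10000L) {
  stopifnot(alpha > 0, alpha < 1)
  F0 <- Y
  for (t in seq_len(max_iter)) {
    F1 <- alpha * (S %*% F0) + (1 - alpha) * Y
    delta <- max(abs(F1 - F0)) / (1 - alpha)
    F0 <- F1
    if (delta < tol) return(F0 / (1 - alpha))
  }
  stop("propagation did not converge within ", max_iter,
       " iterations (last residual ", signif(delta, 3), ")", call. = FALSE)
}

#' Label propagation in closed form
#'
#' Solves (I - alpha S) F* = Y; valid for alpha in (0, 1) because the
#' eigenvalues of S lie in \[-1, 1\].
#'
#' @inheritParams propagate_iterative
#' @return Score matrix F*.
#' @export
propagate_closed_form <- function(S, Y, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  solve(diag(nrow(S)) - alpha * S, Y)
}

# z-score standardization over the full transductive set; constant columns
# are left at zero
.standardize <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  scale(X, center = mu, scale = sdv)
}

.median_sigma <- function(X) {
  n <- nrow(X)
  # deterministic thinning for large sets: evenly spaced rows
  idx <- if (n > 800L) unique(round(seq(1L, n, length.out = 800L))) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit-and-predict with the transductive label-propagation classifier
#'
#' Standardizes the feature columns (z-score over the full labelled +
#' unlabelled set), builds the Gaussian affinity graph, propagates the
#' partial labels and returns per-point soft SGI scores.
#'
#' @param features data.frame from [pair_features()] or a bare numeric
#'   matrix of feature vectors.
#' @param labels Integer vector (0/1/`NA`) aligned with the rows of
#'   `features`; at least one labelled example per class.
#' @param cfg An [ssl_config()].
#' @return data.frame with columns `score` (SGI propensity in \[0, 1\]) and
#'   `hard_label` (argmax class), plus `from`/`to` when present in
#'   `features`.
#' @export
fit_predict_ssl <- function(features, labels, cfg = ssl_config()) {
  X <- .feature_matrix(features)
  if (nrow(X) == 0L) stop("empty feature table", call. = FALSE)
  if (length(labels) != nrow(X)) stop("labels/features length mismatch", call. = FALSE)
  if (!all(stats::na.omit(labels) %in% c(0L, 1L)))
    stop("labels must be 0, 1 or NA", call. = FALSE)
  if (length(unique(stats::na.omit(labels))) < 2L)
    stop("need at least one labelled example per class", call. = FALSE)
  Xs <- .standardize(X)
  sigma <- if (identical(cfg$sigma, "median")) .median_sigma(Xs) else cfg$sigma
  W <- affinity_matrix(Xs, sigma)
  S <- normalize_affinity(W)
  Y <- label_matrix(labels)
  Fm <- if (cfg$solver == "closed_form") {
    propagate_closed_form(S, Y, cfg$alpha)
  } else {
    propagate_iterative(S, Y, cfg$alpha, cfg$tol, cfg$max_iter)
  }
  tot <- Fm[, 1L] + Fm[, 2L]
  score <- ifelse(tot == 0, 0.5, Fm[, 2L] / tot)
  out <- data.frame(score = pmin(pmax(score, 0), 1),
                    hard_label = as.integer(Fm[, 2L] > Fm[, 1L]))
  if (is.data.frame(features) && all(c("from", "to") %in% names(features)))
    out <- cbind(features[, c("from", "to")], out)
  out
}

# extract the numeric feature columns from a pair feature table
.feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(is.data.frame(features))
  keep <- intersect(pair_feature_names(), names(features))
  if (length(keep) == 0L)
    keep <- names(features)[vapply(features, is.numeric, logical(1)) &
                              names(features) != "label"]
  as.matrix(features[, keep, drop = FALSE])
}
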