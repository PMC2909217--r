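# Benchmarking protocol: balanced sampling of labelled pairs, n-fold
# cross-validation with per-fold negatives, ROC / sensitivity / specificity,
# and per-feature two-sample Kolmogorov-Smirnov analysis.

# run expr with a local seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Balanced sample of labelled pairs
#'
#' Draws exactly `n_pos` positive and `n_neg` negative pairs without
#' replacement, reproducibly under `seed`.
#'
#' @param labels Labelled pair data.frame (columns `from`, `to`, `label`).
#' @param n_pos,n_neg Requested counts per class.
#' @param seed Integer seed.
#' @return Subset of `labels` with exactly the requested class counts.
#' @export
sample_balanced <- function(labels, n_pos, n_neg, seed = 1L) {
  pos <- which(labels$label == 1L)
  neg <- which(labels$label == 0L)
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop("insufficient pairs: have ", length(pos), " positive / ",
         length(neg), " negative, requested ", n_pos, "/", n_neg, call. = FALSE)
  idx <- .with_seed(seed, c(sample(pos, n_pos), sample(neg, n_neg)))
  out <- labels[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validation fold plan with per-fold negatives
#'
#' The positive pairs are split into `n_folds` subsets of near-equal size
#' (sizes differ by at most one); an equal number of negatives is assigned
#' to each fold. Folds are disjoint and cover the sample.
#'
#' @param sample Labelled pair data.frame.
#' @param n_folds Number of folds (>= 2, <= positive count).
#' @param seed Integer seed.
#' @return Integer vector of fold indices aligned with the rows of `sample`.
#' @export
make_cv_folds <- function(sample, n_folds, seed = 1L) {
  n_folds <- as.integer(n_folds)
  pos <- which(sample$label == 1L)
  neg <- which(sample$label == 0L)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n_folds > length(pos)) stop("more folds than positive pairs", call. = FALSE)
  fold <- integer(nrow(sample))
  .with_seed(seed, {
    fold[pos[sample.int(length(pos))]] <- rep_len(seq_len(n_folds), length(pos))
    fold[neg[sample.int(length(neg))]] <- rep_len(seq_len(n_folds), length(neg))
  })
  fold
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct scores in decreasing order (tied
#' scores are grouped at one threshold) and integrates by the trapezoid
#' rule; the AUC then equals the Mann-Whitney concordance probability.
#'
#' @param scores Numeric scores (higher = more SGI-like).
#' @param truth 0/1 labels; both classes must be present.
#' @return List of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  if (P == 0L || N == 0L) stop("both classes required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tie block
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve: AUC =", format(x$auc, digits = 4), "over",
      length(x$thresholds) - 1L, "threshold(s)\n")
  invisible(x)
}

#' Sensitivity and specificity at a score threshold
#'
#' Scores at or above the threshold are predicted positive.
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP).
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(scores, truth, threshold) {
  truth <- as.integer(truth)
  pred <- scores >= threshold
  c(sensitivity = sum(pred & truth == 1L) / sum(truth == 1L),
    specificity = sum(!pred & truth == 0L) / sum(truth == 0L))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference of the two empirical CDFs;
#' the p-value evaluates the Kolmogorov series at Stephens' finite-sample
#' argument (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) D with effective sample size
#' ne = n1 n2 / (n1 + n2), which keeps the test calibrated down to moderate
#' sample sizes.
#'
#' @param a,b Non-empty numeric samples.
#' @return List of class `ks_result` with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  all_x <- sort(unique(c(a, b)))
  e1 <- stats::ecdf(a)(all_x)
  e2 <- stats::ecdf(b)(all_x)
  D <- max(abs(e1 - e2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- .kolmogorov_tail(lambda)
  structure(list(D = D, p_value = p), class = "ks_result")
}

# complementary CDF of the Kolmogorov distribution,
# Q(x) = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 x^2)
.kolmogorov_tail <- function(x) {
  if (x < 1e-8) return(1)
  k <- seq_len(100L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat("ks_result: D =", format(x$D, digits = 4),
      ", p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Per-feature KS comparison of SGI vs non-SGI pairs
#'
#' For each of the 18 topological features, compares the distribution over
#' positive pairs with the distribution over negative pairs by a two-sample
#' KS test.
#'
#' @param features Labelled pair feature table from [pair_features()].
#' @return data.frame with columns `property`, `summary` (`average` or
#'   `absolute_difference` for node-level properties, `pair` otherwise),
#'   `feature`, `D`, `p_value`.
#' @export
feature_distribution_report <- function(features) {
  stopifnot("label" %in% names(features))
  pos <- features$label == 1L
  if (!any(pos) || all(pos)) stop("both classes required", call. = FALSE)
  feats <- intersect(pair_feature_names(), names(features))
  rows <- lapply(feats, function(f) {
    ks <- ks_two_sample(features[[f]][pos], features[[f]][!pos])
    prop <- sub("_(mean|absdiff)$", "", f)
    summ <- if (grepl("_mean$", f)) "average"
            else if (grepl("_absdiff$", f)) "absolute_difference"
            else "pair"
    data.frame(property = prop, summary = summ, feature = f,
               D = ks$D, p_value = ks$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# map a training fraction to the fold scheme: 0.8 -> 5-fold, 0.5 -> 2-fold,
# 0.2 -> 5-fold with train/test roles inverted
.fold_scheme <- function(fraction) {
  if (fraction >= 0.5) list(n_folds = max(2L, round(1 / (1 - fraction))), invert = FALSE)
  else list(n_folds = max(2L, round(1 / fraction)), invert = TRUE)
}

#' Compare the semi-supervised and SVM classifiers under cross-validation
#'
#' For each training fraction and each repetition (one master seed per
#' repetition), builds a fold plan, trains both classifiers and scores the
#' held-out pairs fold by fold. The label-propagation classifier is
#' transductive: it sees the feature vectors of the test pairs (unlabelled)
#' during propagation. Reported AUC is the mean over folds; sensitivity is
#' read from the pooled held-out scores at 90% specificity. ROC curves are
#' averaged vertically (mean TPR on a fixed FPR grid).
#'
#' @param features Labelled pair feature table.
#' @param train_fractions Training fractions, default `c(0.8, 0.5, 0.2)`.
#' @param seeds Master seeds, one repetition each; default `1:5`.
#' @param ssl An [ssl_config()].
#' @param grid An [svm_grid()].
#' @param methods Which classifiers to run, subset of `c("ssl", "svm")`.
#' @param fpr_grid FPR grid for vertical ROC averaging.
#' @return List of class `comparison_result`: `summary` data.frame (method,
#'   train_fraction, repetition, auc, sensitivity_at_spec90) and
#'   `mean_roc` data.frame of vertically averaged curves.
#' @export
run_comparison <- function(features,
                           train_fractions = c(0.8, 0.5, 0.2),
                           seeds = 1:5,
                           ssl = ssl_config(),
                           grid = svm_grid(),
                           methods = c("ssl", "svm"),
                           fpr_grid = seq(0, 1, by = 0.02)) {
  stopifnot("label" %in% names(features))
  methods <- match.arg(methods, several.ok = TRUE)
  summary_rows <- list()
  roc_rows <- list()
  for (fr in train_fractions) {
    sch <- .fold_scheme(fr)
    for (r in seq_along(seeds)) {
      fold <- make_cv_folds(features, sch$n_folds, seed = seeds[r])
      pooled <- list(ssl = list(), svm = list())
      aucs <- list(ssl = numeric(0), svm = numeric(0))
      for (f in seq_len(sch$n_folds)) {
        test_idx <- if (sch$invert) which(fold != f) else which(fold == f)
        train_idx <- setdiff(seq_len(nrow(features)), test_idx)
        truth <- features$label[test_idx]
        if (length(unique(truth)) < 2L) next
        if ("ssl" %in% methods) {
          lab <- rep(NA_integer_, nrow(features))
          lab[train_idx] <- features$label[train_idx]
          sc <- fit_predict_ssl(features, lab, ssl)$score[test_idx]
          aucs$ssl <- c(aucs$ssl, roc_curve(sc, truth)$auc)
          pooled$ssl[[f]] <- data.frame(score = sc, truth = truth)
        }
        if ("svm" %in% methods) {
          model <- train_grid(features[train_idx, , drop = FALSE],
                              grid = grid, seed = seeds[r] * 131L + f)
          sc <- predict_scores(model, features[test_idx, , drop = FALSE])$score
          aucs$svm <- c(aucs$svm, roc_curve(sc, truth)$auc)
          pooled$svm[[f]] <- data.frame(score = sc, truth = truth)
        }
      }
      for (m in methods) {
        pool <- do.call(rbind, pooled[[m]])
        roc <- roc_curve(pool$score, pool$truth)
        # sensitivity at >= 90% specificity (FPR <= 0.1)
        sens90 <- max(c(0, roc$tpr[roc$fpr <= 0.1]))
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          method = m, train_fraction = fr, repetition = r,
          auc = mean(aucs[[m]]), pooled_auc = roc$auc,
          sensitivity_at_spec90 = sens90, stringsAsFactors = FALSE)
        roc_rows[[length(roc_rows) + 1L]] <- data.frame(
          method = m, train_fraction = fr, repetition = r, fpr = fpr_grid,
          tpr = vapply(fpr_grid, function(x) max(c(0, roc$tpr[roc$fpr <= x])),
                       numeric(1)), stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  roc_all <- do.call(rbind, roc_rows)
  mean_roc <- stats::aggregate(tpr ~ method + train_fraction + fpr,
                               data = roc_all, FUN = mean)
  structure(list(summary = summary, mean_roc = mean_roc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  agg <- stats::aggregate(auc ~ method + train_fraction, data = x$summary, FUN = mean)
  cat("comparison_result (mean AUC over repetitions):\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
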