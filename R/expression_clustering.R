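# Divisive correlation clustering of expression profiles.
#
# Genes are split recursively until no pair of genes inside any cluster is
# negatively correlated; edge weights of the functional gene network are
# later derived from the resulting cluster centroids.

#' Impute missing expression values by condition means
#'
#' Each missing entry is replaced by the mean of the observed values in its
#' condition (column). Observed entries are untouched.
#'
#' @param matrix Numeric genes x conditions matrix, possibly with `NA`s.
#' @return The matrix with no missing entries.
#' @export
impute_missing <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (!anyNA(matrix)) return(matrix)
  obs_n <- colSums(!is.na(matrix))
  if (any(obs_n == 0L))
    stop("column(s) with no observed values: ",
         paste(colnames(matrix)[obs_n == 0L], collapse = ", "), call. = FALSE)
  cm <- colMeans(matrix, na.rm = TRUE)
  idx <- which(is.na(matrix), arr.ind = TRUE)
  matrix[idx] <- cm[idx[, 2L]]
  matrix
}

#' Pearson correlation of two expression profiles
#'
#' @param x,y Numeric vectors of equal length (>= 2), both non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length", call. = FALSE)
  if (length(x) < 2L) stop("profiles need at least two conditions", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant profile", call. = FALSE)
  stats::cor(x, y)
}

# correlation matrix over rows; constant rows yield NA rows/cols
.row_cor <- function(matrix) {
  suppressWarnings(stats::cor(t(matrix)))
}

# lexicographically smallest unordered pair among candidate index pairs
.lex_min_pair <- function(ids, pairs) {
  keys <- apply(pairs, 1L, function(p) paste(sort(ids[p]), collapse = "\r"))
  pairs[order(keys)[1L], ]
}

#' Split a cluster on its most negatively correlated gene pair
#'
#' The two genes with the most negative correlation seed the two child
#' clusters; every other member joins the seed with which it is more
#' positively correlated (ties go to the lexicographically smaller seed id).
#'
#' @param members Character vector of gene identifiers (cluster members).
#' @param matrix Imputed expression matrix containing those genes as rows.
#' @return List of two character vectors partitioning `members`.
#' @export
split_cluster <- function(members, matrix) {
  stopifnot(all(members %in% rownames(matrix)))
  R <- .row_cor(matrix[members, , drop = FALSE])
  neg <- which(R < 0 & upper.tri(R), arr.ind = TRUE)
  if (nrow(neg) == 0L) stop("no negatively correlated pair; nothing to split", call. = FALSE)
  vals <- R[neg]
  cand <- neg[vals == min(vals), , drop = FALSE]
  seed <- .lex_min_pair(members, cand)
  # order the two seeds so ties favour the lexicographically smaller id
  si <- members[seed[1L]]; sj <- members[seed[2L]]
  if (si > sj) { tmp <- si; si <- sj; sj <- tmp }
  left <- si; right <- sj
  for (g in setdiff(members, c(si, sj))) {
    if (R[g, si] >= R[g, sj]) left <- c(left, g) else right <- c(right, g)
  }
  list(sort(left), sort(right))
}

#' Divisive correlation clustering
#'
#' Starting from one cluster holding all genes, repeatedly selects the
#' cluster containing the globally most negative within-cluster correlation
#' and splits it with [split_cluster()], until every within-cluster pair has
#' non-negative correlation. Constant-expression genes (undefined
#' correlation) are placed in their own singleton clusters up front with a
#' warning. Deterministic: all ties are broken by gene identifier order.
#'
#' @param matrix Imputed (complete) expression matrix.
#' @return Object of class `cluster_partition`: list with `assignment`
#'   (named integer vector gene -> cluster), `clusters` (list of member
#'   vectors) and `centroids` (cluster x condition matrix).
#' @export
divisive_cluster <- function(matrix) {
  stopifnot(is.matrix(matrix), !anyNA(matrix))
  genes <- rownames(matrix)
  const <- genes[apply(matrix, 1L, function(r) stats::sd(r) == 0)]
  if (length(const) > 0L)
    warning("constant-expression gene(s) placed in singleton clusters: ",
            paste(const, collapse = ", "))
  active <- sort(setdiff(genes, const))
  clusters <- list()
  if (length(active) > 0L) {
    R <- .row_cor(matrix[active, , drop = FALSE])
    work <- list(active)
    done <- list()
    while (length(work) > 0L) {
      # most negative within-cluster correlation per working cluster
      mins <- vapply(work, function(m) {
        if (length(m) < 2L) return(0)
        sub <- R[m, m]
        min(sub[upper.tri(sub)])
      }, numeric(1))
      if (all(mins >= 0)) { done <- c(done, work); break }
      # split the cluster with the smallest (most negative) minimum;
      # ties -> smallest member gene id (members are kept sorted)
      neg_idx <- which(mins < 0)
      best <- min(mins[neg_idx])
      cand <- neg_idx[mins[neg_idx] == best]
      if (length(cand) > 1L) {
        firsts <- vapply(work[cand], `[[`, character(1), 1L)
        cand <- cand[order(firsts)[1L]]
      } else cand <- cand[1L]
      halves <- split_cluster(work[[cand]], matrix)
      settled <- vapply(work, function(m) {
        if (length(m) < 2L) return(TRUE)
        sub <- R[m, m]
        min(sub[upper.tri(sub)]) >= 0
      }, logical(1))
      settled[cand] <- FALSE
      done <- c(done, work[settled & seq_along(work) != cand])
      work <- c(work[!settled & seq_along(work) != cand], halves)
    }
    clusters <- done
  }
  clusters <- c(clusters, as.list(const))
  # deterministic cluster numbering: by smallest member id
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[[`, character(1), 1L))]
  assignment <- integer(0)
  for (k in seq_along(clusters))
    assignment[clusters[[k]]] <- k
  assignment <- assignment[genes]
  names(assignment) <- genes
  part <- structure(list(assignment = assignment, clusters = clusters,
                         centroids = NULL),
                    class = "cluster_partition")
  part$centroids <- centroids(part, matrix)
  part
}

#' Cluster centroids
#'
#' The centroid of a cluster is the coordinate-wise mean of its members'
#' expression profiles.
#'
#' @param partition A `cluster_partition`.
#' @param matrix Expression matrix covering all assigned genes.
#' @return Numeric matrix, one row per cluster.
#' @export
centroids <- function(partition, matrix) {
  stopifnot(inherits(partition, "cluster_partition"))
  miss <- setdiff(names(partition$assignment), rownames(matrix))
  if (length(miss) > 0L)
    stop("genes missing from matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  cent <- t(vapply(partition$clusters, function(m)
    colMeans(matrix[m, , drop = FALSE]), numeric(ncol(matrix))))
  if (ncol(matrix) == 1L) cent <- matrix(cent, ncol = 1L)
  rownames(cent) <- seq_len(nrow(cent))
  colnames(cent) <- colnames(matrix)
  cent
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition:", length(x$clusters), "cluster(s),",
      length(x$assignment), "gene(s)\n")
  invisible(x)
}
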