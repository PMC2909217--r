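# Independent brute-force oracles for graph properties, used to verify the
# package implementations on small graphs: exhaustive simple-path
# enumeration for geodesics, dense matrix formulas for spectral and
# current-flow quantities. Deliberately naive and separate from the package
# code paths.

# random connected weighted graph on n nodes (weights in (0,1])
random_connected_net <- function(n, seed, p = 0.5) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    sel <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(sel)) < p
    # always include a random spanning tree so the graph is connected
    perm <- sample(n)
    tree <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), integer(1))])
    idx <- unique(rbind(sel[keep, , drop = FALSE], tree))
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    a <- pmin(idx[, 1], idx[, 2]); b <- pmax(idx[, 1], idx[, 2])
    dup <- duplicated(paste(a, b))
    a <- a[!dup]; b <- b[!dup]
    w <- runif(length(a), 0.05, 1)
    edges <- data.frame(from = nodes[a], to = nodes[b], weight = w,
                        stringsAsFactors = FALSE)
    net <- gene_network(nodes, edges)
    if (igraph::is_connected(as_igraph(net))) return(net)
  }
}

# all simple paths between s and t as lists of node indices
all_simple_paths_idx <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  rec <- function(v, visited, path) {
    if (v == t) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    for (u in which(A[v, ] > 0)) if (!visited[u]) {
      visited[u] <- TRUE
      rec(u, visited, c(path, u))
      visited[u] <- FALSE
    }
  }
  visited <- rep(FALSE, n); visited[s] <- TRUE
  rec(s, visited, s)
  paths
}

path_cost <- function(path, Cmat) {
  sum(Cmat[cbind(path[-length(path)], path[-1])])
}

# exhaustive geodesic structure of a weighted graph: per pair, minimum cost,
# geodesic count (costs equal within relative tolerance) and per-node
# through counts
oracle_geodesics <- function(net, weighted = TRUE, tol = 1e-9) {
  A <- sgipred:::.adjacency(net, weighted = weighted)
  Cmat <- ifelse(A > 0, 1 / A, Inf)
  n <- nrow(A)
  mincost <- matrix(Inf, n, n); diag(mincost) <- 0
  gcount <- matrix(0, n, n)
  through <- array(0, c(n, n, n))  # [j, k, v]
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    paths <- all_simple_paths_idx(A, j, k)
    if (length(paths) == 0L) next
    costs <- vapply(paths, path_cost, numeric(1), Cmat = Cmat)
    m <- min(costs)
    geo <- paths[costs <= m * (1 + tol) + tol]
    mincost[j, k] <- mincost[k, j] <- m
    gcount[j, k] <- gcount[k, j] <- length(geo)
    for (p in geo) for (v in setdiff(p, c(j, k)))
      through[j, k, v] <- through[j, k, v] + 1
  }
  list(mincost = mincost, gcount = gcount, through = through)
}

oracle_betweenness <- function(net, tol = 1e-9) {
  geo <- oracle_geodesics(net, weighted = TRUE, tol = tol)
  n <- length(net$nodes)
  b <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (v %in% c(j, k) || geo$gcount[j, k] == 0) next
      acc <- acc + geo$through[j, k, v] / geo$gcount[j, k]
    }
    b[v] <- acc / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(b, net$nodes)
}

oracle_stress <- function(net) {
  geo <- oracle_geodesics(net, weighted = FALSE)
  n <- length(net$nodes)
  stats::setNames(vapply(seq_len(n), function(v) {
    acc <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n)
      if (!v %in% c(j, k)) acc <- acc + geo$through[j, k, v]
    acc
  }, numeric(1)), net$nodes)
}

oracle_closeness <- function(net) {
  geo <- oracle_geodesics(net, weighted = TRUE)
  n <- length(net$nodes)
  stats::setNames(vapply(seq_len(n), function(v) {
    d <- geo$mincost[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1)), net$nodes)
}

oracle_barrat_clustering <- function(net) {
  A <- sgipred:::.adjacency(net)
  n <- nrow(A)
  stats::setNames(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- sum(A[i, ])
    acc <- 0
    for (j in nb) for (h in nb) if (j != h && A[j, h] > 0)
      acc <- acc + (A[i, j] + A[i, h]) / 2   # ordered neighbour pairs
    acc / (s * (k - 1))
  }, numeric(1)), net$nodes)
}

oracle_eigenvector <- function(net, iters = 20000) {
  A <- sgipred:::.adjacency(net)
  # shift so the dominant eigenvalue is unique and positive even on
  # bipartite graphs (eigenvectors are unchanged)
  B <- A + diag(1 + max(rowSums(A)), nrow(A))
  x <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    x1 <- B %*% x
    x1 <- x1 / sqrt(sum(x1^2))
    if (max(abs(x1 - x)) < 1e-14) break
    x <- as.vector(x1)
  }
  stats::setNames(as.vector(abs(x)), net$nodes)
}

# Stephenson-Zelen information centrality via Laplacian pseudo-inverse
# (effective resistances), an independent route from the package's
# (L + J)^{-1} computation
oracle_information <- function(net) {
  A <- sgipred:::.adjacency(net, weighted = FALSE)
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  G <- MASS::ginv(L)
  R <- outer(diag(G), diag(G), `+`) - 2 * G
  stats::setNames(n / rowSums(R), net$nodes)
}

# current-flow betweenness by solving one linear system per source-sink pair
oracle_flow_betweenness <- function(net) {
  A <- sgipred:::.adjacency(net, weighted = FALSE)
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  acc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    p <- numeric(n)
    keep <- setdiff(seq_len(n), t)
    rhs <- numeric(n - 1); rhs[match(s, keep)] <- 1
    p[keep] <- solve(L[keep, keep], rhs)
    cur <- vapply(seq_len(n), function(i) 0.5 * sum(A[i, ] * abs(p[i] - p)), numeric(1))
    cur[c(s, t)] <- 0
    acc <- acc + cur
  }
  stats::setNames(acc / ((n - 1) * (n - 2) / 2), net$nodes)
}

oracle_mutual_neighbors <- function(net, i, j) {
  A <- sgipred:::.adjacency(net, weighted = FALSE)
  sum(A[i, ] > 0 & A[j, ] > 0 & seq_len(nrow(A)) != match(i, net$nodes) &
        seq_len(nrow(A)) != match(j, net$nodes))
}

# AUC as exhaustive Mann-Whitney concordance (ties credited 1/2)
oracle_auc_concordance <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# small deterministic test networks
path_net <- function(w = c(1, 1)) {
  gene_network(c("A", "B", "C"),
               data.frame(from = c("A", "B"), to = c("B", "C"), weight = w))
}
triangle_net <- function(w = c(1, 1, 1)) {
  gene_network(c("A", "B", "C"),
               data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"), weight = w))
}
star_net <- function(leaves = 4) {
  lv <- LETTERS[seq_len(leaves) + 1]
  gene_network(c("A", lv),
               data.frame(from = rep("A", leaves), to = lv, weight = rep(1, leaves)))
}
cycle_net <- function(n = 4) {
  v <- LETTERS[seq_len(n)]
  gene_network(v, data.frame(from = v, to = v[c(2:n, 1)], weight = rep(1, n)))
}
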