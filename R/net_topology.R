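# Topological node and pair properties of the functional gene network.
#
# Six properties are computed on the weighted graph (strength, clustering
# coefficient, betweenness, closeness, eigenvector centrality, shortest-path
# length) and four on the binary view (stress centrality, information
# centrality, current-flow betweenness, mutual neighbours). Geodesics on the
# weighted graph use edge costs 1/weight, so strong functional coupling
# means short distance.

.check_node <- function(net, v) {
  if (!all(v %in% net$nodes)) stop("unknown node: ",
                                   paste(setdiff(v, net$nodes), collapse = ", "),
                                   call. = FALSE)
}

#' Node strength (weighted degree)
#'
#' Sum of the weights of a node's incident edges; equals the binary degree
#' when all weights are 1.
#'
#' @param net A `gene_network`.
#' @param v Node identifier(s); default all nodes.
#' @return Named numeric vector.
#' @export
strength <- function(net, v = NULL) {
  A <- .adjacency(net)
  s <- rowSums(A)
  if (is.null(v)) return(s)
  .check_node(net, v)
  s[v]
}

#' Weighted clustering coefficient (Barrat)
#'
#' For node i with strength s_i and degree k_i,
#' C_w(i) = 1/(s_i (k_i - 1)) * sum over connected neighbour pairs (j, h) of
#' (w_ij + w_ih)/2. Nodes of degree < 2 get 0. Reduces to the binary
#' clustering coefficient when all weights are 1.
#'
#' @inheritParams strength
#' @return Named numeric vector in \[0, 1\].
#' @export
weighted_clustering <- function(net, v = NULL) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  names(cc) <- net$nodes
  cc[!is.finite(cc)] <- 0
  if (is.null(v)) return(cc)
  .check_node(net, v)
  cc[v]
}

#' Weighted shortest-path cost matrix
#'
#' Dijkstra distances with edge cost 1/weight, so high-confidence edges are
#' short. Unreachable pairs are `Inf`; [pair_features()] substitutes the
#' configurable sentinel.
#'
#' @param net A `gene_network` with strictly positive weights.
#' @return Symmetric numeric matrix of pairwise costs.
#' @export
shortest_path_costs <- function(net) {
  if (nrow(net$edges) > 0L && any(net$edges$weight <= 0))
    stop("nonpositive edge weight", call. = FALSE)
  g <- as_igraph(net)
  costs <- if (nrow(net$edges) > 0L) 1 / igraph::E(g)$weight else numeric(0)
  d <- igraph::distances(g, weights = costs, algorithm = "dijkstra")
  d[net$nodes, net$nodes, drop = FALSE]
}

#' Weighted closeness centrality
#'
#' Inverse of the average geodesic cost from a node to the other nodes it
#' can reach: closeness(v) = n_reach / sum of costs to reachable nodes.
#' Isolated nodes get 0.
#'
#' @inheritParams strength
#' @param dist Optional precomputed matrix from [shortest_path_costs()].
#' @return Named numeric vector.
#' @export
weighted_closeness <- function(net, v = NULL, dist = NULL) {
  if (is.null(dist)) dist <- shortest_path_costs(net)
  cl <- vapply(seq_along(net$nodes), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  }, numeric(1))
  names(cl) <- net$nodes
  if (is.null(v)) return(cl)
  .check_node(net, v)
  cl[v]
}

#' Weighted betweenness centrality
#'
#' Fraction of weighted geodesics (cost 1/weight) passing through each node,
#' summed over unordered source-target pairs that exclude the node, and
#' normalised by (n-1)(n-2)/2 so values lie in \[0, 1\].
#'
#' @inheritParams strength
#' @return Named numeric vector in \[0, 1\].
#' @export
weighted_betweenness <- function(net, v = NULL) {
  n <- length(net$nodes)
  if (n < 3L) {
    b <- stats::setNames(rep(0, n), net$nodes)
  } else {
    g <- as_igraph(net)
    costs <- if (nrow(net$edges) > 0L) 1 / igraph::E(g)$weight else numeric(0)
    b <- igraph::betweenness(g, weights = costs, directed = FALSE)
    b <- b[net$nodes] / ((n - 1) * (n - 2) / 2)
  }
  if (is.null(v)) return(b)
  .check_node(net, v)
  b[v]
}

#' Eigenvector centrality of the weighted adjacency matrix
#'
#' Principal eigenvector of the weighted adjacency matrix, computed on the
#' largest connected component (nodes elsewhere get 0), sign-fixed
#' nonnegative and scaled to unit Euclidean norm.
#'
#' @inheritParams strength
#' @return Named numeric vector, nonnegative, Euclidean norm 1.
#' @export
eigenvector_centrality <- function(net, v = NULL) {
  n <- length(net$nodes)
  if (n == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(as_igraph(net))
  sizes <- comp$csize
  big <- which(sizes == max(sizes))[1L]
  members <- net$nodes[comp$membership[net$nodes] == big]
  x <- stats::setNames(rep(0, n), net$nodes)
  if (length(members) == 1L) {
    x[members] <- 1
  } else {
    A <- .adjacency(net)[members, members]
    ev <- eigen(A, symmetric = TRUE)
    vec <- ev$vectors[, 1L]
    if (sum(vec) < 0) vec <- -vec
    vec[vec < 0] <- 0  # clip tiny negative round-off
    x[members] <- vec / sqrt(sum(vec^2))
  }
  if (is.null(v)) return(x)
  .check_node(net, v)
  x[v]
}

# hop distances and geodesic counts on the binary view.
# sigma_st = (A^d)_st where d is the hop distance (every minimal-length walk
# is a geodesic), so counts come from repeated adjacency squaring-free powers.
.binary_geodesics <- function(net) {
  A <- .adjacency(net, weighted = FALSE)
  g <- as_igraph(net, weighted = FALSE)
  D <- igraph::distances(g, weights = NA)[net$nodes, net$nodes, drop = FALSE]
  diam <- max(D[is.finite(D)], 0)
  n <- nrow(A)
  Sig <- matrix(0, n, n, dimnames = dimnames(A))
  P <- diag(n)
  for (k in seq_len(diam)) {
    P <- P %*% A
    sel <- which(D == k)
    Sig[sel] <- P[sel]
  }
  list(D = D, Sig = Sig)
}

#' Stress centrality (binary view)
#'
#' Number of shortest paths, over all unordered source-target pairs
#' excluding the node, that pass through the node on the unweighted graph.
#'
#' @inheritParams strength
#' @return Named integer-valued numeric vector.
#' @export
stress_centrality <- function(net, v = NULL) {
  n <- length(net$nodes)
  geo <- .binary_geodesics(net)
  D <- geo$D; Sig <- geo$Sig
  fin <- is.finite(D)
  st <- stats::setNames(numeric(n), net$nodes)
  for (i in seq_len(n)) {
    through <- outer(Sig[, i], Sig[i, ]) *
      (outer(D[, i], D[i, ], `+`) == D) * fin *
      is.finite(outer(D[, i], D[i, ], `+`))
    through[i, ] <- 0; through[, i] <- 0
    st[i] <- sum(through[upper.tri(through)])
  }
  if (is.null(v)) return(st)
  .check_node(net, v)
  st[v]
}

#' Information centrality (binary view)
#'
#' Stephenson-Zelen centrality: with C the inverse of (Laplacian + all-ones)
#' on a connected component of size m, the pairwise "resistance"
#' R_ij = C_ii + C_jj - 2 C_ij defines IC(i) = m / sum_j R_ij (the harmonic
#' aggregation over all paths). Computed per connected component; singleton
#' components get 0.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
information_centrality <- function(net, v = NULL) {
  comp <- igraph::components(as_igraph(net))
  ic <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  A <- .adjacency(net, weighted = FALSE)
  for (k in seq_len(comp$no)) {
    members <- net$nodes[comp$membership[net$nodes] == k]
    m <- length(members)
    if (m < 2L) { ic[members] <- 0; next }
    Ak <- A[members, members]
    L <- diag(rowSums(Ak)) - Ak
    C <- solve(L + matrix(1, m, m))
    Rsum <- m * diag(C) + sum(diag(C)) - 2 * rowSums(C)
    ic[members] <- m / Rsum
  }
  if (is.null(v)) return(ic)
  .check_node(net, v)
  ic[v]
}

#' Current-flow (random-walk) betweenness (binary view)
#'
#' Treats each unordered node pair as a unit current source/sink on the
#' unweighted graph and measures the current through every other node,
#' normalised by (m-1)(m-2)/2 within each connected component of size m
#' (Newman's flow betweenness). Values lie in \[0, 1\].
#'
#' @inheritParams strength
#' @return Named numeric vector in \[0, 1\].
#' @export
flow_betweenness <- function(net, v = NULL) {
  comp <- igraph::components(as_igraph(net))
  fb <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  A <- .adjacency(net, weighted = FALSE)
  for (k in seq_len(comp$no)) {
    members <- net$nodes[comp$membership[net$nodes] == k]
    m <- length(members)
    if (m < 3L) { fb[members] <- 0; next }
    Ak <- A[members, members]
    L <- diag(rowSums(Ak)) - Ak
    Tm <- solve(L + matrix(1 / m, m, m))
    # edge (u,w): x_s = T_us - T_ws; summed |x_s - x_t| over pairs excluding
    # the endpoint gives that endpoint's gross throughput from this edge
    eidx <- which(Ak > 0 & upper.tri(Ak), arr.ind = TRUE)
    acc <- numeric(m)
    for (e in seq_len(nrow(eidx))) {
      u <- eidx[e, 1L]; w <- eidx[e, 2L]
      x <- Tm[u, ] - Tm[w, ]
      xs <- sort(x)
      total <- sum(xs * (2 * seq_len(m) - m - 1))  # sum over pairs |x_s - x_t|
      acc[u] <- acc[u] + 0.5 * (total - sum(abs(x[u] - x)))
      acc[w] <- acc[w] + 0.5 * (total - sum(abs(x[w] - x)))
    }
    fb[members] <- acc / ((m - 1) * (m - 2) / 2)
  }
  if (is.null(v)) return(fb)
  .check_node(net, v)
  fb[v]
}

#' Mutual neighbour count
#'
#' Number of common neighbours of two distinct nodes on the binary view
#' (excluding the two nodes themselves).
#'
#' @param net A `gene_network`.
#' @param i,j Distinct node identifiers.
#' @return Nonnegative integer.
#' @export
mutual_neighbors <- function(net, i, j) {
  if (identical(i, j)) stop("mutual_neighbors requires two distinct nodes", call. = FALSE)
  .check_node(net, c(i, j))
  A <- .adjacency(net, weighted = FALSE)
  ni <- net$nodes[A[i, ] > 0]
  nj <- net$nodes[A[j, ] > 0]
  length(setdiff(intersect(ni, nj), c(i, j)))
}

#' All eight node properties
#'
#' @param net A `gene_network`.
#' @return data.frame with one row per node and columns `node`, `strength`,
#'   `clustering`, `betweenness`, `closeness`, `eigenvector`, `stress`,
#'   `information`, `flow`.
#' @export
node_properties <- function(net) {
  dist <- shortest_path_costs(net)
  data.frame(
    node = net$nodes,
    strength = as.numeric(strength(net)),
    clustering = as.numeric(weighted_clustering(net)),
    betweenness = as.numeric(weighted_betweenness(net)),
    closeness = as.numeric(weighted_closeness(net, dist = dist)),
    eigenvector = as.numeric(eigenvector_centrality(net)),
    stress = as.numeric(stress_centrality(net)),
    information = as.numeric(information_centrality(net)),
    flow = as.numeric(flow_betweenness(net)),
    stringsAsFactors = FALSE
  )
}

.node_property_names <- c("strength", "clustering", "betweenness", "closeness",
                          "eigenvector", "stress", "information", "flow")

#' Feature column names of the pair feature table
#' @return Character vector of the 18 feature names, in table order.
#' @export
pair_feature_names <- function() {
  c(as.vector(t(outer(.node_property_names, c("mean", "absdiff"), paste, sep = "_"))),
    "sp_length", "mutual_neighbors")
}

#' Topological feature vectors for gene pairs
#'
#' For each pair, the mean and absolute difference of the eight node
#' properties (16 features) plus the weighted shortest-path cost and the
#' mutual-neighbour count (2 features). Pairs with a gene absent from the
#' network are dropped with a message. Disconnected pairs get the sentinel
#' path length 2 x (maximum finite pairwise cost).
#'
#' @param net A `gene_network`.
#' @param pairs Two-column matrix/data.frame of gene pairs, or a labelled
#'   pair data.frame from [pair_labels()] (the `label` column is carried
#'   through).
#' @param sentinel Optional numeric override for the disconnected-pair
#'   path-length sentinel.
#' @return data.frame with columns `from`, `to`, the 18 features named by
#'   [pair_feature_names()], and `label` if supplied.
#' @export
pair_features <- function(net, pairs, sentinel = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  has_label <- "label" %in% names(pairs)
  from <- as.character(pairs[[1L]]); to <- as.character(pairs[[2L]])
  keep <- from %in% net$nodes & to %in% net$nodes
  if (any(!keep))
    message("pair_features: dropped ", sum(!keep), " pair(s) with genes absent from the network")
  from <- from[keep]; to <- to[keep]
  np <- node_properties(net)
  rownames(np) <- np$node
  dist <- shortest_path_costs(net)
  finite <- dist[is.finite(dist) & dist > 0]
  if (is.null(sentinel))
    sentinel <- if (length(finite) > 0L) 2 * max(finite) else 0
  Abin <- .adjacency(net, weighted = FALSE)
  common <- Abin %*% Abin  # common-neighbour counts incl. i,j adjacency
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  for (p in .node_property_names) {
    a <- np[from, p]; b <- np[to, p]
    out[[paste0(p, "_mean")]] <- (a + b) / 2
    out[[paste0(p, "_absdiff")]] <- abs(a - b)
  }
  d <- dist[cbind(from, to)]
  d[!is.finite(d)] <- sentinel
  out$sp_length <- d
  # A has zero diagonal, so two-step walks i->k->j never use k = i or k = j
  out$mutual_neighbors <- common[cbind(from, to)]
  if (has_label) out$label <- pairs$label[keep]
  out
}
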