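# Assembly of the weighted functional gene network (FGN): topology from the
# union of protein-protein interactions and expanded complexes, edge weights
# from expression profiles and cluster centroids.

#' Expand protein complexes into binary interactions
#'
#' A complex of n members contributes all n(n-1)/2 unordered member pairs;
#' the union over complexes is de-duplicated.
#'
#' @param complexes List of character vectors (complex memberships).
#' @return Two-column character matrix of unordered pairs.
#' @export
expand_complexes <- function(complexes) {
  pairs <- lapply(complexes, function(m) {
    m <- unique(m)
    if (length(m) < 2L) return(NULL)
    t(utils::combn(sort(m), 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(cbind(from = character(0), to = character(0)))
  .canonical_pairs(pairs[, 1L], pairs[, 2L])
}

#' Merge PPI and complex-derived pairs into an unweighted network skeleton
#'
#' @param ppi Two-column matrix of unordered pairs (see [read_edge_list()]).
#' @param complex_pairs Two-column matrix from [expand_complexes()].
#' @return A `gene_network` with unit placeholder weights and per-edge
#'   provenance (`ppi`, `complex` or `both`).
#' @export
merge_topology <- function(ppi, complex_pairs) {
  key <- function(m) if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L], sep = "\r")
  kp <- key(ppi); kc <- key(complex_pairs)
  all_keys <- union(kp, kc)
  if (length(all_keys) == 0L)
    return(gene_network(character(0),
                        data.frame(from = character(0), to = character(0),
                                   weight = numeric(0), provenance = character(0),
                                   stringsAsFactors = FALSE)))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  prov <- ifelse(all_keys %in% kp & all_keys %in% kc, "both",
                 ifelse(all_keys %in% kp, "ppi", "complex"))
  edges <- data.frame(from = parts[, 1L], to = parts[, 2L], weight = 1,
                      provenance = prov, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  gene_network(sort(unique(c(parts))), edges)
}

#' Construct a gene network object
#'
#' Undirected weighted graph over gene identifiers. Weights are
#' functional-coupling confidences in (0, 1].
#'
#' @param nodes Character vector of gene identifiers.
#' @param edges data.frame with columns `from`, `to`, `weight` and optionally
#'   `provenance`.
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(nodes, edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$weight <= 0 | edges$weight > 1))
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicate edges", call. = FALSE)
  if (is.null(edges$provenance)) edges$provenance <- rep("ppi", nrow(edges))
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "node(s),", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

#' Convert a gene network to an igraph graph
#'
#' @param net A `gene_network`.
#' @param weighted If `FALSE`, the binary view (all weights 1) is returned.
#' @return An undirected `igraph` graph with an edge `weight` attribute.
#' @export
as_igraph <- function(net, weighted = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$weight <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
  g
}

# dense weighted adjacency matrix, nodes in net$nodes order
.adjacency <- function(net, weighted = TRUE) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    w <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Weight configuration for the functional gene network
#'
#' @param L1 Tradeoff in \[0,1\] between the gene-to-centroid term and the
#'   centroid-to-centroid term of the edge-weight distance; default 0.3
#'   (the centroid separation dominates).
#' @param transform Map from distance to confidence: `"reciprocal"`
#'   (w = 1/(1+D), default) or `"exponential"` (w = exp(-D)).
#' @param fallback Weight for skeleton edges lacking an expression profile on
#'   either endpoint: `"median"` (median of the computed weights, default) or
#'   a numeric constant in (0, 1].
#' @return List of class `weight_config`.
#' @export
weight_config <- function(L1 = 0.3, transform = c("reciprocal", "exponential"),
                          fallback = "median") {
  stopifnot(L1 >= 0, L1 <= 1)
  transform <- match.arg(transform)
  if (is.numeric(fallback)) stopifnot(fallback > 0, fallback <= 1)
  structure(list(L1 = L1, transform = transform, fallback = fallback),
            class = "weight_config")
}

#' Edge weight from expression profiles and cluster centroids
#'
#' The functional-coupling distance of an edge (i, j) combines how far each
#' gene sits from its own cluster centroid with how far the two centroids
#' are from each other:
#' D = L1 (||xi - ci||^2 + ||xj - cj||^2) + (1 - L1) ||ci - cj||^2,
#' mapped to a confidence in (0, 1] by w = 1/(1 + D) (or exp(-D)).
#'
#' @param xi,xj Expression profiles of the two genes.
#' @param ci,cj Centroids of their clusters.
#' @param cfg A [weight_config()].
#' @return Weight in (0, 1]; 1 exactly when D = 0.
#' @export
edge_weight <- function(xi, xj, ci, cj, cfg = weight_config()) {
  len <- length(xi)
  if (any(c(length(xj), length(ci), length(cj)) != len))
    stop("profile/centroid length mismatch", call. = FALSE)
  D <- cfg$L1 * (sum((xi - ci)^2) + sum((xj - cj)^2)) +
    (1 - cfg$L1) * sum((ci - cj)^2)
  if (cfg$transform == "reciprocal") 1 / (1 + D) else exp(-D)
}

#' Build the weighted functional gene network
#'
#' Every skeleton edge whose two endpoints both have expression profiles is
#' weighted with [edge_weight()]; edges with an unprofiled endpoint receive
#' the fallback weight (logged via `message()`).
#'
#' @param skeleton Unweighted `gene_network` from [merge_topology()].
#' @param matrix Imputed expression matrix.
#' @param partition `cluster_partition` over the expression genes.
#' @param cfg A [weight_config()].
#' @return Weighted `gene_network`.
#' @export
build_fgn <- function(skeleton, matrix, partition, cfg = weight_config()) {
  stopifnot(inherits(skeleton, "gene_network"),
            inherits(partition, "cluster_partition"))
  edges <- skeleton$edges
  prof <- rownames(matrix)
  cent <- partition$centroids
  asg <- partition$assignment
  have <- edges$from %in% prof & edges$to %in% prof
  w <- rep(NA_real_, nrow(edges))
  for (e in which(have)) {
    i <- edges$from[e]; j <- edges$to[e]
    w[e] <- edge_weight(matrix[i, ], matrix[j, ],
                        cent[asg[[i]], ], cent[asg[[j]], ], cfg)
  }
  if (any(!have)) {
    fb <- if (is.numeric(cfg$fallback)) cfg$fallback
          else if (any(have)) stats::median(w[have]) else 0.5
    w[!have] <- fb
    message("build_fgn: ", sum(!have),
            " edge(s) without expression profiles given fallback weight ",
            signif(fb, 4))
  }
  edges$weight <- w
  gene_network(skeleton$nodes, edges)
}
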