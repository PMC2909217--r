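# Network assembly: complex expansion, topology merging, edge weighting.

test_that("complex expansion yields n(n-1)/2 pairs per complex, deduplicated", {
  expect_equal(nrow(expand_complexes(list(c("A", "B", "C", "D")))), 6L)
  expect_equal(nrow(expand_complexes(list("A"))), 0L)
  # overlapping complexes share the BC pair
  expect_equal(nrow(expand_complexes(list(c("A", "B", "C"), c("B", "C", "D")))), 5L)
  expect_equal(nrow(expand_complexes(list())), 0L)
})

test_that("topology merge unions edge sets and records provenance", {
  ppi <- cbind(from = "A", to = "B")
  cpx <- expand_complexes(list(c("B", "C")))
  net <- merge_topology(ppi, cpx)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$provenance, c("ppi", "complex"))

  both <- merge_topology(cbind(from = "A", to = "B"),
                         expand_complexes(list(c("A", "B"))))
  expect_equal(both$edges$provenance, "both")

  empty <- merge_topology(cbind(from = character(0), to = character(0)),
                          expand_complexes(list()))
  expect_length(empty$nodes, 0L)
})

test_that("gene_network validates weights, self-loops and duplicates", {
  expect_error(gene_network("A", data.frame(from = "A", to = "A", weight = 1)),
               "self-loops")
  expect_error(gene_network(c("A", "B"),
                            data.frame(from = "A", to = "B", weight = 1.5)),
               "weights")
  expect_error(gene_network(c("A", "B"),
                            data.frame(from = c("A", "B"), to = c("B", "A"),
                                       weight = c(0.5, 0.5))),
               "duplicate")
})

test_that("edge weight follows the centroid-distance form and its limits", {
  cfg <- weight_config(L1 = 0.3)
  x <- c(1, 2); c0 <- c(1, 2)
  expect_equal(edge_weight(x, x, c0, c0, cfg), 1.0)  # D = 0
  # ||xi-ci||^2 = 1, ||xj-cj||^2 = 1, ||ci-cj||^2 = 4
  # D = 0.3*2 + 0.7*4 = 3.4 -> w = 1/4.4 (independent arithmetic)
  w <- edge_weight(c(1, 0), c(3, 0), c(0, 0), c(2, 0), cfg)
  expect_equal(w, 1 / 4.4)
  # monotone decrease as centroid separation grows
  w2 <- edge_weight(c(1, 0), c(4, 0), c(0, 0), c(3, 0), cfg)
  expect_lt(w2, w)
  # exponential transform stays in (0, 1]
  we <- edge_weight(c(1, 0), c(3, 0), c(0, 0), c(2, 0),
                    weight_config(transform = "exponential"))
  expect_equal(we, exp(-3.4))
  expect_error(edge_weight(c(1, 2), c(1, 2, 3), c(0, 0), c(0, 0)), "mismatch")
})

test_that("build_fgn weights every profiled edge by the per-edge formula", {
  set.seed(21)
  genes <- sprintf("g%d", 1:6)
  m <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(genes, sprintf("c%d", 1:8)))
  part <- divisive_cluster(m)
  skel <- merge_topology(cbind(from = genes[c(1, 1, 2, 3, 4)],
                               to = genes[c(2, 3, 4, 5, 6)]),
                         expand_complexes(list(genes[4:6])))
  cfg <- weight_config()
  fgn <- build_fgn(skel, m, part, cfg)
  expect_equal(nrow(fgn$edges), nrow(skel$edges))
  for (e in seq_len(nrow(fgn$edges))) {
    i <- fgn$edges$from[e]; j <- fgn$edges$to[e]
    expect_equal(fgn$edges$weight[e],
                 edge_weight(m[i, ], m[j, ],
                             part$centroids[part$assignment[[i]], ],
                             part$centroids[part$assignment[[j]], ], cfg))
  }
  expect_true(all(fgn$edges$weight > 0 & fgn$edges$weight <= 1))
})

test_that("two same-cluster genes sitting at their shared centroid get weight 1", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
  # identical profiles: one cluster, centroid equals both rows
  part <- divisive_cluster(m)
  skel <- merge_topology(cbind(from = "A", to = "B"), expand_complexes(list()))
  fgn <- build_fgn(skel, m, part)
  expect_equal(fgn$edges$weight, 1.0)
})

test_that("edges lacking expression profiles get the fallback weight", {
  set.seed(4)
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"), sprintf("c%d", 1:4)))
  part <- divisive_cluster(m)
  skel <- merge_topology(cbind(from = c("A", "B", "A"), to = c("B", "C", "Z")),
                         expand_complexes(list()))
  expect_message(fgn <- build_fgn(skel, m, part), "fallback")
  wz <- fgn$edges$weight[fgn$edges$to == "Z" | fgn$edges$from == "Z"]
  profiled <- fgn$edges$weight[fgn$edges$to != "Z" & fgn$edges$from != "Z"]
  expect_equal(wz, median(profiled))
  # numeric override
  fgn2 <- suppressMessages(
    build_fgn(skel, m, part, weight_config(fallback = 0.25)))
  expect_equal(fgn2$edges$weight[fgn2$edges$to == "Z"], 0.25)
})

test_that("within-cluster edges never weigh less than between-cluster edges at equal centroid distances", {
  # two clusters; genes at fixed distance 1 from their centroid
  spec <- synthetic_spec(n_modules = 2, genes_per_module = 5, n_conditions = 10,
                         noise_sd = 0.2, archetypes = "anti_correlated",
                         missing_fraction = 0, seed = 8)
  m <- generate_expression(spec)
  part <- divisive_cluster(m)
  genes <- rownames(m)
  pairs <- t(combn(genes, 2))
  cfg <- weight_config()
  w <- apply(pairs, 1, function(p)
    edge_weight(m[p[1], ], m[p[2], ],
                part$centroids[part$assignment[[p[1]]], ],
                part$centroids[part$assignment[[p[2]]], ], cfg))
  same <- part$assignment[pairs[, 1]] == part$assignment[pairs[, 2]]
  expect_gt(min(w[same]), max(w[!same]))
})

test_that("build_fgn is invariant to node relabeling", {
  set.seed(31)
  genes <- sprintf("g%d", 1:5)
  m <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(genes, sprintf("c%d", 1:6)))
  part <- divisive_cluster(m)
  skel <- merge_topology(cbind(from = genes[c(1, 2, 3, 1)], to = genes[c(2, 3, 4, 5)]),
                         expand_complexes(list()))
  fgn <- build_fgn(skel, m, part)
  # relabel g -> h reversing the order
  relab <- setNames(sprintf("h%d", 5:1), genes)
  m2 <- m; rownames(m2) <- relab[rownames(m2)]
  part2 <- divisive_cluster(m2)
  skel2 <- merge_topology(cbind(from = relab[skel$edges$from],
                                to = relab[skel$edges$to]),
                          expand_complexes(list()))
  fgn2 <- build_fgn(skel2, m2, part2)
  key1 <- paste(pmin(relab[fgn$edges$from], relab[fgn$edges$to]),
                pmax(relab[fgn$edges$from], relab[fgn$edges$to]))
  key2 <- paste(fgn2$edges$from, fgn2$edges$to)
  expect_equal(fgn$edges$weight[order(key1)], fgn2$edges$weight[order(key2)])
})
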