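# Node and pair topology measures, checked against closed-form cases and
# the brute-force oracles on deterministic small graphs.

test_that("strength sums incident weights and reduces to degree at unit weights", {
  net <- gene_network(c("A", "B", "C", "D"),
                      data.frame(from = c("A", "A", "A"), to = c("B", "C", "D"),
                                 weight = c(0.2, 0.3, 0.5)))
  expect_equal(unname(strength(net, "A")), 1.0)
  iso <- gene_network(c("A", "B", "X"),
                      data.frame(from = "A", to = "B", weight = 1))
  expect_equal(unname(strength(iso, "X")), 0)
  expect_equal(unname(strength(star_net(4), "A")), 4)
  expect_error(strength(net, "Q"), "unknown node")
})

test_that("Barrat clustering coefficient handles triangles, paths and weighted cases", {
  expect_equal(unname(weighted_clustering(triangle_net(), "A")), 1.0)
  expect_equal(unname(weighted_clustering(path_net(), "B")), 0.0)
  # one weighted triangle plus a pendant edge, against the direct formula
  net <- gene_network(c("A", "B", "C", "D"),
                      data.frame(from = c("A", "A", "B", "C"),
                                 to = c("B", "C", "C", "D"),
                                 weight = c(0.5, 0.5, 1.0, 0.8)))
  expect_equal(weighted_clustering(net), oracle_barrat_clustering(net))
})

test_that("shortest-path costs invert weights so strong edges are short", {
  net <- gene_network(c("A", "B", "C"),
                      data.frame(from = c("A", "A", "C"), to = c("B", "C", "B"),
                                 weight = c(0.1, 0.9, 0.9)))
  d <- shortest_path_costs(net)
  expect_equal(d["A", "B"], 20 / 9)  # two strong hops beat one weak edge
  expect_equal(shortest_path_costs(path_net())["A", "C"], 2)
  disc <- gene_network(c("A", "B", "C"),
                       data.frame(from = "A", to = "B", weight = 1))
  expect_true(is.infinite(shortest_path_costs(disc)["A", "C"]))
})

test_that("closeness averages geodesic costs over reachable nodes", {
  expect_equal(unname(weighted_closeness(triangle_net(), "A")), 1.0)
  expect_equal(unname(weighted_closeness(path_net(), "A")), 2 / 3)  # (1+2)/2 inverted
  iso <- gene_network(c("A", "B", "X"),
                      data.frame(from = "A", to = "B", weight = 1))
  expect_equal(unname(weighted_closeness(iso, "X")), 0)
})

test_that("weighted betweenness is the normalised geodesic fraction", {
  b <- weighted_betweenness(path_net())
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  expect_equal(unname(weighted_betweenness(star_net(4), "A")), 1.0)
  # complete unit-weight graph: direct edges are unique geodesics
  cg <- gene_network(LETTERS[1:4],
                     data.frame(from = c("A", "A", "A", "B", "B", "C"),
                                to = c("B", "C", "D", "C", "D", "D"),
                                weight = rep(1, 6)))
  expect_equal(max(weighted_betweenness(cg)), 0)
})

test_that("eigenvector centrality is the unit-norm principal component", {
  x <- eigenvector_centrality(cg <- gene_network(LETTERS[1:4],
      data.frame(from = c("A", "A", "A", "B", "B", "C"),
                 to = c("B", "C", "D", "C", "D", "D"), weight = rep(1, 6))))
  expect_equal(unname(x), rep(0.5, 4))
  two <- gene_network(c("A", "B"), data.frame(from = "A", to = "B", weight = 0.42))
  expect_equal(unname(eigenvector_centrality(two)), rep(1 / sqrt(2), 2))
  # star K1,3: centre/leaf ratio sqrt(3), unit norm
  x3 <- eigenvector_centrality(star_net(3))
  expect_equal(unname(x3["A"] / x3["B"]), sqrt(3))
  expect_equal(sum(x3^2), 1)
  # disconnected: zeros off the largest component
  disc <- gene_network(c("A", "B", "C", "X", "Y"),
                       data.frame(from = c("A", "B", "X"), to = c("B", "C", "Y"),
                                  weight = rep(1, 3)))
  xd <- eigenvector_centrality(disc)
  expect_equal(unname(xd[c("X", "Y")]), c(0, 0))
  expect_error(eigenvector_centrality(gene_network(character(0),
    data.frame(from = character(0), to = character(0), weight = numeric(0)))),
    "empty")
})

test_that("stress centrality counts geodesics through a node on the binary view", {
  expect_equal(unname(stress_centrality(path_net(), "B")), 1)
  expect_equal(unname(stress_centrality(star_net(4), "B")), 0)
  expect_equal(unname(stress_centrality(cycle_net(4))), rep(1, 4))
  expect_equal(stress_centrality(star_net(4), "A"), c(A = 6))
})

test_that("information centrality matches the resistance-based oracle", {
  tri <- information_centrality(triangle_net())
  expect_equal(unname(tri), rep(unname(tri[1]), 3))
  p <- information_centrality(path_net())
  expect_gt(p[["B"]], p[["A"]])
  expect_equal(p, oracle_information(path_net()))
  # two disconnected edges: computed per component
  disc <- gene_network(c("A", "B", "X", "Y"),
                       data.frame(from = c("A", "X"), to = c("B", "Y"),
                                  weight = c(1, 1)))
  ic <- information_centrality(disc)
  expect_equal(unname(ic["A"]), unname(ic["X"]))
  single <- gene_network(c("A", "B", "Z"),
                         data.frame(from = "A", to = "B", weight = 1))
  expect_equal(unname(information_centrality(single, "Z")), 0)
})

test_that("current-flow betweenness routes unit currents through interior nodes", {
  fb <- flow_betweenness(path_net())
  expect_equal(unname(fb[c("A", "B", "C")]), c(0, 1, 0))
  cyc <- flow_betweenness(cycle_net(4))
  expect_equal(unname(cyc), rep(unname(cyc[1]), 4))
  expect_equal(cyc, oracle_flow_betweenness(cycle_net(4)))
})

test_that("mutual neighbour counts exclude the pair itself", {
  expect_equal(mutual_neighbors(triangle_net(), "A", "B"), 1L)
  k4 <- gene_network(LETTERS[1:4],
                     data.frame(from = c("A", "A", "A", "B", "B", "C"),
                                to = c("B", "C", "D", "C", "D", "D"),
                                weight = rep(1, 6)))
  expect_equal(mutual_neighbors(k4, "A", "B"), 2L)
  disjoint <- gene_network(c("A", "B", "C", "D"),
                           data.frame(from = c("A", "B"), to = c("C", "D"),
                                      weight = c(1, 1)))
  expect_equal(mutual_neighbors(disjoint, "A", "B"), 0L)
  expect_error(mutual_neighbors(triangle_net(), "A", "A"), "distinct")
})

test_that("pair feature vectors have 18 symmetric features matching the per-property oracles", {
  net <- random_connected_net(6, seed = 101)
  pairs <- rbind(c(net$nodes[1], net$nodes[4]),
                 c(net$nodes[2], net$nodes[5]),
                 c(net$nodes[3], net$nodes[6]))
  ft <- pair_features(net, pairs)
  expect_equal(setdiff(names(ft), c("from", "to")), pair_feature_names())
  expect_length(pair_feature_names(), 18L)
  # symmetry under gene swap
  ft_rev <- pair_features(net, pairs[, 2:1])
  expect_equal(as.matrix(ft[pair_feature_names()]),
               as.matrix(ft_rev[pair_feature_names()]))
  # values recompose from the single-property implementations
  np <- node_properties(net); rownames(np) <- np$node
  d <- shortest_path_costs(net)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_equal(ft$strength_mean[r], (np[i, "strength"] + np[j, "strength"]) / 2)
    expect_equal(ft$flow_absdiff[r], abs(np[i, "flow"] - np[j, "flow"]))
    expect_equal(ft$sp_length[r], d[i, j])
    expect_equal(ft$mutual_neighbors[r], mutual_neighbors(net, i, j))
  }
})

test_that("disconnected pairs receive the finite sentinel path length", {
  disc <- gene_network(c("A", "B", "C", "D"),
                       data.frame(from = c("A", "C"), to = c("B", "D"),
                                  weight = c(0.5, 1)))
  ft <- pair_features(disc, rbind(c("A", "B"), c("A", "C")))
  expect_equal(ft$sp_length[1], 2)          # 1/0.5
  expect_equal(ft$sp_length[2], 4)          # 2 x max finite cost
  expect_true(all(is.finite(as.matrix(ft[pair_feature_names()]))))
  ft2 <- pair_features(disc, rbind(c("A", "C")), sentinel = 99)
  expect_equal(ft2$sp_length, 99)
})

test_that("pairs with genes absent from the network are dropped with a message", {
  net <- path_net()
  expect_message(ft <- pair_features(net, rbind(c("A", "C"), c("A", "Z"))),
                 "dropped 1")
  expect_equal(nrow(ft), 1L)
})
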