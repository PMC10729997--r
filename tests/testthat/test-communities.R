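test_that("edge betweenness matches hand-enumerated shortest paths", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  eb <- edge_betweenness_gn(path3)
  expect_equal(eb$betweenness, c(2, 2))

  tri <- igraph::make_graph(~ a - b, a - c, b - c)
  expect_equal(edge_betweenness_gn(tri)$betweenness, c(1, 1, 1))

  star <- igraph::make_graph(~ hub - l1, hub - l2, hub - l3)
  expect_equal(edge_betweenness_gn(star)$betweenness, c(3, 3, 3))
})

test_that("edge betweenness equals exhaustive enumeration on random graphs", {
  set.seed(99)
  checked <- 0
  rep <- 0
  while (checked < 200) {
    rep <- rep + 1
    n <- sample(4:12, 1)
    g <- random_named_graph(n, runif(1, 0.2, 0.7), seed = 1000 + rep)
    if (igraph::ecount(g) == 0) next
    mine <- edge_betweenness_gn(g)
    oracle <- brute_force_edge_betweenness(g)
    key <- paste(mine$from, mine$to, sep = "|")
    expect_equal(mine$betweenness, unname(oracle[key]), tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 200)
})

test_that("modularity matches closed forms and stays in [-0.5, 1]", {
  tri2 <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f)
  one_group <- tibble::tibble(node = letters[1:6], group = 1)
  expect_equal(modularity_q(tri2, one_group), 0)
  split2 <- tibble::tibble(node = letters[1:6], group = rep(1:2, each = 3))
  expect_equal(modularity_q(tri2, split2), 0.5)

  bridged <- bridged_triangles()
  cut_at_bridge <- tibble::tibble(node = letters[1:6], group = rep(1:2, each = 3))
  expect_equal(modularity_q(bridged, cut_at_bridge), 5 / 14)

  # singleton-per-node partition of a clique is negative
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  singl <- tibble::tibble(node = letters[1:4], group = 1:4)
  expect_equal(modularity_q(k4, singl), -0.25)

  set.seed(55)
  for (rep in 1:30) {
    g <- random_named_graph(sample(4:10, 1), runif(1, 0.3, 0.9), seed = rep)
    if (igraph::ecount(g) == 0) next
    part <- tibble::tibble(node = igraph::V(g)$name,
                           group = sample(1:3, igraph::vcount(g), replace = TRUE))
    q <- modularity_q(g, part)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
    # cross-check against igraph's modularity
    expect_equal(q, igraph::modularity(g, part$group), tolerance = 1e-12)
  }
  expect_error(modularity_q(igraph::make_graph(NULL, n = 2) |>
                              igraph::set_vertex_attr("name", value = c("a", "b")),
                            tibble::tibble(node = c("a", "b"), group = 1)),
               "edgeless")
})

test_that("the bridge between two dense clusters is always cut first", {
  gn <- girvan_newman(bridged_triangles())
  expect_equal(gn$steps$removed_edge[2], "c -- d")
  # and the best partition is the two triangles, Q = 5/14
  bp <- best_partition(gn)
  expect_equal(attr(bp, "n_groups"), 2)
  expect_equal(attr(bp, "Q"), 5 / 14)
  expect_equal(bp$group[match(c("a", "b", "c"), bp$node)], rep(1, 3))
  expect_equal(bp$group[match(c("d", "e", "f"), bp$node)], rep(2, 3))

  # larger bridged cliques behave the same
  for (k in 4:5) {
    g1 <- igraph::make_full_graph(k)
    igraph::V(g1)$name <- sprintf("x%d", 1:k)
    g2 <- igraph::make_full_graph(k)
    igraph::V(g2)$name <- sprintf("y%d", 1:k)
    g <- igraph::disjoint_union(g1, g2)
    g <- igraph::add_edges(g, c(match("x1", igraph::V(g)$name),
                                match("y1", igraph::V(g)$name)))
    gn <- girvan_newman(g)
    expect_equal(gn$steps$removed_edge[2], "x1 -- y1")
  }
})

test_that("the removal sequence records components and original-graph Q", {
  # two disconnected triangles start as 2 components
  tri2 <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f)
  gn <- girvan_newman(tri2)
  expect_equal(gn$steps$n_components[1], 2)
  expect_equal(gn$steps$modularity[1], 0.5)
  expect_true(all(diff(gn$steps$n_components) >= 0))
  expect_equal(tail(gn$steps$n_components, 1), 6)

  # 4-cycle: after two removals, two components of two nodes
  c4 <- igraph::make_graph(~ a - b, b - c, c - d, a - d)
  gn4 <- girvan_newman(c4)
  memb <- gn4$membership[3, ]
  expect_equal(gn4$steps$n_components[3], 2)
  expect_equal(sort(as.vector(table(memb))), c(2, 2))

  # edgeless graph: single-step trivial partition
  g0 <- igraph::make_graph(NULL, n = 3)
  igraph::V(g0)$name <- c("a", "b", "c")
  gn0 <- girvan_newman(g0)
  expect_equal(nrow(gn0$steps), 1)
  expect_equal(gn0$steps$n_components, 3)
  bp0 <- best_partition(gn0)
  expect_equal(nrow(bp0), 3)
})

test_that("identical inputs give identical dendrograms", {
  g <- random_named_graph(10, 0.4, seed = 7)
  a <- girvan_newman(g)
  b <- girvan_newman(g)
  expect_identical(a$steps, b$steps)
  expect_identical(a$membership, b$membership)
})

test_that("best-partition selection maximizes Q with coarsest-earliest ties", {
  gn <- girvan_newman(bridged_triangles())
  q <- gn$steps$modularity
  expect_equal(attr(best_partition(gn), "Q"), max(q))
  # all-equal Q (a single edge): earliest, coarsest partition wins
  g1 <- igraph::make_graph(~ a - b)
  gn1 <- girvan_newman(g1)
  bp1 <- best_partition(gn1)
  expect_equal(attr(bp1, "step"), 0)
  expect_equal(attr(bp1, "n_groups"), 1)
})

test_that("fixed group counts cut the dendrogram at the earliest match", {
  gn <- girvan_newman(bridged_triangles())
  p2 <- partition_at(gn, 2)
  expect_equal(attr(p2, "n_groups"), 2)
  expect_equal(attr(p2, "step"), 1) # the bridge cut
  p6 <- partition_at(gn, 6)
  expect_equal(attr(p6, "n_groups"), 6)
  expect_error(partition_at(gn, 99), "No step")
})

test_that("partitions agree with an independent reference implementation", {
  set.seed(123)
  for (rep in 1:20) {
    sizes <- c(5, 5, 5)
    pm <- matrix(0.05, 3, 3)
    diag(pm) <- 0.9
    g <- igraph::sample_sbm(sum(sizes), pref.matrix = pm, block.sizes = sizes)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(sum(sizes)))
    if (igraph::ecount(g) < 2) next
    mine <- best_partition(girvan_newman(g))
    ref <- igraph::cluster_edge_betweenness(g, weights = NULL, modularity = TRUE)
    expect_equal(length(unique(mine$group)), length(unique(igraph::membership(ref))))
    expect_equal(pair_count_ari(mine$group, as.integer(igraph::membership(ref))), 1)
  }
})

test_that("tidy, glance and autoplot expose the fit", {
  gn <- girvan_newman(bridged_triangles())
  td <- tidy(gn)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "removed_edge", "n_components", "modularity"))
  gl <- glance(gn)
  expect_equal(gl$n_edges, 7)
  expect_equal(gl$best_modularity, 5 / 14)
  expect_s3_class(autoplot(gn), "ggplot")
})
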