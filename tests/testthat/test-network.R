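test_that("two-mode graphs keep isolates and bipartite purity", {
  m <- matrix(c(1, 0, 0, 3), 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  g <- build_two_mode(mni_from_matrix(m))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)

  zero <- matrix(0, 2, 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  g0 <- build_two_mode(mni_from_matrix(zero))
  expect_equal(igraph::vcount(g0), 4)
  expect_equal(igraph::ecount(g0), 0)

  # weighted rule: tie weight is percent MNI of the species in the context
  mw <- matrix(c(2, 8, 5, 0), 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  gw <- build_two_mode(mni_from_matrix(mw), tie_rule = "weight")
  ends <- igraph::as_edgelist(gw)
  w <- igraph::E(gw)$weight
  expect_equal(w[ends[, 1] == "t1" & ends[, 2] == "A"], 0.2)
  expect_equal(w[ends[, 1] == "t2" & ends[, 2] == "A"], 0.8)

  # every tie joins a species to a context, never within a class
  cls <- igraph::V(g)$node_class
  names(cls) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  expect_true(all(cls[el[, 1]] != cls[el[, 2]]))

  # Operation P invertebrate submatrix: species-side node count equals the
  # invertebrate taxa with at least one occurrence in levels 99-105
  mni <- pineland_mni()
  taxa <- pineland_taxa()
  ctx <- pineland_contexts()
  op <- intersect(names(mni), ctx$context_id[ctx$site_area == "operation_p"])
  sub <- mni[mni$taxon_id %in% taxa$taxon_id[taxa$class == "invertebrate"],
             c("taxon_id", op)]
  present <- rowSums(as.matrix(sub[-1])) >= 1
  gop <- build_two_mode(sub[present, ])
  expect_equal(sum(igraph::V(gop)$node_class == "species"), sum(present))
  expect_equal(sum(igraph::V(gop)$node_class == "context"), 4)
})

test_that("threshold semantics are strict where captions say greater-than", {
  m <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.33, 0.2, 0.33, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sim <- sim_from_matrix(m)
  expect_equal(igraph::ecount(threshold_graph(sim, 0.5)), 1)
  expect_equal(igraph::ecount(threshold_graph(sim, 1.0)), 0)
  # a value of exactly 0.33 is not a tie at a strict 0.33 cutoff...
  g33 <- threshold_graph(sim, 0.33)
  el <- apply(igraph::as_edgelist(g33), 1, paste, collapse = "-")
  expect_false("b-c" %in% el)
  # ...but is at an inclusive one
  g33i <- threshold_graph(sim, 0.33, strict = FALSE)
  expect_equal(igraph::ecount(g33i), 2)
  # isolates stay in the graph
  expect_equal(igraph::vcount(threshold_graph(sim, 0.95)), 3)
  expect_error(threshold_graph(sim, 1.5), "0, 1")
})

test_that("edge count is monotonically non-increasing in the threshold", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    v <- matrix(runif(n * n), n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    dimnames(v) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
    sim <- sim_from_matrix(v)
    counts <- sapply(seq(0, 1, by = 0.1), function(t) {
      igraph::ecount(threshold_graph(sim, t))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the connectivity-preserving threshold sits just before breakup", {
  m <- diag(1, 3)
  m[1, 2] <- m[2, 1] <- 0.8
  m[2, 3] <- m[3, 2] <- 0.6
  m[1, 3] <- m[3, 1] <- 0.1
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  sw <- max_connected_threshold(sim_from_matrix(m))
  expect_equal(sw$t_star, 0.6)

  all4 <- matrix(0.4, 4, 4)
  diag(all4) <- 1
  dimnames(all4) <- list(letters[1:4], letters[1:4])
  expect_equal(max_connected_threshold(sim_from_matrix(all4))$t_star, 0.4)

  # two pairs with zero cross-pair similarity: error, or largest component
  pairs <- diag(1, 4)
  pairs[1, 2] <- pairs[2, 1] <- 0.9
  pairs[3, 4] <- pairs[4, 3] <- 0.7
  dimnames(pairs) <- list(letters[1:4], letters[1:4])
  expect_error(max_connected_threshold(sim_from_matrix(pairs)), "not connected")
  expect_warning(
    sw2 <- max_connected_threshold(sim_from_matrix(pairs),
                                   on_disconnected = "largest_component"),
    "largest component")
  expect_equal(length(sw2$scope), 2)
})

test_that("graphs at t* are connected and break just above it", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    v <- matrix(runif(n * n, 0.05, 1), n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    dimnames(v) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
    sim <- sim_from_matrix(v)
    sw <- suppressWarnings(max_connected_threshold(sim))
    g_at <- threshold_graph(sim, sw$t_star, strict = FALSE)
    g_at <- igraph::induced_subgraph(g_at, sw$scope)
    expect_true(igraph::is_connected(g_at))
    above <- sw$sweep$candidate[sw$sweep$candidate > sw$t_star]
    if (length(above)) {
      g_up <- threshold_graph(sim, min(above), strict = FALSE)
      g_up <- igraph::induced_subgraph(g_up, sw$scope)
      expect_false(igraph::is_connected(g_up))
    }
  }
})

test_that("subgroup projection applies the inclusive five-percent rule", {
  # context X total 100: group g2 holds exactly 5, g3 holds 3
  m <- matrix(c(85, 7, 5, 3,
                10, 80, 5, 5), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), c("X", "Y")))
  part <- tibble::tibble(node = c("a", "b", "c", "d"),
                         group = c(1, 1, 2, 3))
  g <- project_subgroup_ties(mni_from_matrix(m), part)
  el <- igraph::as_edgelist(g)
  key <- paste(el[, 1], el[, 2])
  w <- setNames(igraph::E(g)$weight, key)
  expect_equal(unname(w["1 X"]), 0.92)      # 7% + 85% ties comfortably
  expect_equal(unname(w["2 X"]), 0.05)      # exactly 5%: "at least" includes
  expect_false("3 X" %in% key)              # 3% misses the cutoff
  # per-context weights over all groups sum to 1 when the cutoff is 0
  g0 <- project_subgroup_ties(mni_from_matrix(m), part, cutoff = 0)
  el0 <- igraph::as_edgelist(g0)
  w0 <- igraph::E(g0)$weight
  for (cn in c("X", "Y")) {
    expect_equal(sum(w0[el0[, 2] == cn | el0[, 1] == cn]), 1)
  }
  expect_error(project_subgroup_ties(mni_from_matrix(m), part[-1, ]),
               "does not cover")
})

test_that("graph export writes GraphML plus readable CSV twins", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 0, 0, 3), 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  g <- build_two_mode(mni_from_matrix(m))
  paths <- export_graph(g, file.path(dir, "g"))
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  edges <- readr::read_csv(paths["edges"], show_col_types = FALSE)
  expect_equal(nrow(edges), igraph::ecount(g))
})
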