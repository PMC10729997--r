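# Graph construction. Graphs are undirected igraph objects with a node_class
# vertex attribute (context / species / habitat / subgroup); bipartite graphs
# carry ties only between distinct classes, and no graph has self-loops.

zn_graph <- function(nodes, edges, directed = FALSE) {
  # nodes: tibble(name, node_class, ...attrs); edges: tibble(from, to, ...attrs)
  g <- igraph::graph_from_data_frame(edges, directed = directed, vertices = nodes)
  if (any(igraph::which_loop(g))) abort("Self-loops are not allowed.")
  if ("weight" %in% igraph::edge_attr_names(g) &&
      any(igraph::E(g)$weight <= 0, na.rm = TRUE)) {
    abort("Edge weights, when present, must be positive.")
  }
  g
}

#' Build a two-mode (bipartite) context-by-species graph
#'
#' One node per taxon and per context. Under the `"presence"` tie rule an
#' unweighted tie links a species to every context where its MNI is at least
#' 1; under the `"weight"` rule the same ties are weighted by the species'
#' percent MNI in that context. All taxa and contexts appear as nodes even if
#' isolated.
#'
#' @param mni MNI tibble.
#' @param tie_rule `"presence"` or `"weight"`.
#' @return An undirected bipartite igraph with vertex attributes `node_class`
#'   (`"context"` / `"species"`) and `type` (TRUE for contexts).
#' @export
#' @examples
#' g <- build_two_mode(pineland_mni())
#' igraph::vcount(g)
build_two_mode <- function(mni, tie_rule = c("presence", "weight")) {
  tie_rule <- match.arg(tie_rule)
  ctx <- setdiff(names(mni), "taxon_id")
  nodes <- bind_rows(
    tibble(name = mni$taxon_id, node_class = "species"),
    tibble(name = ctx, node_class = "context")
  )
  long <- mni |>
    pivot_longer(all_of(ctx), names_to = "context_id", values_to = "mni") |>
    filter(.data$mni >= 1)
  edges <- tibble(from = long$taxon_id, to = long$context_id)
  if (tie_rule == "weight") {
    prop <- suppressWarnings(percent_mni(mni))
    plong <- prop |>
      pivot_longer(all_of(ctx), names_to = "context_id", values_to = "p")
    edges$weight <- plong$p[match(paste(long$taxon_id, long$context_id),
                                  paste(plong$taxon_id, plong$context_id))]
  }
  g <- zn_graph(nodes, edges)
  igraph::V(g)$type <- igraph::V(g)$node_class == "context"
  g
}

#' Threshold a similarity table into a one-mode graph
#'
#' Draws a tie between two items when their similarity exceeds `t` (strict
#' inequality, the default reading of "greater than" cutoffs) or is at least
#' `t` when `strict = FALSE`. Every item stays in the graph, so isolates are
#' allowed.
#'
#' @param sim Similarity tibble (class `zn_similarity`).
#' @param t Threshold in `[0, 1]`.
#' @param strict Use `>` (TRUE, default) or `>=` (FALSE).
#' @param node_class Node class label for the items (default `"species"`).
#' @return Undirected igraph whose edges carry the similarity as `weight`.
#' @export
threshold_graph <- function(sim, t, strict = TRUE, node_class = "species") {
  if (t < 0 || t > 1) abort("Threshold must be in [0, 1].")
  items <- similarity_items(sim)
  keep <- if (strict) sim$similarity > t else sim$similarity >= t
  edges <- tibble(from = sim$item1[keep], to = sim$item2[keep],
                  weight = sim$similarity[keep])
  edges <- edges[edges$weight > 0, ] # a zero-similarity tie is no tie
  zn_graph(tibble(name = items, node_class = node_class), edges)
}

#' Largest threshold that keeps the graph connected
#'
#' Sweeps the distinct observed similarity values in decreasing order, adding
#' at each candidate `v` every tie with similarity `>= v`, and returns the
#' largest candidate at which the scoped items form a single connected
#' component: the graph "just before it is broken apart". Items with no
#' positive similarity to any other item can never connect and are excluded
#' from the scope with a warning.
#'
#' @param sim Similarity tibble.
#' @param on_disconnected What to do if the scoped items are disconnected even
#'   with every positive tie: `"error"` (default); `"largest_component"`,
#'   which re-scopes to the largest component and re-runs; or `"minimum"`,
#'   which returns the smallest positive similarity as the threshold (the
#'   densest positive-tie graph, whose components are then the natural
#'   communities).
#' @return A list of class `zn_threshold_sweep` with elements `t_star` (the
#'   selected threshold), `sweep` (tibble of candidate values and
#'   connectivity), `scope` (the item ids swept) and `excluded` (items dropped
#'   for having no positive similarity).
#' @export
max_connected_threshold <- function(sim, on_disconnected = c("error", "largest_component", "minimum")) {
  on_disconnected <- match.arg(on_disconnected)
  items <- similarity_items(sim)
  pos <- sim[sim$similarity > 0, ]
  connected_items <- unique(c(pos$item1, pos$item2))
  excluded <- setdiff(items, connected_items)
  if (length(excluded)) {
    warn(paste0("Excluding ", length(excluded),
                " item(s) with no positive similarity from the connectivity scope."))
  }
  scope <- items[items %in% connected_items]
  if (length(scope) < 2) abort("Fewer than two connectable items in scope.")

  run_sweep <- function(scope) {
    sub <- pos[pos$item1 %in% scope & pos$item2 %in% scope, ]
    cand <- sort(unique(sub$similarity), decreasing = TRUE)
    # incremental union-find while the threshold drops
    parent <- seq_along(scope)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    n_comp <- length(scope)
    i1 <- match(sub$item1, scope)
    i2 <- match(sub$item2, scope)
    ord <- order(sub$similarity, decreasing = TRUE)
    connected_at <- logical(length(cand))
    e <- 1
    for (k in seq_along(cand)) {
      while (e <= length(ord) && sub$similarity[ord[e]] >= cand[k]) {
        a <- find(i1[ord[e]]); b <- find(i2[ord[e]])
        if (a != b) {
          parent[a] <- b
          n_comp <- n_comp - 1
        }
        e <- e + 1
      }
      connected_at[k] <- n_comp == 1
    }
    list(cand = cand, connected_at = connected_at)
  }

  res <- run_sweep(scope)
  if (!any(res$connected_at)) {
    if (on_disconnected == "error") {
      abort("Scoped items are not connected even at the minimum positive similarity.")
    }
    if (on_disconnected == "minimum") {
      warn("Scoped items never connect; using the minimum positive similarity.")
      return(structure(
        list(t_star = min(res$cand),
             sweep = tibble(candidate = res$cand, connected = res$connected_at),
             scope = scope, excluded = excluded),
        class = "zn_threshold_sweep"))
    }
    g <- threshold_graph(sim, 0, strict = TRUE)
    g <- igraph::induced_subgraph(g, scope)
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    scope <- names(comp$membership)[comp$membership == big]
    warn(paste0("Re-scoping to the largest component (", length(scope), " items)."))
    res <- run_sweep(scope)
  }
  t_star <- max(res$cand[res$connected_at])
  structure(
    list(t_star = t_star,
         sweep = tibble(candidate = res$cand, connected = res$connected_at),
         scope = scope, excluded = excluded),
    class = "zn_threshold_sweep")
}

#' @export
print.zn_threshold_sweep <- function(x, ...) {
  cat("Connectivity-preserving threshold sweep\n")
  cat("  scope:", length(x$scope), "items;", length(x$excluded), "excluded\n")
  cat("  candidates:", nrow(x$sweep), " t* =", format(x$t_star, digits = 6), "\n")
  invisible(x)
}

#' Project subgroup-to-context weighted ties
#'
#' From a taxon partition, builds a bipartite graph of contexts and subgroups.
#' The tie weight between a subgroup and a context is the summed percent MNI
#' (as a fraction of the scoped context total) of the subgroup's members in
#' that context; a tie is drawn when the weight reaches `cutoff` (inclusive,
#' "at least"). With `cutoff = 0` the weights over all subgroups sum to 1 in
#' every non-flagged context.
#'
#' @param mni MNI tibble, already restricted to the taxon scope the partition
#'   covers.
#' @param partition Tibble with columns `node` (taxon ids) and `group`; must
#'   cover every taxon in `mni`.
#' @param cutoff Minimum share (fraction) for a tie; default 0.05, i.e. at
#'   least 5 percent of the context's scoped MNI.
#' @return Undirected bipartite igraph (`node_class` `"context"` /
#'   `"subgroup"`) with tie weights as fractions.
#' @export
project_subgroup_ties <- function(mni, partition, cutoff = 0.05) {
  uncovered <- setdiff(mni$taxon_id, partition$node)
  if (length(uncovered)) {
    abort(paste0("Partition does not cover ", length(uncovered),
                 " scoped taxa (e.g. '", uncovered[1], "')."))
  }
  prop <- suppressWarnings(percent_mni(mni))
  ctx <- setdiff(names(prop), "taxon_id")
  groups <- unique(partition$group)
  long <- prop |>
    pivot_longer(all_of(ctx), names_to = "context_id", values_to = "p") |>
    mutate(group = partition$group[match(.data$taxon_id, partition$node)]) |>
    group_by(.data$group, .data$context_id) |>
    summarise(weight = sum(.data$p), .groups = "drop") |>
    filter(!is.na(.data$weight), .data$weight >= cutoff, .data$weight > 0)
  nodes <- bind_rows(
    tibble(name = as.character(groups), node_class = "subgroup"),
    tibble(name = ctx, node_class = "context")
  )
  g <- zn_graph(nodes, tibble(from = as.character(long$group),
                              to = long$context_id, weight = long$weight))
  igraph::V(g)$type <- igraph::V(g)$node_class == "context"
  g
}

#' Export a graph as GraphML plus plain CSV tables
#'
#' Writes `<stem>.graphml` along with `<stem>_edges.csv` (edge list with any
#' weight) and `<stem>_nodes.csv` (node attribute table) so the graph can be
#' consumed by network viewers and spreadsheets alike.
#'
#' @param g igraph object.
#' @param stem Output path without extension.
#' @return Named character vector of written paths, invisibly.
#' @export
export_graph <- function(g, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  gml <- paste0(stem, ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  ep <- paste0(stem, "_edges.csv")
  np <- paste0(stem, "_nodes.csv")
  readr::write_csv(as_tibble(edges), ep, progress = FALSE)
  readr::write_csv(as_tibble(nodes), np, progress = FALSE)
  invisible(c(graphml = gml, edges = ep, nodes = np))
}

#' Plot a network graph
#'
#' Simple ggplot rendering of an igraph object: Fruchterman-Reingold layout
#' (seeded, so the figure is reproducible), nodes coloured by `color_key` when
#' present and otherwise by `node_class`, sized by `size_value` when present,
#' edges drawn with width proportional to weight.
#'
#' @param g igraph object.
#' @param seed Layout seed.
#' @param label Draw node names (default TRUE for graphs with at most 30
#'   nodes).
#' @return A ggplot object.
#' @export
plot_network <- function(g, seed = 42, label = igraph::vcount(g) <= 30) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices"))
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  if (!"color_key" %in% names(nodes)) nodes$color_key <- nodes$node_class
  if (!"size_value" %in% names(nodes)) nodes$size_value <- 1
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges"))
  if (!"weight" %in% names(edges)) edges$weight <- 1
  i <- match(edges$from, nodes$name)
  j <- match(edges$to, nodes$name)
  edges$x <- nodes$x[i]; edges$y <- nodes$y[i]
  edges$xend <- nodes$x[j]; edges$yend <- nodes$y[j]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linewidth = .data$weight),
      colour = "grey60", alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$color_key,
                   size = .data$size_value)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_size(range = c(2, 8), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 2.5, vjust = -1)
  }
  p
}
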