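# Girvan-Newman community detection, implemented from scratch: Brandes edge
# betweenness (compiled), iterative removal of the maximum-betweenness edge
# with a deterministic lexicographic tie-break, modularity of every partition
# in the removal sequence evaluated on the original edge set, and best-Q
# partition selection.

# internal: canonical node order + 0-based sorted edge list for the C++ core.
# Nodes are sorted bytewise so the lexicographically-smallest-pair tie-break is
# locale independent; edge index order then equals lexicographic pair order.
gn_edgelist <- function(g) {
  nodes <- sort(igraph::V(g)$name, method = "radix")
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ends)) {
    i <- match(ends[, 1], nodes) - 1L
    j <- match(ends[, 2], nodes) - 1L
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    ord <- order(lo, hi, method = "radix")
    lo <- lo[ord]
    hi <- hi[ord]
  } else {
    lo <- hi <- integer()
  }
  list(nodes = nodes, ei = lo, ej = hi)
}

#' Edge betweenness (unweighted shortest paths)
#'
#' Brandes-style accumulation of the number of shortest paths crossing each
#' edge, each unordered vertex pair contributing once and equal-length path
#' multiplicities split fractionally. Edge weights, if any, are ignored for
#' path lengths: once ties have been thresholded they are treated as binary.
#'
#' @param g Undirected igraph object with named vertices.
#' @return Tibble with columns `from`, `to` (endpoint pair, `from < to`
#'   bytewise) and `betweenness`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' edge_betweenness_gn(g)
edge_betweenness_gn <- function(g) {
  el <- gn_edgelist(g)
  eb <- if (length(el$ei)) {
    cpp_edge_betweenness(length(el$nodes), el$ei, el$ej)
  } else {
    numeric()
  }
  tibble(from = el$nodes[el$ei + 1L], to = el$nodes[el$ej + 1L],
         betweenness = eb)
}

#' Modularity of a partition
#'
#' Newman-Girvan modularity `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c`
#' is the number of edges inside group `c`, `d_c` the summed degree of its
#' members and `m` the total edge count. The trivial one-group partition has
#' `Q = 0`; isolated nodes contribute nothing through their zero degree.
#'
#' @param g Undirected igraph with at least one edge.
#' @param partition Tibble with columns `node`, `group`, covering every vertex
#'   of `g`.
#' @return Modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(g, partition) {
  m <- igraph::ecount(g)
  if (m == 0) abort("Modularity is undefined on an edgeless graph.")
  nodes <- igraph::V(g)$name
  uncovered <- setdiff(nodes, partition$node)
  if (length(uncovered)) {
    abort(paste0("Partition does not cover node(s): ",
                 paste(head(uncovered, 3), collapse = ", ")))
  }
  lab <- partition$group[match(nodes, partition$node)]
  ends <- igraph::as_edgelist(g, names = TRUE)
  same <- lab[match(ends[, 1], nodes)] == lab[match(ends[, 2], nodes)]
  deg <- igraph::degree(g)
  d_c <- tapply(deg, lab, sum)
  sum(same) / m - sum((d_c / (2 * m))^2)
}

#' Girvan-Newman removal sequence
#'
#' Repeatedly recomputes edge betweenness on the current graph and removes the
#' maximum-betweenness edge, breaking exact ties by the bytewise smallest
#' endpoint pair so the sequence is fully deterministic. After every removal
#' the connected-component partition and its modularity on the original graph
#' are recorded; step 0 is the intact graph. An edgeless input yields the
#' single-step trivial partition (with undefined modularity).
#'
#' @param g Undirected igraph object with named vertices.
#' @return An object of class `girvan_newman`: the original graph, the node
#'   roster, a `steps` tibble (`step`, `removed_edge`, `n_components`,
#'   `modularity`) and the per-step membership matrix.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B, A - C, B - C, C - D, D - E, D - F, E - F)
#' gn <- girvan_newman(g)
#' tidy(gn)
girvan_newman <- function(g) {
  el <- gn_edgelist(g)
  n <- length(el$nodes)
  m <- length(el$ei)
  if (m == 0) {
    membership <- matrix(seq_len(n) - 1L, nrow = 1)
    colnames(membership) <- el$nodes
    steps <- tibble(step = 0L, removed_edge = NA_character_,
                    n_components = n, modularity = NA_real_)
    return(structure(list(graph = g, nodes = el$nodes, steps = steps,
                          membership = membership),
                     class = "girvan_newman"))
  }
  res <- cpp_girvan_newman(n, el$ei, el$ej)
  membership <- res$membership
  colnames(membership) <- el$nodes
  deg <- tabulate(c(el$ei, el$ej) + 1L, nbins = n)
  q_of <- function(lab) {
    same <- lab[el$ei + 1L] == lab[el$ej + 1L]
    d_c <- tapply(deg, lab, sum)
    sum(same) / m - sum((d_c / (2 * m))^2)
  }
  steps <- tibble(
    step = 0:m,
    removed_edge = c(NA_character_,
                     paste0(el$nodes[el$ei[res$removed + 1L] + 1L], " -- ",
                            el$nodes[el$ej[res$removed + 1L] + 1L])),
    n_components = map_int(seq_len(m + 1), function(k) {
      length(unique(membership[k, ]))
    }),
    modularity = map_dbl(seq_len(m + 1), function(k) q_of(membership[k, ]))
  )
  structure(list(graph = g, nodes = el$nodes, steps = steps,
                 membership = membership),
            class = "girvan_newman")
}

#' @export
print.girvan_newman <- function(x, ...) {
  cat("Girvan-Newman dendrogram:", length(x$nodes), "nodes,",
      nrow(x$steps) - 1, "removals\n")
  best <- best_partition(x)
  cat("  best partition:", attr(best, "n_groups"), "groups, Q =",
      format(attr(best, "Q"), digits = 4), "\n")
  invisible(x)
}

# internal: membership row -> partition tibble with groups numbered by first
# appearance in node order
row_partition <- function(gn, k) {
  lab <- gn$membership[k, ]
  lab <- match(lab, unique(lab))
  out <- tibble(node = gn$nodes, group = lab)
  class(out) <- c("zn_partition", class(out))
  out
}

#' Best-modularity partition of a dendrogram
#'
#' Selects the step of the removal sequence with the highest modularity; exact
#' ties go first to the partition with fewer groups and then to the earliest
#' step. On an edgeless dendrogram the trivial partition is returned.
#'
#' @param gn A `girvan_newman` object.
#' @return Tibble with columns `node` and `group` (class `zn_partition`),
#'   carrying attributes `Q`, `step` and `n_groups`.
#' @export
best_partition <- function(gn) {
  s <- gn$steps
  if (all(is.na(s$modularity))) {
    k <- 1L
  } else {
    ord <- order(-s$modularity, s$n_components, s$step, method = "radix")
    k <- ord[1]
  }
  out <- row_partition(gn, k)
  attr(out, "Q") <- s$modularity[k]
  attr(out, "step") <- s$step[k]
  attr(out, "n_groups") <- s$n_components[k]
  out
}

#' Partition at a fixed group count
#'
#' Cuts the removal sequence at the earliest step whose component partition
#' has exactly `k` groups. Because each removal increases the component count
#' by at most one, every count between the initial component count and the
#' node count is attainable; asking for fewer groups than the graph starts
#' with is an error.
#'
#' @param gn A `girvan_newman` object.
#' @param k Target number of groups.
#' @return A `zn_partition` tibble, as in [best_partition()].
#' @export
partition_at <- function(gn, k) {
  hit <- which(gn$steps$n_components == k)
  if (!length(hit)) {
    abort(paste0("No step of the removal sequence has ", k, " groups ",
                 "(range: ", min(gn$steps$n_components), "-",
                 max(gn$steps$n_components), ")."))
  }
  idx <- hit[1]
  out <- row_partition(gn, idx)
  attr(out, "Q") <- gn$steps$modularity[idx]
  attr(out, "step") <- gn$steps$step[idx]
  attr(out, "n_groups") <- k
  out
}

#' @rdname girvan_newman
#' @param x A `girvan_newman` object.
#' @param ... Unused.
#' @export
tidy.girvan_newman <- function(x, ...) {
  x$steps
}

#' @rdname girvan_newman
#' @export
glance.girvan_newman <- function(x, ...) {
  best <- best_partition(x)
  tibble(n_nodes = length(x$nodes),
         n_edges = nrow(x$steps) - 1L,
         best_modularity = attr(best, "Q"),
         best_n_groups = attr(best, "n_groups"),
         best_step = attr(best, "step"))
}

#' @rdname girvan_newman
#' @param object A `girvan_newman` object.
#' @export
autoplot.girvan_newman <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(x = .data$step, y = .data$modularity)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "edges removed", y = "modularity Q",
                  title = "Girvan-Newman removal sequence") +
    ggplot2::theme_minimal()
}

#' Export a partition and its dendrogram
#'
#' Writes `<stem>_partition.csv` (node, group) and `<stem>_dendrogram.csv`
#' (step, removed_edge, n_components, modularity).
#'
#' @param gn A `girvan_newman` object.
#' @param partition A `zn_partition` tibble.
#' @param stem Output path without suffix.
#' @return Named character vector of written paths, invisibly.
#' @export
export_partition <- function(gn, partition, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  pp <- paste0(stem, "_partition.csv")
  dp <- paste0(stem, "_dendrogram.csv")
  readr::write_csv(partition, pp, progress = FALSE)
  readr::write_csv(gn$steps, dp, progress = FALSE)
  invisible(c(partition = pp, dendrogram = dp))
}
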