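# Independent oracles and small fixture builders shared across tests.

# Brute-force edge betweenness: enumerate every shortest path between every
# unordered vertex pair (via igraph's path enumeration, not Brandes) and give
# each edge on each path an equal fractional share.
brute_force_edge_betweenness <- function(g) {
  vs <- igraph::V(g)$name
  eb <- setNames(numeric(igraph::ecount(g)), apply(
    igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "|")))
  if (length(vs) < 2) return(eb)
  for (i in seq_len(length(vs) - 1)) {
    for (j in (i + 1):length(vs)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = vs[i], to = vs[j])$vpaths)
      if (!length(paths)) next
      w <- 1 / length(paths)
      for (p in paths) {
        nm <- igraph::V(g)$name[as.integer(p)]
        if (length(nm) < 2) next
        for (k in seq_len(length(nm) - 1)) {
          key <- paste(sort(nm[k:(k + 1)]), collapse = "|")
          eb[key] <- eb[key] + w
        }
      }
    }
  }
  eb
}

# Set-algebra Jaccard oracle on a presence matrix (items in rows).
brute_force_jaccard <- function(pres) {
  items <- rownames(pres)
  out <- list()
  for (i in seq_len(nrow(pres) - 1)) {
    for (j in (i + 1):nrow(pres)) {
      a <- which(pres[i, ])
      b <- which(pres[j, ])
      un <- union(a, b)
      out[[length(out) + 1]] <- data.frame(
        item1 = items[i], item2 = items[j],
        jaccard = if (!length(un)) 1 else length(intersect(a, b)) / length(un))
    }
  }
  do.call(rbind, out)
}

# Pair-counting closed form for the Adjusted Rand Index.
pair_count_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  exp_idx <- si * sj / choose(n, 2)
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}

# Random connected-ish test graph with named vertices.
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Two triangles joined by one bridge (c -- d).
bridged_triangles <- function() {
  igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f, c - d)
}

# Tiny MNI tibble from a counts matrix.
mni_from_matrix <- function(m) {
  tb <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)), tb)
}

# Similarity table from an explicit symmetric matrix (internal constructor).
sim_from_matrix <- function(m) {
  zooarchnet:::new_similarity(rownames(m), m)
}

# Tiny taxon metadata table.
taxa_meta <- function(taxon_id, class = "invertebrate", habitats = list()) {
  tibble::tibble(
    taxon_id = taxon_id,
    scientific_name = taxon_id,
    common_name = NA_character_,
    class = rep_len(class, length(taxon_id)),
    habitats = rep_len(habitats, length(taxon_id)),
    food_status = "unknown")
}

# Printed per-context totals of the bundled Pineland matrix, in column order.
# The last value is the printed cells' own column sum; see the fidelity tests.
pineland_printed_totals <- c(
  "Old Mound 1 (A-8-101)" = 3480,
  "Surf Clam Ridge (Trench 11B-93)" = 164,
  "Low Mound (A-1-77-1)" = 2957,
  "Old Mound 2 (A-16-92)" = 1561,
  "Brown's Complex 1 (C-6-92-1)" = 2241,
  "Brown's Complex 2 (C-5-88-2)" = 230,
  "Brown's Complex 3 (C-5-79-1)" = 3293,
  "Randell Complex 1 (A-Prof-63)" = 1762,
  "Randell Complex 2 (A-Prof-55)" = 1518,
  "Brown's Complex Mound 2a (I-2-73)" = 479,
  "Brown's Complex Mound 2b (I-2-66)" = 1797,
  "Operation P (P-10-99)" = 1949,
  "Operation P (P-10-101)" = 1156,
  "Operation P (P-1-103)" = 2631,
  "Operation P (P-10-105)" = 9949)
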