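# Pairwise similarity tables. A similarity is stored long: one row per
# unordered item pair (item1 < item2 in item order), with the full ordered item
# roster kept in the "items" attribute so isolates survive thresholding.

new_similarity <- function(items, values) {
  # values: symmetric matrix over items
  idx <- which(upper.tri(values), arr.ind = TRUE)
  out <- tibble(item1 = items[idx[, 1]], item2 = items[idx[, 2]],
                similarity = values[idx])
  attr(out, "items") <- items
  class(out) <- c("zn_similarity", class(out))
  out
}

#' Items covered by a similarity table
#'
#' @param sim A similarity tibble from [jaccard_similarity()] or
#'   [abundance_similarity()].
#' @return Character vector of item identifiers in canonical order.
#' @export
similarity_items <- function(sim) {
  attr(sim, "items") %||% sort(unique(c(sim$item1, sim$item2)), method = "radix")
}

#' Expand a similarity table to a symmetric matrix
#'
#' @inheritParams similarity_items
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(sim) {
  items <- similarity_items(sim)
  m <- diag(1, length(items))
  dimnames(m) <- list(items, items)
  i <- match(sim$item1, items)
  j <- match(sim$item2, items)
  m[cbind(i, j)] <- sim$similarity
  m[cbind(j, i)] <- sim$similarity
  m
}

#' Jaccard similarity from presence/absence
#'
#' Computes `J(A, B) = |A intersect B| / |A union B|` over presence sets
#' (presence means MNI at or above `presence_threshold`, 1 by default), for
#' every unordered pair of contexts or of taxa. Two items that are both empty
#' have no evidence of difference; their Jaccard value is defined as 1 and a
#' warning is raised, since such items are normally excluded upstream.
#'
#' @param mni MNI tibble.
#' @param axis `"contexts"` (compare context columns) or `"taxa"` (compare
#'   taxon rows).
#' @param presence_threshold Minimum MNI that counts as presence.
#' @return A long similarity tibble (class `zn_similarity`).
#' @export
#' @examples
#' jaccard_similarity(pineland_mni(), axis = "contexts")
jaccard_similarity <- function(mni, axis = c("contexts", "taxa"),
                               presence_threshold = 1) {
  axis <- match.arg(axis)
  m <- as_count_matrix(mni) >= presence_threshold
  if (axis == "contexts") m <- t(m)
  if (nrow(m) < 2) abort("Need at least two items on the chosen axis.")
  items <- rownames(m)
  sizes <- rowSums(m)
  inter <- tcrossprod(m * 1)
  un <- outer(sizes, sizes, "+") - inter
  vals <- ifelse(un == 0, 1, inter / pmax(un, 1))
  if (any(un[upper.tri(un)] == 0)) {
    warn("Pair(s) of empty presence sets: Jaccard defined as 1 for identical emptiness.")
  }
  new_similarity(items, vals)
}

#' Renkonen (percentage) similarity of abundance profiles
#'
#' Measures how similarly two taxa are distributed across contexts in both
#' presence and abundance. Each taxon's percent-MNI profile across contexts is
#' normalized to sum 1, and the similarity of two taxa is the Renkonen
#' percentage similarity `S(x, y) = sum_c min(x_c, y_c)`, which is 1 exactly
#' for identical profiles and 0 for profiles with disjoint context support.
#' Taxa whose scoped proportions are all zero carry no profile and are excluded
#' with a warning. As an alternative overlap measure,
#' `method = "manhattan"` uses `1 - sum(|x_c - y_c|) / 2` (one minus the
#' normalized Manhattan distance), which coincides with Renkonen on normalized
#' profiles but is kept as an explicit option for cross-checking.
#'
#' @param prop A proportion tibble from [percent_mni()] (columns sum to 1).
#' @param method `"renkonen"` (default) or `"manhattan"`.
#' @return A long similarity tibble over taxa (class `zn_similarity`).
#' @export
abundance_similarity <- function(prop, method = c("renkonen", "manhattan")) {
  method <- match.arg(method)
  m <- as_count_matrix(prop)
  m[is.na(m)] <- 0 # flagged contexts contribute nothing to any profile
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warn(paste0("Excluding ", sum(tot == 0),
                " taxon/taxa with zero total in scope from abundance similarity."))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(m) < 2) abort("Need at least two taxa with nonzero profiles.")
  m <- m / tot
  n <- nrow(m)
  vals <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      s <- if (method == "renkonen") sum(pmin(xi, m[j, ])) else
        1 - sum(abs(xi - m[j, ])) / 2
      vals[i, j] <- s
      vals[j, i] <- s
    }
  }
  new_similarity(rownames(m), vals)
}
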