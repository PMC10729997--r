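#' Percent MNI per context
#'
#' Converts counts to within-context proportions (percent MNI as fractions).
#' The denominator of each context is the column total over the selected taxon
#' scope, so restricting the scope (for example to invertebrates) rescales the
#' proportions accordingly. Contexts whose scoped total is zero are flagged:
#' their proportions are `NA` and their names are returned in the
#' `"flagged_contexts"` attribute.
#'
#' @param mni MNI tibble.
#' @param taxa_subset Optional character vector of taxon identifiers defining
#'   the scope; `NULL` keeps every taxon. Must select at least one taxon.
#' @return A tibble shaped like the scoped matrix with proportions in place of
#'   counts; non-flagged columns sum to 1.
#' @export
#' @examples
#' p <- percent_mni(pineland_mni())
#' colSums(p[-1])
percent_mni <- function(mni, taxa_subset = NULL) {
  if (!is.null(taxa_subset)) {
    unknown <- setdiff(taxa_subset, mni$taxon_id)
    if (length(unknown)) {
      abort(paste0("Unknown taxon in scope: '", unknown[1], "'"))
    }
    mni <- mni[match(intersect(mni$taxon_id, taxa_subset), mni$taxon_id), ]
  }
  if (!nrow(mni)) abort("Scope selects no taxa.")
  ctx <- setdiff(names(mni), "taxon_id")
  flagged <- character()
  out <- mni
  for (cn in ctx) {
    tot <- sum(mni[[cn]])
    if (tot == 0) {
      flagged <- c(flagged, cn)
      out[[cn]] <- rep(NA_real_, nrow(mni))
    } else {
      out[[cn]] <- mni[[cn]] / tot
    }
  }
  if (length(flagged)) {
    warn(paste0("Context(s) with zero scoped MNI flagged: ",
                paste(flagged, collapse = ", ")))
  }
  attr(out, "flagged_contexts") <- flagged
  out
}

#' Shannon diversity of a proportion vector
#'
#' Computes `H = -sum(p * log(p))` in nats over the positive entries of a
#' normalized proportion vector. Zero entries carry no information and are
#' ignored; an unnormalized vector is an error.
#'
#' @param p Numeric vector of proportions summing to 1.
#' @return Shannon entropy in nats (`>= 0`).
#' @export
#' @examples
#' shannon_diversity(c(0.5, 0.25, 0.25))
shannon_diversity <- function(p) {
  if (any(is.na(p)) || any(p < 0)) abort("Proportions must be non-negative and non-missing.")
  if (abs(sum(p) - 1) > 1e-8) abort("Proportions must sum to 1.")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Taxonomic richness of a count vector
#'
#' @param counts Numeric vector of MNI counts.
#' @return Number of taxa with at least one individual.
#' @export
richness <- function(counts) {
  sum(counts >= 1)
}

#' Ubiquity of a taxon across contexts
#'
#' Fraction of contexts in which the taxon is present (MNI >= 1).
#'
#' @param mni MNI tibble.
#' @param taxon_id Single taxon identifier.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' ubiquity(pineland_mni(), "Mugil spp.")
ubiquity <- function(mni, taxon_id) {
  i <- match(taxon_id, mni$taxon_id)
  if (is.na(i)) abort(paste0("Unknown taxon '", taxon_id, "'"))
  ctx <- setdiff(names(mni), "taxon_id")
  row <- map_dbl(ctx, function(cn) mni[[cn]][i])
  sum(row >= 1) / length(row)
}

#' Per-taxon ubiquity table
#'
#' @param mni MNI tibble.
#' @return Tibble with `taxon_id` and `ubiquity` for every taxon.
#' @export
ubiquity_table <- function(mni) {
  m <- as_count_matrix(mni)
  tibble(taxon_id = rownames(m), ubiquity = rowMeans(m >= 1))
}

#' Per-context summary metrics
#'
#' Combines total MNI, richness and Shannon diversity per context into one
#' node-attribute table. Diversity is computed on percent MNI within the given
#' scope; contexts with zero scoped MNI get `NA` diversity.
#'
#' @inheritParams percent_mni
#' @return Tibble with `context_id`, `total_mni`, `richness`, `shannon`.
#' @export
context_metrics <- function(mni, taxa_subset = NULL) {
  scoped <- if (is.null(taxa_subset)) mni else
    mni[match(intersect(mni$taxon_id, taxa_subset), mni$taxon_id), ]
  ctx <- setdiff(names(scoped), "taxon_id")
  tibble(
    context_id = ctx,
    total_mni = map_int(ctx, function(cn) as.integer(sum(scoped[[cn]]))),
    richness = map_int(ctx, function(cn) as.integer(richness(scoped[[cn]]))),
    shannon = map_dbl(ctx, function(cn) {
      tot <- sum(scoped[[cn]])
      if (tot == 0) return(NA_real_)
      shannon_diversity(scoped[[cn]] / tot)
    })
  )
}

#' Restrict a matrix to invertebrates exclusive to one habitat
#'
#' Keeps exactly the invertebrate taxa whose habitat set has a single element;
#' multi-habitat and unclassified taxa are dropped, and the context set is
#' unchanged. This is the taxon scope used for habitat-level analyses, where a
#' species found in several habitat types cannot witness any one of them.
#'
#' @param mni MNI tibble.
#' @param taxa Taxon metadata tibble (see [read_taxon_metadata()]).
#' @return The filtered MNI tibble, in the original row order.
#' @export
filter_exclusive_habitat <- function(mni, taxa) {
  keep <- taxa$taxon_id[taxa$class == "invertebrate" &
                          map_int(taxa$habitats, length) == 1L]
  mni[mni$taxon_id %in% keep, ]
}

#' Collapse taxon percent MNI into habitat percent MNI
#'
#' Sums MNI over the taxa belonging to each habitat category and expresses the
#' result as each habitat's share of the scoped MNI per context. With the
#' default `scope = "exclusive"` only single-habitat invertebrates contribute,
#' each to its one habitat. With `scope = "fractional"` every
#' habitat-classified invertebrate contributes, its counts split equally among
#' its habitats. Habitat shares conserve mass: each non-flagged context column
#' sums to 1 over classified MNI.
#'
#' @param mni MNI tibble.
#' @param taxa Taxon metadata tibble.
#' @param scope `"exclusive"` (default) or `"fractional"`.
#' @return Tibble with a `habitat` column (all five categories, in canonical
#'   order) and one share column per context. Contexts with zero scoped MNI are
#'   flagged in the `"flagged_contexts"` attribute and hold `NA`.
#' @export
collapse_to_habitats <- function(mni, taxa, scope = c("exclusive", "fractional")) {
  scope <- match.arg(scope)
  taxa <- taxa[taxa$class == "invertebrate", ]
  nh <- map_int(taxa$habitats, length)
  taxa <- if (scope == "exclusive") taxa[nh == 1L, ] else taxa[nh >= 1L, ]
  scoped <- mni[mni$taxon_id %in% taxa$taxon_id, ]
  ctx <- setdiff(names(mni), "taxon_id")
  hb <- matrix(0, nrow = length(ZN_HABITATS), ncol = length(ctx),
               dimnames = list(ZN_HABITATS, ctx))
  for (i in seq_len(nrow(scoped))) {
    habs <- taxa$habitats[[match(scoped$taxon_id[i], taxa$taxon_id)]]
    w <- 1 / length(habs)
    for (h in habs) {
      hb[h, ] <- hb[h, ] + w * map_dbl(ctx, function(cn) scoped[[cn]][i])
    }
  }
  totals <- colSums(hb)
  flagged <- ctx[totals == 0]
  shares <- hb
  for (j in seq_along(ctx)) {
    shares[, j] <- if (totals[j] == 0) NA_real_ else hb[, j] / totals[j]
  }
  if (length(flagged)) {
    warn(paste0("Context(s) with zero habitat-classified MNI flagged: ",
                paste(flagged, collapse = ", ")))
  }
  out <- bind_cols(tibble(habitat = ZN_HABITATS),
                   as_tibble(shares, .name_repair = "minimal"))
  attr(out, "flagged_contexts") <- flagged
  out
}

#' Export node-attribute metric tables
#'
#' Writes the per-context metrics of [context_metrics()] and the per-taxon
#' ubiquities of [ubiquity_table()] as CSV files for use as node attributes in
#' external network tools.
#'
#' @param mni MNI tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_metrics <- function(mni, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctx_path <- file.path(dir, "context_metrics.csv")
  ubi_path <- file.path(dir, "taxon_ubiquity.csv")
  readr::write_csv(context_metrics(mni), ctx_path, progress = FALSE)
  readr::write_csv(ubiquity_table(mni), ubi_path, progress = FALSE)
  invisible(c(context_metrics = ctx_path, taxon_ubiquity = ubi_path))
}
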