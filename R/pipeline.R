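# End-to-end pipelines reproducing the two published analyses: the Operation P
# stratigraphic column (habitat ego-network through subgroup projection) and
# the site-wide comparison (diversity-sized two-mode graph through the
# group-composition table).

#' Pipeline configuration
#'
#' Returns the full configuration list with the published defaults: abundance
#' similarity cutoff 0.60 (strict), context Jaccard cutoff 0.33 (strict),
#' species Jaccard cutoff 0.40 (strict), subgroup tie cutoff 0.05 (inclusive:
#' "at least 5 percent"). Overrides are supplied as named arguments.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
#' @examples
#' zn_config(stratigraphic_groups = 5)
zn_config <- function(...) {
  defaults <- list(
    similarity_cutoff = 0.60,      # Renkonen tie cutoff, strict >
    context_jaccard_cutoff = 0.33, # context one-mode tie cutoff, strict >
    species_jaccard_cutoff = 0.40, # species one-mode tie cutoff, strict >
    subgroup_cutoff = 0.05,        # subgroup tie share, inclusive >=
    stratigraphic_groups = NULL,   # fixed group count; NULL = best modularity
    sitewide_groups = NULL,
    diversity = "shannon",         # context node sizing: "shannon" or "richness"
    collapse_scope = "exclusive",  # habitat collapse scope
    exclude_base = TRUE,           # drop the top-MNI "base" group from the
                                   # composition table
    renormalize_excluded = FALSE   # renormalize columns after exclusion
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  defaults
}

#' Read a pipeline configuration file
#'
#' Reads a YAML key-value file. The returned list is *not* merged with the
#' defaults; pass it through [zn_config()] (`do.call(zn_config, cfg)`) or hand
#' it to a pipeline runner, which validates that every key is present.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

validate_config <- function(config) {
  need <- names(zn_config())
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys)) {
    abort(paste0("Configuration is missing key(s): ",
                 paste(missing_keys, collapse = ", "),
                 ". Build configs with zn_config()."))
  }
  config
}

# internal: community detection for a pipeline stage. Isolates cannot join any
# community, so detection runs on the tied (degree >= 1) nodes and isolates
# pass through as singleton groups appended after the detected ones.
stage_partition <- function(g, k_fixed = NULL) {
  deg <- igraph::degree(g)
  tied <- names(deg)[deg > 0]
  isolates <- names(deg)[deg == 0]
  if (length(tied) < 2) {
    part <- tibble(node = igraph::V(g)$name,
                   group = seq_along(igraph::V(g)$name))
    return(list(gn = NULL, partition = part, n_detected = nrow(part)))
  }
  gn <- girvan_newman(igraph::induced_subgraph(g, tied))
  part <- if (is.null(k_fixed)) best_partition(gn) else partition_at(gn, k_fixed)
  n_detected <- attr(part, "n_groups")
  if (length(isolates)) {
    part <- bind_rows(part, tibble(node = isolates,
                                   group = max(part$group) + seq_along(isolates)))
  }
  list(gn = gn, partition = part, n_detected = n_detected)
}

# internal: relabel groups as integers 1..K by descending total MNI of their
# members, so "group 1" is always the most abundant package.
relabel_by_mni <- function(partition, mni) {
  totals <- tibble(taxon_id = mni$taxon_id,
                   total = rowSums(as_count_matrix(mni))) |>
    mutate(group = partition$group[match(.data$taxon_id, partition$node)]) |>
    group_by(.data$group) |>
    summarise(total = sum(.data$total), .groups = "drop") |>
    arrange(desc(.data$total), .data$group)
  new_lab <- setNames(seq_len(nrow(totals)), totals$group)
  out <- partition
  out$group <- as.integer(new_lab[as.character(partition$group)])
  out
}

#' Group-composition table
#'
#' Per context, the share of each detected group: summed MNI of the group's
#' members divided by the context's scoped total. Excluded groups (for
#' example a ubiquitous "base" package) are dropped from the table but, by
#' default, kept in the denominators, so the remaining columns sum to at most
#' 1; `renormalize = TRUE` rescales each column over the retained groups
#' instead.
#'
#' @param mni MNI tibble restricted to the taxa the partition covers.
#' @param partition Tibble with `node`, `group`.
#' @param excluded_groups Group labels to drop from the table (default none).
#' @param renormalize Rescale retained shares to sum to 1 per context.
#' @return Tibble with a `group` column and one share column per context;
#'   attribute `"excluded_groups"` records the exclusions.
#' @export
group_composition <- function(mni, partition, excluded_groups = NULL,
                              renormalize = FALSE) {
  uncovered <- setdiff(mni$taxon_id, partition$node)
  if (length(uncovered)) {
    abort(paste0("Partition does not cover ", length(uncovered), " scoped taxa."))
  }
  prop <- suppressWarnings(percent_mni(mni))
  ctx <- setdiff(names(prop), "taxon_id")
  shares <- prop |>
    pivot_longer(all_of(ctx), names_to = "context_id", values_to = "p") |>
    mutate(group = partition$group[match(.data$taxon_id, partition$node)]) |>
    group_by(.data$group, .data$context_id) |>
    summarise(share = sum(.data$p), .groups = "drop") |>
    pivot_wider(names_from = "context_id", values_from = "share") |>
    arrange(.data$group)
  shares <- shares[c("group", ctx)]
  if (!is.null(excluded_groups)) {
    shares <- shares[!shares$group %in% excluded_groups, ]
    if (renormalize) {
      for (cn in ctx) {
        tot <- sum(shares[[cn]])
        shares[[cn]] <- if (isTRUE(tot > 0)) shares[[cn]] / tot else shares[[cn]]
      }
    }
  }
  attr(shares, "excluded_groups") <- excluded_groups
  shares
}

# internal: attach period colour / diversity size attributes to context nodes
decorate_contexts <- function(g, contexts, metrics, diversity = "shannon") {
  idx <- igraph::V(g)$node_class == "context"
  names_ctx <- igraph::V(g)$name[idx]
  igraph::V(g)$color_key <- ifelse(igraph::V(g)$node_class == "context",
    contexts$period_label[match(igraph::V(g)$name, contexts$context_id)],
    igraph::V(g)$node_class)
  size_col <- if (diversity == "richness") "richness" else "shannon"
  sizes <- metrics[[size_col]][match(names_ctx, metrics$context_id)]
  sv <- rep(NA_real_, igraph::vcount(g))
  sv[idx] <- sizes
  igraph::V(g)$size_value <- sv
  g
}

manifest_entry <- function(stage_name, inputs, parameters, outputs, summary_counts) {
  list(stage_name = stage_name, inputs = inputs, parameters = parameters,
       outputs = as.list(outputs), summary_counts = summary_counts)
}

graph_counts <- function(g) {
  list(nodes = igraph::vcount(g), edges = igraph::ecount(g))
}

write_manifest <- function(stages, out_dir) {
  # paths are stored relative to the output directory so that re-runs into
  # different directories stay byte-identical
  prefix <- paste0(normalizePath(out_dir, winslash = "/"), "/")
  relativize <- function(x) {
    if (is.list(x)) return(lapply(x, relativize))
    if (is.character(x)) {
      x <- sub(prefix, "", normalizePath(x, winslash = "/", mustWork = FALSE),
               fixed = TRUE)
    }
    x
  }
  stages <- lapply(stages, function(st) {
    st$outputs <- relativize(st$outputs)
    st
  })
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(stages, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

#' Run the stratigraphic (Operation P) analysis
#'
#' Reproduces the within-column analysis on the four Operation P levels, in
#' order: the habitat-species ego network; the layer-by-exclusive-species
#' presence graph coloured by habitat; the layer-by-habitat collapsed weighted
#' graph; the exclusive-species one-mode graph tied at Renkonen similarity
#' above the cutoff; its Girvan-Newman partition (best modularity, or a fixed
#' group count via `stratigraphic_groups`); and the layer-by-subgroup weighted
#' graph with inclusive 5-percent ties. Community detection runs on the tied
#' species; untied species pass through as singleton groups. Group labels are
#' integers ordered by descending total MNI.
#'
#' @param mni MNI tibble (defaults to the bundled Pineland matrix).
#' @param taxa Taxon metadata; habitat designations are required.
#' @param contexts Context metadata; the stage scopes to `site_area ==
#'   "operation_p"`.
#' @param out_dir Output directory for graphs, tables and the JSON manifest.
#' @param config Configuration list from [zn_config()].
#' @return The stage manifest (named list, one entry per stage), invisibly
#'   annotated with `partition` and `out_dir`.
#' @export
run_stratigraphic <- function(mni = pineland_mni(), taxa = pineland_taxa(),
                              contexts = pineland_contexts(), out_dir,
                              config = zn_config()) {
  config <- validate_config(config)
  if (is.null(taxa) || !any(map_int(taxa$habitats, length) > 0)) {
    abort("Habitat metadata is required for the stratigraphic analysis.")
  }
  op_ctx <- contexts$context_id[contexts$site_area == "operation_p"]
  op_ctx <- intersect(names(mni), op_ctx) # preserve matrix column order
  if (!length(op_ctx)) abort("No Operation P contexts found in the matrix.")
  sub <- mni[c("taxon_id", op_ctx)]
  inv <- taxa$taxon_id[taxa$class == "invertebrate"]
  sub_inv <- sub[sub$taxon_id %in% inv, ]
  present <- rowSums(as_count_matrix(sub_inv)) >= 1
  sub_inv <- sub_inv[present, ]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- context_metrics(sub_inv)
  stages <- list()

  # 1. habitat ego-network: invertebrate species tied to the habitats they
  # occupy
  hab_edges <- taxa |>
    filter(.data$taxon_id %in% sub_inv$taxon_id) |>
    select("taxon_id", "habitats") |>
    tidyr::unnest_longer("habitats", values_to = "habitat")
  g1 <- zn_graph(
    bind_rows(tibble(name = sub_inv$taxon_id, node_class = "species"),
              tibble(name = ZN_HABITATS, node_class = "habitat")),
    tibble(from = hab_edges$taxon_id, to = hab_edges$habitat))
  out1 <- export_graph(g1, file.path(out_dir, "habitat_species"))
  stages$habitat_species <- manifest_entry(
    "habitat_species", list(contexts = op_ctx),
    list(scope = "invertebrates present in Operation P"),
    out1, graph_counts(g1))

  # 2. layers x exclusive-habitat species, coloured by habitat
  excl <- filter_exclusive_habitat(sub_inv, taxa)
  g2 <- build_two_mode(excl, tie_rule = "presence")
  hab_of <- map_chr(igraph::V(g2)$name, function(nm) {
    i <- match(nm, taxa$taxon_id)
    if (is.na(i) || !length(taxa$habitats[[i]])) NA_character_ else taxa$habitats[[i]][1]
  })
  igraph::V(g2)$color_key <- ifelse(igraph::V(g2)$node_class == "species",
                                    hab_of, "layer")
  out2 <- export_graph(g2, file.path(out_dir, "layer_exclusive_species"))
  stages$layer_exclusive_species <- manifest_entry(
    "layer_exclusive_species", list(contexts = op_ctx),
    list(scope = "single-habitat invertebrates"),
    out2, graph_counts(g2))

  # 3. layers x habitats, percent MNI collapsed
  hp <- suppressWarnings(collapse_to_habitats(sub_inv, taxa,
                                              scope = config$collapse_scope))
  hp_long <- hp |>
    pivot_longer(all_of(op_ctx), names_to = "context_id", values_to = "share") |>
    filter(!is.na(.data$share), .data$share > 0)
  g3 <- zn_graph(
    bind_rows(tibble(name = ZN_HABITATS, node_class = "habitat"),
              tibble(name = op_ctx, node_class = "context")),
    tibble(from = hp_long$habitat, to = hp_long$context_id,
           weight = hp_long$share))
  out3 <- export_graph(g3, file.path(out_dir, "layer_habitat"))
  hp_path <- file.path(out_dir, "habitat_profile.csv")
  readr::write_csv(hp, hp_path, progress = FALSE)
  out3 <- c(out3, habitat_profile = hp_path)
  stages$layer_habitat <- manifest_entry(
    "layer_habitat", list(contexts = op_ctx),
    list(collapse_scope = config$collapse_scope),
    out3, graph_counts(g3))

  # 4. exclusive-species one-mode graph at Renkonen similarity > cutoff
  prop <- suppressWarnings(percent_mni(excl))
  sim <- suppressWarnings(abundance_similarity(prop))
  g4 <- threshold_graph(sim, config$similarity_cutoff, strict = TRUE)
  out4 <- export_graph(g4, file.path(out_dir, "species_similarity"))
  stages$species_similarity <- manifest_entry(
    "species_similarity", list(contexts = op_ctx),
    list(metric = "renkonen", cutoff = config$similarity_cutoff, strict = TRUE),
    out4, graph_counts(g4))

  # 5. Girvan-Newman subgroups of the similarity graph
  sp <- stage_partition(g4, config$stratigraphic_groups)
  partition <- relabel_by_mni(sp$partition, excl[excl$taxon_id %in% sp$partition$node, ])
  igraph::V(g4)$color_key <- as.character(
    partition$group[match(igraph::V(g4)$name, partition$node)])
  out5 <- export_graph(g4, file.path(out_dir, "species_partition"))
  if (!is.null(sp$gn)) {
    out5 <- c(out5, export_partition(sp$gn, partition,
                                     file.path(out_dir, "species")))
  }
  stages$species_partition <- manifest_entry(
    "species_partition", list(contexts = op_ctx),
    list(fixed_groups = config$stratigraphic_groups %||% "best_modularity"),
    out5,
    c(graph_counts(g4),
      list(groups_detected = sp$n_detected,
           groups_total = length(unique(partition$group)))))

  # 6. layers x subgroups, >= 5 percent MNI ties
  scoped <- excl[excl$taxon_id %in% partition$node, ]
  g6 <- project_subgroup_ties(scoped, partition, cutoff = config$subgroup_cutoff)
  out6 <- export_graph(g6, file.path(out_dir, "layer_subgroup"))
  stages$layer_subgroup <- manifest_entry(
    "layer_subgroup", list(contexts = op_ctx),
    list(cutoff = config$subgroup_cutoff, inclusive = TRUE),
    out6, graph_counts(g6))

  manifest_path <- write_manifest(stages, out_dir)
  attr(stages, "partition") <- partition
  attr(stages, "out_dir") <- out_dir
  attr(stages, "manifest_path") <- manifest_path
  invisible(stages)
}

#' Run the site-wide analysis
#'
#' Reproduces the cross-context analysis on the full matrix, in order: the
#' context-by-species two-mode graph with contexts sized by assemblage
#' diversity and coloured by period; the context one-mode graph tied at
#' Jaccard similarity above 0.33; the species one-mode graph tied at Jaccard
#' above 0.40, sized by ubiquity and partitioned with Girvan-Newman (best
#' modularity, or `sitewide_groups`); the context-by-subgroup weighted graph;
#' and the group-composition table, by default excluding the top-MNI "base"
#' group from the table while keeping it in the denominators.
#'
#' @inheritParams run_stratigraphic
#' @return The stage manifest, invisibly, with attributes `partition`,
#'   `composition` and `out_dir`.
#' @export
run_sitewide <- function(mni = pineland_mni(), taxa = pineland_taxa(),
                         contexts = pineland_contexts(), out_dir,
                         config = zn_config()) {
  config <- validate_config(config)
  ctx <- setdiff(names(mni), "taxon_id")
  missing_ctx <- setdiff(ctx, contexts$context_id)
  if (length(missing_ctx)) {
    abort(paste0("Context metadata (periods) missing for: ",
                 paste(head(missing_ctx, 3), collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- context_metrics(mni)
  present <- rowSums(as_count_matrix(mni)) >= 1
  scoped <- mni[present, ]
  stages <- list()

  # 1. contexts x all species, sized by diversity, coloured by period
  g1 <- build_two_mode(mni, tie_rule = "presence")
  g1 <- decorate_contexts(g1, contexts, metrics, config$diversity)
  out1 <- export_graph(g1, file.path(out_dir, "context_species"))
  metrics_path <- file.path(out_dir, "context_metrics.csv")
  readr::write_csv(metrics, metrics_path, progress = FALSE)
  out1 <- c(out1, context_metrics = metrics_path)
  stages$context_species <- manifest_entry(
    "context_species", list(contexts = ctx),
    list(diversity = config$diversity),
    out1, graph_counts(g1))

  # 2. context one-mode graph, Jaccard > cutoff
  jc <- jaccard_similarity(mni, axis = "contexts")
  g2 <- threshold_graph(jc, config$context_jaccard_cutoff, strict = TRUE,
                        node_class = "context")
  g2 <- decorate_contexts(g2, contexts, metrics, config$diversity)
  out2 <- export_graph(g2, file.path(out_dir, "context_jaccard"))
  stages$context_jaccard <- manifest_entry(
    "context_jaccard", list(contexts = ctx),
    list(metric = "jaccard", cutoff = config$context_jaccard_cutoff,
         strict = TRUE),
    out2, graph_counts(g2))

  # 3. species one-mode graph, Jaccard > cutoff, sized by ubiquity,
  # partitioned
  js <- jaccard_similarity(scoped, axis = "taxa")
  g3 <- threshold_graph(js, config$species_jaccard_cutoff, strict = TRUE)
  ubi <- ubiquity_table(scoped)
  igraph::V(g3)$size_value <- ubi$ubiquity[match(igraph::V(g3)$name,
                                                 ubi$taxon_id)]
  sp <- stage_partition(g3, config$sitewide_groups)
  partition <- relabel_by_mni(sp$partition, scoped)
  igraph::V(g3)$color_key <- as.character(
    partition$group[match(igraph::V(g3)$name, partition$node)])
  out3 <- export_graph(g3, file.path(out_dir, "species_jaccard"))
  if (!is.null(sp$gn)) {
    out3 <- c(out3, export_partition(sp$gn, partition,
                                     file.path(out_dir, "species")))
  }
  stages$species_jaccard <- manifest_entry(
    "species_jaccard", list(contexts = ctx),
    list(metric = "jaccard", cutoff = config$species_jaccard_cutoff,
         strict = TRUE,
         fixed_groups = config$sitewide_groups %||% "best_modularity"),
    out3,
    c(graph_counts(g3),
      list(groups_detected = sp$n_detected,
           groups_total = length(unique(partition$group)))))

  # 4. contexts x subgroups, weighted ties
  g4 <- project_subgroup_ties(scoped, partition, cutoff = config$subgroup_cutoff)
  g4 <- decorate_contexts(g4, contexts, metrics, config$diversity)
  out4 <- export_graph(g4, file.path(out_dir, "context_subgroup"))
  stages$context_subgroup <- manifest_entry(
    "context_subgroup", list(contexts = ctx),
    list(cutoff = config$subgroup_cutoff, inclusive = TRUE),
    out4, graph_counts(g4))

  # 5. group-composition table, base group excluded from the table (not the
  # denominators) by default
  excluded <- if (isTRUE(config$exclude_base)) 1L else NULL
  comp <- group_composition(scoped, partition, excluded_groups = excluded,
                            renormalize = config$renormalize_excluded)
  comp_path <- file.path(out_dir, "group_composition.csv")
  readr::write_csv(comp, comp_path, progress = FALSE)
  stages$group_composition <- manifest_entry(
    "group_composition", list(contexts = ctx),
    list(excluded_groups = excluded %||% "none",
         renormalize = config$renormalize_excluded),
    c(composition = comp_path),
    list(groups = nrow(comp), contexts = length(ctx)))

  manifest_path <- write_manifest(stages, out_dir)
  attr(stages, "partition") <- partition
  attr(stages, "composition") <- comp
  attr(stages, "out_dir") <- out_dir
  attr(stages, "manifest_path") <- manifest_path
  invisible(stages)
}
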