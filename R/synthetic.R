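# Synthetic assemblage generator: planted "packages" of species that co-occur
# in similar proportions across subsets of contexts, a ubiquitous base
# package, Poisson stray counts, and blockwise habitat labels. Used to test
# every pipeline stage, including community-detection recovery, without real
# data.

#' Specify a synthetic assemblage
#'
#' Describes a planted-partition count matrix: `n_groups` species packages of
#' `species_per_group` members, each package abundant only in its supported
#' contexts; a base package of `base_group_size` species abundant everywhere;
#' within-package member weights drawn once per package from a symmetric
#' Dirichlet (higher `within_group_concentration` makes member profiles more
#' even, hence more similar across contexts); every cell additionally receives
#' Poisson stray counts with mean `background_rate`.
#'
#' @param n_contexts Number of contexts.
#' @param n_groups Number of planted (non-base) packages.
#' @param species_per_group Species per package.
#' @param base_group_size Species in the ubiquitous base package (0 for none).
#' @param context_support Named list mapping group labels `"g1"`, `"g2"`, ...
#'   to the integer indices of their supported contexts; `NULL` (default)
#'   splits the contexts into `n_groups` contiguous, disjoint, near-equal
#'   blocks.
#' @param within_group_concentration Dirichlet concentration for member
#'   weights (dimensionless, > 0).
#' @param background_rate Expected stray MNI per species per context.
#' @param context_total Expected MNI allocated per context (before strays).
#' @return A list of class `zn_synthetic_spec`.
#' @export
synthetic_spec <- function(n_contexts = 8, n_groups = 4, species_per_group = 10,
                           base_group_size = 5, context_support = NULL,
                           within_group_concentration = 50,
                           background_rate = 0.2, context_total = 500) {
  if (n_contexts < 1 || n_groups < 1 || species_per_group < 1) {
    abort("n_contexts, n_groups and species_per_group must all be >= 1.")
  }
  if (base_group_size < 0) abort("base_group_size must be >= 0.")
  if (background_rate < 0) abort("background_rate must be >= 0.")
  if (context_total < 1) abort("context_total must be >= 1.")
  if (is.null(context_support)) {
    blocks <- split(seq_len(n_contexts),
                    cut(seq_len(n_contexts), n_groups, labels = FALSE))
    context_support <- setNames(blocks, paste0("g", seq_len(n_groups)))
  }
  if (length(context_support) != n_groups ||
      any(!map_lgl(context_support, function(s) length(s) >= 1))) {
    abort("context_support must give a nonempty context set for every group.")
  }
  structure(list(n_contexts = n_contexts, n_groups = n_groups,
                 species_per_group = species_per_group,
                 base_group_size = base_group_size,
                 context_support = context_support,
                 within_group_concentration = within_group_concentration,
                 background_rate = background_rate,
                 context_total = context_total),
            class = "zn_synthetic_spec")
}

rdirichlet1 <- function(k, alpha) {
  x <- rgamma(k, shape = alpha)
  x / sum(x)
}

#' Generate a synthetic assemblage with known structure
#'
#' Draws an integer MNI matrix from a [synthetic_spec()]: each context's total
#' is allocated multinomially among the packages supported there (the base
#' package is supported everywhere), packages share the context total equally
#' and split their share by their Dirichlet member weights; Poisson stray
#' counts are then added to every cell. Habitat labels are assigned blockwise,
#' one of the five habitat categories per package, so habitat filtering and
#' collapsing have non-trivial behaviour on synthetic data. Identical seeds
#' give identical output.
#'
#' @param spec A `zn_synthetic_spec`.
#' @param seed Integer seed for all randomness.
#' @return A list of class `zn_synthetic` with `mni` (wide MNI tibble),
#'   `truth` (tibble `taxon_id`, `group`, `habitat`; base species are group
#'   `"base"`) and `spec`.
#' @export
#' @examples
#' truth <- generate_assemblage(synthetic_spec(n_contexts = 4, n_groups = 2,
#'                                             species_per_group = 3), seed = 1)
#' truth$mni
generate_assemblage <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "zn_synthetic_spec"))
  set.seed(seed)
  contexts <- sprintf("ctx_%02d", seq_len(spec$n_contexts))
  groups <- names(spec$context_support)
  species <- unlist(map(groups, function(g) {
    sprintf("%s_sp%02d", g, seq_len(spec$species_per_group))
  }))
  group_of <- rep(groups, each = spec$species_per_group)
  if (spec$base_group_size > 0) {
    base_sp <- sprintf("base_sp%02d", seq_len(spec$base_group_size))
    species <- c(species, base_sp)
    group_of <- c(group_of, rep("base", spec$base_group_size))
  }
  weights <- lapply(setNames(unique(group_of), unique(group_of)), function(g) {
    members <- species[group_of == g]
    setNames(rdirichlet1(length(members), spec$within_group_concentration),
             members)
  })
  counts <- matrix(0, nrow = length(species), ncol = spec$n_contexts,
                   dimnames = list(species, contexts))
  for (ci in seq_len(spec$n_contexts)) {
    active <- groups[map_lgl(groups, function(g) ci %in% spec$context_support[[g]])]
    if (spec$base_group_size > 0) active <- c(active, "base")
    if (length(active)) {
      probs <- unlist(map(active, function(g) weights[[g]] / length(active)))
      size <- rpois(1, spec$context_total) # context_total is an expectation
      draw <- rmultinom(1, size = size, prob = probs)[, 1]
      counts[names(probs), ci] <- counts[names(probs), ci] + draw
    }
    if (spec$background_rate > 0) {
      counts[, ci] <- counts[, ci] + rpois(length(species), spec$background_rate)
    }
  }
  habitats <- setNames(ZN_HABITATS[(seq_along(unique(group_of)) - 1) %% 5 + 1],
                       unique(group_of))
  truth <- tibble(taxon_id = species, group = group_of,
                  habitat = unname(habitats[group_of]))
  mni <- as_mni_tibble(counts)
  mni[contexts] <- lapply(mni[contexts], as.integer)
  structure(list(mni = mni, truth = truth, spec = spec), class = "zn_synthetic")
}

#' Write a synthetic assemblage to disk
#'
#' Emits the same CSV formats as the assemblage readers (MNI matrix and a
#' taxon metadata table marking every species invertebrate with its blockwise
#' habitat) plus a `truth.csv` (taxon, group, habitat) for test harnesses.
#'
#' @param synth A `zn_synthetic` object.
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mni_path <- file.path(dir, "synthetic_mni.csv")
  taxa_path <- file.path(dir, "synthetic_taxa.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_mni_matrix(synth$mni, mni_path)
  taxa <- tibble(taxon_id = synth$truth$taxon_id,
                 scientific_name = synth$truth$taxon_id,
                 common_name = NA_character_,
                 class = "invertebrate",
                 habitats = synth$truth$habitat,
                 food_status = "unknown")
  readr::write_csv(taxa, taxa_path, progress = FALSE)
  readr::write_csv(synth$truth, truth_path, progress = FALSE)
  invisible(c(mni = mni_path, taxa = taxa_path, truth = truth_path))
}

#' Recover species packages from an assemblage
#'
#' Runs the abundance-profile community pipeline end to end: Renkonen
#' similarity of context-normalized percent-MNI profiles, the
#' connectivity-preserving maximum threshold, Girvan-Newman on the thresholded
#' graph (inclusive at the selected threshold, since that is the value at
#' which connectivity holds) and best-modularity partition selection.
#'
#' @param mni MNI tibble.
#' @return A `zn_partition` tibble over the taxa in scope, with the threshold
#'   sweep attached as attribute `"sweep"`.
#' @export
recover_groups <- function(mni) {
  prop <- suppressWarnings(percent_mni(mni))
  sim <- suppressWarnings(abundance_similarity(prop))
  # with perfectly separated packages the graph never connects; fall back to
  # the densest positive-tie graph, whose components are the packages
  sweep <- suppressWarnings(max_connected_threshold(sim, on_disconnected = "minimum"))
  sub <- sim[sim$item1 %in% sweep$scope & sim$item2 %in% sweep$scope, ]
  attr(sub, "items") <- sweep$scope
  g <- threshold_graph(sub, sweep$t_star, strict = FALSE)
  part <- best_partition(girvan_newman(g))
  attr(part, "sweep") <- sweep
  part
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between a found and a reference partition of the
#' same node set; 1 means identical up to label permutation, 0 is the expected
#' agreement of random labellings.
#'
#' @param found,truth Tibbles with columns `node` (or `taxon_id`) and `group`.
#' @return ARI in `[-1, 1]`.
#' @export
recovery_score <- function(found, truth) {
  get_nodes <- function(x) if ("node" %in% names(x)) x$node else x$taxon_id
  fn <- get_nodes(found)
  tn <- get_nodes(truth)
  if (!setequal(fn, tn) || length(fn) != length(tn)) {
    abort("Partitions must cover the same node set.")
  }
  mclust::adjustedRandIndex(found$group[order(fn, method = "radix")],
                            truth$group[order(tn, method = "radix")])
}
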