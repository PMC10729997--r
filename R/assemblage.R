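#' Read a taxon-by-context MNI matrix
#'
#' Reads a comma-delimited abundance table whose first column holds taxon
#' identifiers and whose remaining columns hold Minimum Number of Individuals
#' (MNI) counts, one column per archaeological context. Absence may be recorded
#' as an em dash (`—`), a hyphen, or an empty cell; all three are parsed
#' as zero. Any other non-integer cell is an error that names the offending
#' taxon and context. Row and column order of the file are preserved.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble with a `taxon_id` character column followed by one integer
#'   column per context.
#' @export
#' @examples
#' mni <- pineland_mni()
#' dim(mni)
read_mni_matrix <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) {
    abort("MNI matrix needs a taxon column plus at least one context column.")
  }
  names(raw)[1] <- "taxon_id"
  ctx <- names(raw)[-1]
  if (anyDuplicated(ctx)) {
    abort(paste0("Duplicate context identifier(s): ",
                 paste(unique(ctx[duplicated(ctx)]), collapse = ", ")))
  }
  if (anyDuplicated(raw$taxon_id)) {
    abort(paste0("Duplicate taxon identifier(s): ",
                 paste(unique(raw$taxon_id[duplicated(raw$taxon_id)]), collapse = ", ")))
  }
  parse_col <- function(x, ctx_id) {
    x <- ifelse(is.na(x) | x %in% c("—", "-", ""), "0", trimws(x))
    bad <- !grepl("^[0-9]+$", x)
    if (any(bad)) {
      abort(paste0("Non-integer MNI cell for taxon '", raw$taxon_id[which(bad)[1]],
                   "' in context '", ctx_id, "': '", x[which(bad)[1]], "'"))
    }
    as.integer(x)
  }
  counts <- map2(raw[ctx], ctx, parse_col)
  out <- tibble(taxon_id = raw$taxon_id)
  out[ctx] <- counts
  out
}

#' Write an MNI matrix
#'
#' Inverse of [read_mni_matrix()]: writes the counts as plain integers (zeros
#' stay zeros, no placeholder dashes) so that a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param mni An MNI tibble as returned by [read_mni_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mni_matrix <- function(mni, path) {
  readr::write_csv(mni, path, progress = FALSE)
  invisible(path)
}

#' Read taxon metadata
#'
#' Reads per-taxon records: scientific and common name, coarse class
#' (invertebrate or vertebrate) and the set of habitat categories the taxon
#' occupies, given as a semicolon-joined subset of the five categories
#' `tidal_stream`, `estuarine_mangrove`, `oyster_bed`, `seagrass_meadow` and
#' `littoral`. An empty habitat cell means the taxon is unclassified (for
#' example terrestrial snails or indeterminate higher taxa); any habitat name
#' outside the five categories is an error.
#'
#' @param path Path to a CSV with columns `taxon_id`, `scientific_name`,
#'   `common_name`, `class`, `habitats`, `food_status`.
#' @return A tibble with those columns; `habitats` is a list-column of
#'   character vectors.
#' @export
read_taxon_metadata <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("taxon_id", "class", "habitats")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Taxon metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(raw$taxon_id)) {
    abort(paste0("Duplicate taxon identifier(s) in metadata: ",
                 paste(unique(raw$taxon_id[duplicated(raw$taxon_id)]), collapse = ", ")))
  }
  bad_class <- setdiff(unique(raw$class), c("invertebrate", "vertebrate"))
  if (length(bad_class)) {
    abort(paste0("Unknown class value(s): ", paste(bad_class, collapse = ", ")))
  }
  parse_habitats <- function(x, id) {
    if (is.na(x) || trimws(x) == "") return(character())
    h <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    h <- h[nzchar(h)]
    unknown <- setdiff(h, ZN_HABITATS)
    if (length(unknown)) {
      abort(paste0("Unknown habitat '", unknown[1], "' for taxon '", id,
                   "'; habitats must be among: ", paste(ZN_HABITATS, collapse = ", ")))
    }
    unique(h)
  }
  raw$habitats <- map2(raw$habitats, raw$taxon_id, parse_habitats)
  if (!"scientific_name" %in% names(raw)) raw$scientific_name <- raw$taxon_id
  if (!"common_name" %in% names(raw)) raw$common_name <- NA_character_
  if (!"food_status" %in% names(raw)) raw$food_status <- "unknown"
  raw$food_status <- replace_na(raw$food_status, "unknown")
  as_tibble(raw[c("taxon_id", "scientific_name", "common_name", "class",
                  "habitats", "food_status")])
}

#' Read context metadata
#'
#' @param path Path to a CSV with columns `context_id`, `site_area`,
#'   `period_label`, `strat_order`. `strat_order`, where present, must be a
#'   strict total order within each site area (smallest = stratigraphically
#'   lowest, i.e. earliest).
#' @return A tibble of context records.
#' @export
read_context_metadata <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    context_id = readr::col_character(),
    site_area = readr::col_character(),
    period_label = readr::col_character(),
    strat_order = readr::col_integer()
  ), progress = FALSE)
  if (anyDuplicated(raw$context_id)) {
    abort(paste0("Duplicate context identifier(s): ",
                 paste(unique(raw$context_id[duplicated(raw$context_id)]), collapse = ", ")))
  }
  bad_area <- setdiff(unique(raw$site_area), ZN_SITE_AREAS)
  if (length(bad_area)) {
    abort(paste0("Unknown site_area value(s): ", paste(bad_area, collapse = ", ")))
  }
  dup_order <- raw |>
    filter(!is.na(.data$strat_order)) |>
    count(.data$site_area, .data$strat_order) |>
    filter(.data$n > 1)
  if (nrow(dup_order)) {
    abort("strat_order must be a strict total order within a site_area.")
  }
  raw
}

#' Bundled Pineland fixtures
#'
#' `pineland_mni()` returns the species-by-context MNI table transcribed from
#' the published compilation for the Pineland Site Complex (15 contexts, 336
#' taxa). `pineland_taxa()` returns the taxon metadata; its habitat
#' designations are a curated stand-in assigned at genus/family level from
#' standard ecology of southwestern-Florida estuarine invertebrates (the
#' original study's designations follow a companion publication and are not
#' printed), so they are editable data, not a published reference.
#' `pineland_contexts()` returns site area, period label and (for the
#' Operation P column samples) stratigraphic order per context.
#'
#' @return A tibble; see [read_mni_matrix()], [read_taxon_metadata()] and
#'   [read_context_metadata()] for the column contracts.
#' @export
pineland_mni <- function() {
  read_mni_matrix(system.file("extdata", "pineland_mni.csv",
                              package = "zooarchnet", mustWork = TRUE))
}

#' @rdname pineland_mni
#' @export
pineland_taxa <- function() {
  read_taxon_metadata(system.file("extdata", "pineland_taxa.csv",
                                  package = "zooarchnet", mustWork = TRUE))
}

#' @rdname pineland_mni
#' @export
pineland_contexts <- function() {
  read_context_metadata(system.file("extdata", "pineland_contexts.csv",
                                    package = "zooarchnet", mustWork = TRUE))
}

#' Validate an assemblage dataset
#'
#' Cross-checks an MNI matrix against taxon and context metadata. Structural
#' problems in the matrix itself (negative or fractional counts) are errors;
#' taxa or contexts missing from the metadata are warnings. `is_valid` is true
#' exactly when there are no errors.
#'
#' @param mni MNI tibble (see [read_mni_matrix()]).
#' @param taxa Optional taxon metadata tibble.
#' @param contexts Optional context metadata tibble.
#' @return A list with `errors` (tibble of row, column, message), `warnings`
#'   (character) and `is_valid` (logical).
#' @export
validate_assemblage <- function(mni, taxa = NULL, contexts = NULL) {
  errors <- list()
  warnings <- character()
  ctx <- setdiff(names(mni), "taxon_id")
  if (!length(ctx) || !nrow(mni)) {
    errors[[length(errors) + 1]] <-
      tibble(row = NA_integer_, column = NA_character_,
             message = "matrix needs at least one taxon and one context")
  }
  for (cn in ctx) {
    x <- mni[[cn]]
    bad <- which(is.na(x) | x < 0 | x != trunc(x))
    for (i in bad) {
      errors[[length(errors) + 1]] <-
        tibble(row = i, column = cn,
               message = paste0("count for '", mni$taxon_id[i],
                                "' is not a non-negative integer"))
    }
  }
  if (anyDuplicated(mni$taxon_id)) {
    errors[[length(errors) + 1]] <-
      tibble(row = NA_integer_, column = "taxon_id",
             message = "duplicate taxon identifiers")
  }
  if (!is.null(taxa)) {
    orphan <- setdiff(mni$taxon_id, taxa$taxon_id)
    if (length(orphan)) {
      warnings <- c(warnings, paste0(length(orphan),
        " matrix taxa missing from taxon metadata (e.g. '", orphan[1], "')"))
    }
    extra <- setdiff(taxa$taxon_id, mni$taxon_id)
    if (length(extra)) {
      warnings <- c(warnings, paste0(length(extra),
        " metadata taxa absent from the matrix (e.g. '", extra[1], "')"))
    }
  }
  if (!is.null(contexts)) {
    orphan <- setdiff(ctx, contexts$context_id)
    if (length(orphan)) {
      warnings <- c(warnings, paste0(length(orphan),
        " matrix contexts missing from context metadata (e.g. '", orphan[1], "')"))
    }
  }
  errors <- if (length(errors)) list_rbind(errors) else
    tibble(row = integer(), column = character(), message = character())
  list(errors = errors, warnings = warnings, is_valid = nrow(errors) == 0)
}

#' Per-context MNI totals
#'
#' @param mni MNI tibble.
#' @return A tibble with columns `context_id` and `total_mni` (exact integer
#'   column sums), in the matrix's column order.
#' @export
#' @examples
#' context_totals(pineland_mni())
context_totals <- function(mni) {
  ctx <- setdiff(names(mni), "taxon_id")
  tibble(context_id = ctx,
         total_mni = map_int(ctx, function(cn) sum(as.integer(mni[[cn]]))))
}

# internal: wide tibble -> integer matrix with dimnames
as_count_matrix <- function(mni) {
  ctx <- setdiff(names(mni), "taxon_id")
  m <- as.matrix(mni[ctx])
  storage.mode(m) <- "double"
  rownames(m) <- mni$taxon_id
  m
}

# internal: matrix -> wide tibble
as_mni_tibble <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(taxon_id = rownames(m)), out)
  out
}
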