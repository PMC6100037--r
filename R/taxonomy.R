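#' Validate an aromatic-series taxonomy
#'
#' The taxonomy maps odor descriptors to aromatic series. Every descriptor
#' belongs to exactly one of the ten primary series (herbaceous, floral,
#' fruity, sweet, spicy, roasty, fatty, earthy, balsamic, solvent). The three
#' broad primaries -- fruity, floral and sweet -- are subdivided further, so a
#' descriptor under one of them may additionally carry secondary series
#' (e.g. descriptor "honey" maps to primary sweet, secondary honey).
#' Secondary series under any other primary are rejected, as is a descriptor
#' mapped to two different primaries or a secondary series with inconsistent
#' parents.
#'
#' @param taxonomy A data frame with columns `descriptor`, `primary_series`
#'   and `secondary_series` (list-column or pipe-separated character).
#' @return A validated tibble with `secondary_series` as a list-column.
#' @export
as_aroma_taxonomy <- function(taxonomy) {
  assert_columns(taxonomy, c("descriptor", "primary_series"), "taxonomy")
  tax <- as_tibble(taxonomy)
  if (nrow(tax) == 0) {
    abort("taxonomy is empty: at least one descriptor row is required",
          class = "vitisaroma_validation_error")
  }
  if (!"secondary_series" %in% names(tax)) tax$secondary_series <- list()
  if (!is.list(tax$secondary_series)) {
    tax$secondary_series <- split_tokens(as.character(tax$secondary_series))
  } else {
    tax$secondary_series <- lapply(tax$secondary_series, fold_descriptor)
  }
  tax$descriptor <- fold_descriptor(as.character(tax$descriptor))
  tax$primary_series <- fold_descriptor(as.character(tax$primary_series))

  bad_primary <- setdiff(unique(tax$primary_series), .primary_series)
  if (length(bad_primary) > 0) {
    abort(sprintf("unknown primary series: %s (allowed: %s)",
                  paste(bad_primary, collapse = ", "),
                  paste(.primary_series, collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  conflicts <- tax %>%
    distinct(.data$descriptor, .data$primary_series) %>%
    count(.data$descriptor) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf("descriptor(s) mapped to more than one primary series: %s",
                  paste(conflicts$descriptor, collapse = ", ")),
          class = "vitisaroma_conflict_error")
  }
  dup <- tax$descriptor[duplicated(tax$descriptor)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate descriptor row(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  has_secondary <- lengths(tax$secondary_series) > 0
  bad_parent <- has_secondary & !(tax$primary_series %in% .secondary_parents)
  if (any(bad_parent)) {
    abort(sprintf(
      "secondary series are only defined under %s; offending descriptor(s): %s",
      paste(.secondary_parents, collapse = "/"),
      paste(tax$descriptor[bad_parent], collapse = ", ")),
      class = "vitisaroma_validation_error")
  }
  # each secondary series must have a single consistent parent primary
  parent_map <- tibble(
    secondary = unlist(tax$secondary_series, use.names = FALSE) %||%
      character(0),
    parent = rep(tax$primary_series, lengths(tax$secondary_series))
  ) %>% distinct()
  multi <- parent_map %>% count(.data$secondary) %>% filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("secondary series with conflicting parent primaries: %s",
                  paste(multi$secondary, collapse = ", ")),
          class = "vitisaroma_conflict_error")
  }
  tax[, c("descriptor", "primary_series", "secondary_series")]
}

#' Read an aromatic-series taxonomy from a delimited file
#'
#' Expects UTF-8 CSV/TSV with header columns `descriptor`, `primary_series`
#' and optional `secondary_series` (pipe-separated).
#'
#' @param path Path to the file.
#' @return A validated taxonomy tibble.
#' @export
read_aroma_taxonomy <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vitisaroma_io_error")
  }
  raw <- read_delim_auto(path, col_types = readr::cols(
    descriptor = readr::col_character(),
    primary_series = readr::col_character(),
    secondary_series = readr::col_character()
  ))
  if (nrow(raw) == 0) {
    abort(sprintf("taxonomy file %s has no rows", path),
          class = "vitisaroma_validation_error")
  }
  as_aroma_taxonomy(raw)
}

#' Write an aromatic-series taxonomy to CSV
#'
#' @param taxonomy A validated taxonomy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aroma_taxonomy <- function(taxonomy, path) {
  tax <- as_aroma_taxonomy(taxonomy)
  out <- tax
  out$secondary_series <- join_tokens(out$secondary_series)
  readr::write_csv(out, path)
  invisible(path)
}

#' The default aromatic-series taxonomy
#'
#' Ships with the package and encodes the ten primary aromatic series used
#' for grape volatiles (herbaceous, floral, fruity, sweet, spicy, roasty,
#' fatty, earthy, balsamic, solvent) with the fruity, floral and sweet
#' primaries subdivided into 14, 13 and 5 secondary series respectively. The
#' named secondary series are the ones reported for table grapes (apple,
#' citrus, orange, lemon, grape, banana, strawberry and pineapple under
#' fruity; rose, geranium, violet, lavender and orange flower under floral;
#' honey and marshmallow under sweet); the remaining slots are explicit,
#' clearly labelled placeholders (`fruity_placeholder_1`, ...) that users
#' replace with their own descriptor panel.
#'
#' @return A validated taxonomy tibble.
#' @export
default_aroma_taxonomy <- function() {
  path <- system.file("extdata", "aroma_taxonomy.csv",
                      package = "vitisaroma", mustWork = TRUE)
  read_aroma_taxonomy(path)
}

#' Summarize the secondary-series structure of a taxonomy
#'
#' @param taxonomy A taxonomy tibble.
#' @return A tibble with one row per secondary series and its parent primary.
#' @export
secondary_parents <- function(taxonomy) {
  tax <- as_aroma_taxonomy(taxonomy)
  tibble(
    secondary = unlist(tax$secondary_series, use.names = FALSE) %||%
      character(0),
    parent = rep(tax$primary_series, lengths(tax$secondary_series))
  ) %>%
    distinct() %>%
    arrange(.data$parent, .data$secondary)
}
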