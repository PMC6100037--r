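#' Validate a compound library
#'
#' A compound library describes the volatile panel: one row per compound with
#' its chemical class, odor (perception) threshold in micrograms per kilogram
#' of berry matrix, and the odor descriptors reported for it in the flavor
#' literature. Odor thresholds must be strictly positive so that odor activity
#' values (concentration / threshold) are always defined.
#'
#' @param library A data frame with columns `compound_id`, `name`, `class`,
#'   `threshold_ug_per_kg` and `descriptors`. `descriptors` may be either a
#'   list-column of character vectors or a pipe-separated character column.
#' @return A validated tibble with `descriptors` as a list-column of
#'   case-folded descriptor tokens.
#' @export
as_compound_library <- function(library) {
  assert_columns(library,
                 c("compound_id", "name", "class", "threshold_ug_per_kg",
                   "descriptors"),
                 "compound library")
  lib <- as_tibble(library)
  if (!is.list(lib$descriptors)) {
    lib$descriptors <- split_tokens(as.character(lib$descriptors))
  } else {
    lib$descriptors <- lapply(lib$descriptors, fold_descriptor)
  }
  lib$compound_id <- as.character(lib$compound_id)
  lib$class <- as.character(lib$class)
  lib$threshold_ug_per_kg <- as.numeric(lib$threshold_ug_per_kg)

  dup <- lib$compound_id[duplicated(lib$compound_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate compound_id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  bad_class <- setdiff(unique(lib$class), .classes)
  if (length(bad_class) > 0) {
    abort(sprintf("unknown chemical class(es): %s (allowed: %s)",
                  paste(bad_class, collapse = ", "),
                  paste(.classes, collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  bad_thr <- which(!is.finite(lib$threshold_ug_per_kg) |
                     lib$threshold_ug_per_kg <= 0)
  if (length(bad_thr) > 0) {
    abort(sprintf(
      "odor threshold must be > 0; offending row(s): %s (compound %s)",
      paste(bad_thr, collapse = ", "),
      paste(lib$compound_id[bad_thr], collapse = ", ")),
      class = "vitisaroma_validation_error")
  }
  lib[, c("compound_id", "name", "class", "threshold_ug_per_kg",
          "descriptors")]
}

#' Read a compound library from a delimited file
#'
#' The file must be UTF-8 CSV or TSV with a header row and columns
#' `compound_id`, `name`, `class`, `threshold_ug_per_kg`, `descriptors`
#' (pipe-separated descriptor list, possibly empty).
#'
#' @param path Path to the file. The delimiter is inferred from the extension
#'   (`.tsv` reads as tab-separated, anything else as comma-separated).
#' @return A validated compound-library tibble (see [as_compound_library()]).
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vitisaroma_io_error")
  }
  raw <- read_delim_auto(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    name = readr::col_character(),
    class = readr::col_character(),
    threshold_ug_per_kg = readr::col_double(),
    descriptors = readr::col_character()
  ))
  as_compound_library(raw)
}

#' Write a compound library to CSV
#'
#' Inverse of [read_compound_library()]: descriptors are serialized as a
#' pipe-separated field, and a load/save/load round trip preserves all values.
#'
#' @param library A validated compound-library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  lib <- as_compound_library(library)
  out <- lib
  out$descriptors <- join_tokens(out$descriptors)
  readr::write_csv(out, path)
  invisible(path)
}

read_delim_auto <- function(path, col_types = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tryCatch(
    readr::read_delim(path, delim = delim, col_types = col_types,
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(
      sprintf("could not parse %s: %s", path, conditionMessage(e)),
      class = "vitisaroma_format_error")
  )
}

#' Resolve aromatic-series memberships of a compound panel
#'
#' Each compound inherits the union of the series of its descriptors: a
#' compound joins the primary series of every descriptor and, when a
#' descriptor belongs to one of the subdivided primaries (fruity, floral,
#' sweet), all of its secondary series simultaneously. A compound with, say,
#' banana, apple and strawberry descriptors therefore represents the fruity
#' primary series together with the banana, apple and strawberry secondary
#' series at its full odor activity value.
#'
#' Descriptors absent from the taxonomy produce a warning (not an error) and
#' are listed per compound in the `unmapped` column; compounds with no
#' descriptors get an empty membership.
#'
#' @param library A compound-library tibble.
#' @param taxonomy An aromatic-series taxonomy tibble
#'   (see [read_aroma_taxonomy()]).
#' @return A tibble with one row per compound and list-columns
#'   `primary_series`, `secondary_series`, `unmapped`.
#' @export
resolve_memberships <- function(library, taxonomy) {
  lib <- as_compound_library(library)
  tax <- as_aroma_taxonomy(taxonomy)
  primary_of <- setNames(tax$primary_series, tax$descriptor)
  secondary_of <- setNames(tax$secondary_series, tax$descriptor)

  rows <- lapply(seq_len(nrow(lib)), function(i) {
    d <- fold_descriptor(lib$descriptors[[i]])
    known <- d[d %in% names(primary_of)]
    unmapped <- setdiff(d, known)
    list(
      primary_series = sort(unique(unname(primary_of[known]))),
      secondary_series = sort(unique(unlist(secondary_of[known],
                                            use.names = FALSE))),
      unmapped = unmapped
    )
  })
  out <- tibble(
    compound_id = lib$compound_id,
    primary_series = lapply(rows, `[[`, "primary_series"),
    secondary_series = lapply(rows, function(r) {
      s <- r$secondary_series
      if (is.null(s)) character(0) else s
    }),
    unmapped = lapply(rows, `[[`, "unmapped")
  )
  all_unmapped <- unique(unlist(out$unmapped))
  if (length(all_unmapped) > 0) {
    warn(sprintf("descriptor(s) not in taxonomy (ignored): %s",
                 paste(all_unmapped, collapse = ", ")),
         class = "vitisaroma_unmapped_descriptors")
  }
  no_desc <- out$compound_id[lengths(lib$descriptors) == 0]
  if (length(no_desc) > 0) {
    warn(sprintf("compound(s) without descriptors have empty membership: %s",
                 paste(no_desc, collapse = ", ")),
         class = "vitisaroma_empty_membership")
  }
  out
}

#' Long view of series memberships
#'
#' Unnests the list-columns of [resolve_memberships()] into one row per
#' (compound, series) pair, tagged with the series level.
#'
#' @param memberships Output of [resolve_memberships()].
#' @return A tibble with columns `compound_id`, `level`, `series`.
#' @export
membership_long <- function(memberships) {
  assert_columns(memberships,
                 c("compound_id", "primary_series", "secondary_series"),
                 "memberships")
  prim <- tibble(
    compound_id = rep(memberships$compound_id,
                      lengths(memberships$primary_series)),
    level = "primary",
    series = unlist(memberships$primary_series, use.names = FALSE) %||%
      character(0)
  )
  sec <- tibble(
    compound_id = rep(memberships$compound_id,
                      lengths(memberships$secondary_series)),
    level = "secondary",
    series = unlist(memberships$secondary_series, use.names = FALSE) %||%
      character(0)
  )
  bind_rows(prim, sec)
}
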