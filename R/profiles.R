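#' Validate a long-format sample table
#'
#' Samples are stored in long format, one row per detected compound in one
#' (cultivar, tissue, replicate) sample. Compounds that were not detected in
#' a sample are simply absent and are treated as concentration 0 in all
#' downstream arithmetic (OAVs, series values, model features). Tissue is a
#' closed vocabulary (`pulp`, `skin`, `whole`): unknown tissue tokens are a
#' hard error, because a silent typo would corrupt the pulp/skin contrast the
#' analysis is built on.
#'
#' @param samples A data frame with columns `cultivar_id`, `tissue`,
#'   `replicate`, `compound_id`, `concentration_ug_per_kg`.
#' @param library Optional compound library; when given, every `compound_id`
#'   must exist in it.
#' @return A validated tibble.
#' @export
as_sample_table <- function(samples, library = NULL) {
  assert_columns(samples,
                 c("cultivar_id", "tissue", "replicate", "compound_id",
                   "concentration_ug_per_kg"),
                 "sample table")
  smp <- as_tibble(samples)
  smp$cultivar_id <- as.character(smp$cultivar_id)
  smp$tissue <- as.character(smp$tissue)
  smp$replicate <- as.integer(smp$replicate)
  smp$compound_id <- as.character(smp$compound_id)
  smp$concentration_ug_per_kg <- as.numeric(smp$concentration_ug_per_kg)

  bad_tissue <- setdiff(unique(smp$tissue), .tissues)
  if (length(bad_tissue) > 0) {
    abort(sprintf("unknown tissue token(s): %s (allowed: %s)",
                  paste(bad_tissue, collapse = ", "),
                  paste(.tissues, collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  if (any(!is.finite(smp$replicate) | smp$replicate < 1)) {
    abort("replicate must be a positive integer",
          class = "vitisaroma_validation_error")
  }
  neg <- which(!is.finite(smp$concentration_ug_per_kg) |
                 smp$concentration_ug_per_kg < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative or non-finite concentration in row(s): %s",
                  paste(head(neg, 5), collapse = ", ")),
          class = "vitisaroma_validation_error")
  }
  dup <- smp %>%
    count(.data$cultivar_id, .data$tissue, .data$replicate,
          .data$compound_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (sample, compound) row(s), first: cultivar %s %s replicate %d compound %s",
      dup$cultivar_id[1], dup$tissue[1], dup$replicate[1], dup$compound_id[1]),
      class = "vitisaroma_validation_error")
  }
  if (!is.null(library)) {
    lib <- as_compound_library(library)
    unknown <- setdiff(unique(smp$compound_id), lib$compound_id)
    if (length(unknown) > 0) {
      abort(sprintf("compound_id(s) not in library: %s",
                    paste(unknown, collapse = ", ")),
            class = "vitisaroma_reference_error")
    }
  }
  smp
}

#' Read a long-format sample table
#'
#' @param path CSV/TSV with columns `cultivar_id`, `tissue`, `replicate`,
#'   `compound_id`, `concentration_ug_per_kg`.
#' @param library Optional compound library used to check compound references.
#' @return A validated sample tibble.
#' @export
read_samples <- function(path, library = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vitisaroma_io_error")
  }
  raw <- read_delim_auto(path, col_types = readr::cols(
    cultivar_id = readr::col_character(),
    tissue = readr::col_character(),
    replicate = readr::col_integer(),
    compound_id = readr::col_character(),
    concentration_ug_per_kg = readr::col_double()
  ))
  as_sample_table(raw, library)
}

#' Write a sample table to CSV
#' @param samples A validated sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(as_sample_table(samples), path)
  invisible(path)
}

#' Validate and read maturity records
#'
#' One row per cultivar: total soluble solids (TSS, degrees Brix), titratable
#' acidity (TA, g/L), pH and mean berry weight (g). TA must be strictly
#' positive so the TSS/TA ripeness ratio is defined.
#'
#' @param maturity A data frame with columns `cultivar_id`, `tss_brix`,
#'   `ta_g_per_l`, `ph`, `berry_weight_g`.
#' @return A validated tibble.
#' @export
as_maturity_table <- function(maturity) {
  assert_columns(maturity,
                 c("cultivar_id", "tss_brix", "ta_g_per_l", "ph",
                   "berry_weight_g"),
                 "maturity table")
  mat <- as_tibble(maturity)
  mat$cultivar_id <- as.character(mat$cultivar_id)
  for (col in c("tss_brix", "ta_g_per_l", "ph", "berry_weight_g")) {
    mat[[col]] <- as.numeric(mat[[col]])
  }
  if (any(duplicated(mat$cultivar_id))) {
    abort("duplicate cultivar_id in maturity table",
          class = "vitisaroma_validation_error")
  }
  if (any(!is.finite(mat$tss_brix) | mat$tss_brix < 0)) {
    abort("tss_brix must be >= 0", class = "vitisaroma_validation_error")
  }
  if (any(!is.finite(mat$ta_g_per_l) | mat$ta_g_per_l <= 0)) {
    abort("ta_g_per_l must be > 0 (TSS/TA must be defined)",
          class = "vitisaroma_validation_error")
  }
  mat
}

#' @rdname as_maturity_table
#' @param path CSV/TSV path.
#' @export
read_maturity <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vitisaroma_io_error")
  }
  as_maturity_table(read_delim_auto(path))
}

#' Screen cultivars for ripeness
#'
#' Table grapes are conventionally considered ripe at total soluble solids of
#' at least 16 degrees Brix (OIV resolution VITI 1/2008). The report carries
#' TSS, TA, the TSS/TA sugar:acid ratio and a `ripe` flag; unripe cultivars
#' are flagged, never removed -- dropping them is a pipeline option, not a
#' side effect of screening. Concentration data are never touched.
#'
#' @param maturity A maturity tibble.
#' @param cultivars Optional character vector of cultivars that must all be
#'   present (e.g. the cultivars of a sample table); a missing record is an
#'   error naming the cultivar.
#' @param tss_ripe Ripeness threshold in degrees Brix (default 16).
#' @return A tibble with columns `cultivar_id`, `tss_brix`, `ta_g_per_l`,
#'   `tss_ta_ratio`, `ripe`.
#' @export
screen_maturity <- function(maturity, cultivars = NULL, tss_ripe = 16) {
  mat <- as_maturity_table(maturity)
  assert_scalar_number(tss_ripe, "tss_ripe", lower = 0)
  if (!is.null(cultivars)) {
    missing <- setdiff(unique(cultivars), mat$cultivar_id)
    if (length(missing) > 0) {
      abort(sprintf("no maturity record for cultivar(s): %s",
                    paste(missing, collapse = ", ")),
            class = "vitisaroma_reference_error")
    }
  }
  mat %>%
    mutate(tss_ta_ratio = .data$tss_brix / .data$ta_g_per_l,
           ripe = .data$tss_brix >= tss_ripe) %>%
    select("cultivar_id", "tss_brix", "ta_g_per_l", "tss_ta_ratio", "ripe")
}

#' Combine pulp and skin profiles into whole-berry profiles
#'
#' Whole-berry concentrations are a convex mass-weighted blend of the two
#' tissues: `whole = f * skin + (1 - f) * pulp` per compound, where `f` is
#' the skin mass fraction (default 0.2). Compounds absent from one tissue
#' contribute 0 from that tissue. The blend is linear by construction, and
#' the original pulp and skin samples are retained alongside the new
#' `whole` rows.
#'
#' @param samples A sample tibble containing pulp and skin rows.
#' @param skin_mass_fraction Proportion of berry mass contributed by skin,
#'   in `[0, 1]`.
#' @return The sample tibble with `whole` rows appended.
#' @export
combine_tissues <- function(samples, skin_mass_fraction = 0.2) {
  smp <- as_sample_table(samples)
  assert_scalar_number(skin_mass_fraction, "skin_mass_fraction", 0, 1)
  pulp <- filter(smp, .data$tissue == "pulp")
  skin <- filter(smp, .data$tissue == "skin")
  pulp_keys <- distinct(pulp, .data$cultivar_id, .data$replicate)
  skin_keys <- distinct(skin, .data$cultivar_id, .data$replicate)
  unmatched <- bind_rows(
    anti_join(pulp_keys, skin_keys, by = c("cultivar_id", "replicate")) %>%
      mutate(missing = "skin"),
    anti_join(skin_keys, pulp_keys, by = c("cultivar_id", "replicate")) %>%
      mutate(missing = "pulp")
  )
  if (nrow(unmatched) > 0) {
    abort(paste0(
      "unmatched pulp/skin replicate pair(s): ",
      paste(sprintf("%s r%d (missing %s)", unmatched$cultivar_id,
                    unmatched$replicate, unmatched$missing),
            collapse = "; ")),
      class = "vitisaroma_validation_error")
  }
  if (nrow(pulp_keys) == 0) {
    abort("no pulp/skin pairs to combine",
          class = "vitisaroma_validation_error")
  }
  whole <- dplyr::full_join(
    pulp %>% select("cultivar_id", "replicate", "compound_id",
                    pulp = "concentration_ug_per_kg"),
    skin %>% select("cultivar_id", "replicate", "compound_id",
                    skin = "concentration_ug_per_kg"),
    by = c("cultivar_id", "replicate", "compound_id")
  ) %>%
    mutate(
      pulp = dplyr::coalesce(.data$pulp, 0),
      skin = dplyr::coalesce(.data$skin, 0),
      concentration_ug_per_kg =
        skin_mass_fraction * .data$skin +
        (1 - skin_mass_fraction) * .data$pulp,
      tissue = "whole"
    ) %>%
    filter(.data$concentration_ug_per_kg > 0) %>%
    select("cultivar_id", "tissue", "replicate", "compound_id",
           "concentration_ug_per_kg")
  bind_rows(filter(smp, .data$tissue != "whole"), whole) %>%
    arrange(.data$cultivar_id, .data$tissue, .data$replicate,
            .data$compound_id)
}
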