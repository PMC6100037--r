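#' Compute odor activity values
#'
#' The odor activity value (OAV) of a compound in a sample is its
#' concentration divided by its odor threshold; values above 1 mean the
#' compound is present above its perception threshold and contributes to the
#' perceived aroma. OAVs are dimensionless, non-negative and always finite
#' because library thresholds are strictly positive; an absent (not
#' detected) compound has OAV 0.
#'
#' @param samples A sample tibble.
#' @param library A compound library supplying odor thresholds.
#' @return A tibble with one row per (sample, detected compound):
#'   `cultivar_id`, `tissue`, `replicate`, `compound_id`,
#'   `concentration_ug_per_kg`, `oav`.
#' @export
compute_oav <- function(samples, library) {
  smp <- as_sample_table(samples, library)
  lib <- as_compound_library(library)
  smp %>%
    left_join(select(lib, "compound_id", "threshold_ug_per_kg"),
              by = "compound_id") %>%
    mutate(oav = .data$concentration_ug_per_kg / .data$threshold_ug_per_kg) %>%
    select("cultivar_id", "tissue", "replicate", "compound_id",
           "concentration_ug_per_kg", "oav")
}

#' Replicate-mean OAVs
#'
#' Aggregated view of an OAV table: mean and SD over replicates per
#' (cultivar, tissue, compound). Compounds absent from some replicates count
#' as 0 in those replicates, so means are over the full replicate count of
#' each (cultivar, tissue).
#'
#' @param oav Output of [compute_oav()].
#' @return A tibble with `mean_oav` and `sd_oav`.
#' @export
oav_replicate_means <- function(oav) {
  assert_columns(oav, c("cultivar_id", "tissue", "replicate", "compound_id",
                        "oav"), "OAV table")
  n_rep <- oav %>%
    distinct(.data$cultivar_id, .data$tissue, .data$replicate) %>%
    count(.data$cultivar_id, .data$tissue, name = "n_replicates")
  oav %>%
    group_by(.data$cultivar_id, .data$tissue, .data$compound_id) %>%
    summarise(sum_oav = sum(.data$oav), sumsq = sum(.data$oav^2),
              .groups = "drop") %>%
    left_join(n_rep, by = c("cultivar_id", "tissue")) %>%
    mutate(
      mean_oav = .data$sum_oav / .data$n_replicates,
      sd_oav = sqrt(pmax(0, (.data$sumsq -
                               .data$n_replicates * .data$mean_oav^2) /
                           pmax(1, .data$n_replicates - 1)))
    ) %>%
    select("cultivar_id", "tissue", "compound_id", "n_replicates",
           "mean_oav", "sd_oav")
}

#' Aroma-active compounds
#'
#' A compound is aroma-active in a sample when its OAV strictly exceeds the
#' cutoff (default 1). Returns both the per-sample active records and pooled
#' sets: per tissue (the union over all samples of that tissue) and overall.
#'
#' @param oav Output of [compute_oav()].
#' @param cutoff Activity cutoff; strict inequality `oav > cutoff`.
#' @return A list with tibbles `per_sample`, `per_tissue` and `overall`.
#' @export
active_compounds <- function(oav, cutoff = 1) {
  assert_columns(oav, c("cultivar_id", "tissue", "replicate", "compound_id",
                        "oav"), "OAV table")
  assert_scalar_number(cutoff, "cutoff", lower = 0)
  per_sample <- oav %>%
    filter(.data$oav > cutoff) %>%
    select("cultivar_id", "tissue", "replicate", "compound_id", "oav")
  list(
    per_sample = per_sample,
    per_tissue = distinct(per_sample, .data$tissue, .data$compound_id) %>%
      arrange(.data$tissue, .data$compound_id),
    overall = distinct(per_sample, .data$compound_id) %>%
      arrange(.data$compound_id)
  )
}

#' Aromatic-series values
#'
#' The value of an aromatic series in a sample is the sum of the OAVs of its
#' member compounds. A compound belonging to several series (one primary and
#' possibly several secondary series via its descriptors) contributes its
#' full OAV to each of them -- the double counting is intentional and
#' mirrors how descriptor-based series are constructed.
#'
#' @param oav Output of [compute_oav()].
#' @param memberships Output of [resolve_memberships()].
#' @param level `"primary"` or `"secondary"`.
#' @return A tibble `cultivar_id`, `tissue`, `replicate`, `level`, `series`,
#'   `value`, complete over all series of the requested level that have at
#'   least one member compound on the panel (value 0 where no member was
#'   detected).
#' @export
series_values <- function(oav, memberships,
                          level = c("primary", "secondary")) {
  level <- match.arg(level)
  assert_columns(oav, c("cultivar_id", "tissue", "replicate", "compound_id",
                        "oav"), "OAV table")
  members <- membership_long(memberships) %>% filter(.data$level == !!level)
  samples_keys <- distinct(oav, .data$cultivar_id, .data$tissue,
                           .data$replicate)
  all_series <- sort(unique(members$series))
  if (length(all_series) == 0) {
    return(tibble(cultivar_id = character(0), tissue = character(0),
                  replicate = integer(0), level = character(0),
                  series = character(0), value = numeric(0)))
  }
  sums <- oav %>%
    inner_join(members, by = "compound_id",
               relationship = "many-to-many") %>%
    group_by(.data$cultivar_id, .data$tissue, .data$replicate,
             .data$series) %>%
    summarise(value = sum(.data$oav), .groups = "drop")
  tidyr::crossing(samples_keys, series = all_series) %>%
    left_join(sums, by = c("cultivar_id", "tissue", "replicate", "series")) %>%
    mutate(value = dplyr::coalesce(.data$value, 0), level = level) %>%
    select("cultivar_id", "tissue", "replicate", "level", "series",
           "value") %>%
    arrange(.data$cultivar_id, .data$tissue, .data$replicate, .data$series)
}

#' Replicate means and SDs of series values
#'
#' @param series_profile Output of [series_values()].
#' @return A tibble per (cultivar, tissue, series) with `mean_value` and
#'   `sd_value` over replicates.
#' @export
summarize_series <- function(series_profile) {
  assert_columns(series_profile,
                 c("cultivar_id", "tissue", "replicate", "level", "series",
                   "value"), "series profile")
  series_profile %>%
    group_by(.data$cultivar_id, .data$tissue, .data$level, .data$series) %>%
    summarise(n_replicates = n(), mean_value = mean(.data$value),
              sd_value = sd(.data$value), .groups = "drop")
}

#' Active aromatic series
#'
#' A series is active when its value reaches the cutoff (inclusive,
#' default 1) in at least one sample; series below the cutoff everywhere
#' carry no perceptible aroma. Note the asymmetry with compound activity:
#' compound activity is the strict `OAV > 1`, series activity is
#' `value >= 1` (values below 1 define inactivity).
#'
#' @param series_profile Output of [series_values()].
#' @param cutoff Inclusive activity cutoff (default 1).
#' @return A tibble of active series with the number of samples at or above
#'   the cutoff and the maximum value observed.
#' @export
active_series <- function(series_profile, cutoff = 1) {
  assert_columns(series_profile,
                 c("cultivar_id", "tissue", "replicate", "level", "series",
                   "value"), "series profile")
  assert_scalar_number(cutoff, "cutoff", lower = 0)
  series_profile %>%
    group_by(.data$level, .data$series) %>%
    summarise(n_active_samples = sum(.data$value >= cutoff),
              max_value = max(.data$value), .groups = "drop") %>%
    filter(.data$n_active_samples >= 1) %>%
    arrange(.data$level, .data$series)
}

#' Assemble a per-cultivar aroma fingerprint
#'
#' A fingerprint is the radial-plot-ready record of one cultivar: the
#' replicate-mean primary-series values per tissue, and the replicate-mean
#' secondary-series values (fruity/floral/sweet subdivisions) per tissue.
#' Both pulp and skin must be present. An optional display transform can
#' mark selected series for halving in rendered plots (useful when one
#' series dwarfs the rest); it affects only the `display_scale` metadata
#' column -- stored values are never altered.
#'
#' @param primary_profile,secondary_profile Outputs of [series_values()] at
#'   the respective level, covering at least tissues pulp and skin.
#' @param cultivar_id The cultivar to fingerprint.
#' @param halve_series Optional character vector of series names to mark
#'   with `display_scale = 0.5`.
#' @return A list of class `aroma_fingerprint` with elements `cultivar_id`,
#'   `primary` and `secondary` (tibbles `tissue`, `series`, `value`,
#'   `display_scale`).
#' @export
build_fingerprint <- function(primary_profile, secondary_profile,
                              cultivar_id, halve_series = NULL) {
  one <- function(profile, what) {
    prof <- filter(profile, .data$cultivar_id == !!cultivar_id)
    if (nrow(prof) == 0) {
      abort(sprintf("no %s series data for cultivar %s", what, cultivar_id),
            class = "vitisaroma_reference_error")
    }
    missing <- setdiff(c("pulp", "skin"), unique(prof$tissue))
    if (length(missing) > 0) {
      abort(sprintf("fingerprint for %s needs tissue(s): %s",
                    cultivar_id, paste(missing, collapse = ", ")),
            class = "vitisaroma_validation_error")
    }
    summarize_series(prof) %>%
      filter(.data$tissue %in% c("pulp", "skin")) %>%
      mutate(display_scale =
               if_else(.data$series %in% (halve_series %||% character(0)),
                       0.5, 1)) %>%
      select("tissue", "series", value = "mean_value", "display_scale")
  }
  structure(list(
    cultivar_id = cultivar_id,
    primary = one(primary_profile, "primary"),
    secondary = one(secondary_profile, "secondary")
  ), class = "aroma_fingerprint")
}

#' @export
print.aroma_fingerprint <- function(x, ...) {
  cat(sprintf("<aroma_fingerprint> cultivar %s\n", x$cultivar_id))
  top <- x$primary %>% arrange(desc(.data$value)) %>% head(4)
  cat("  dominant primary series:",
      paste(sprintf("%s (%s, %.1f)", top$series, top$tissue,
                    top$value), collapse = ", "), "\n")
  invisible(x)
}

#' Export a fingerprint as a JSON record
#'
#' @param fingerprint An `aroma_fingerprint`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_fingerprint <- function(fingerprint, path = NULL) {
  stopifnot(inherits(fingerprint, "aroma_fingerprint"))
  js <- jsonlite::toJSON(list(
    cultivar_id = fingerprint$cultivar_id,
    primary = fingerprint$primary,
    secondary = fingerprint$secondary
  ), dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Wide sample-by-series or sample-by-compound matrix
#'
#' Convenience pivot used for clustering and heatmaps.
#'
#' @param x A series profile or OAV table.
#' @param values Name of the value column (`"value"` or `"oav"`).
#' @return A wide tibble, one row per (cultivar, tissue, replicate).
#' @export
pivot_profile_wide <- function(x, values = c("value", "oav")) {
  values <- match.arg(values)
  key <- if (values == "value") "series" else "compound_id"
  x %>%
    select("cultivar_id", "tissue", "replicate", all_of(c(key, values))) %>%
    tidyr::pivot_wider(names_from = all_of(key),
                       values_from = all_of(values), values_fill = 0)
}
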