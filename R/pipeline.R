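#' Cultivar-level feature matrix for liking regression
#'
#' Builds the X block of the liking model. The default feature block is the
#' replicate-mean whole-berry concentration of every compound (whole-berry
#' rows are derived with [combine_tissues()] if not already present). The
#' alternative `"series"` block uses replicate-mean whole-berry aromatic
#' series values (primary and secondary together) as features instead.
#'
#' @param samples A sample tibble with pulp and skin (or whole) rows.
#' @param library The compound library.
#' @param feature_block `"concentration"` or `"series"`.
#' @param taxonomy Taxonomy, required for the series block.
#' @param skin_mass_fraction Skin mass fraction for the whole-berry blend.
#' @param tissue Tissue whose profiles become features (default whole).
#' @param per_replicate Keep one row per replicate instead of cultivar
#'   means (used at prediction time).
#' @return A list with `x` (matrix, rownames = cultivar ids or
#'   cultivar/replicate keys) and `info` (tibble of row keys).
#' @export
liking_features <- function(samples, library,
                            feature_block = c("concentration", "series"),
                            taxonomy = NULL, skin_mass_fraction = 0.2,
                            tissue = "whole", per_replicate = FALSE) {
  feature_block <- match.arg(feature_block)
  smp <- as_sample_table(samples, library)
  if (!tissue %in% unique(smp$tissue)) {
    if (tissue == "whole") {
      smp <- combine_tissues(smp, skin_mass_fraction)
    } else {
      abort(sprintf("tissue %s not present in samples", tissue),
            class = "vitisaroma_validation_error")
    }
  }
  smp <- filter(smp, .data$tissue == !!tissue)
  lib <- as_compound_library(library)

  if (feature_block == "concentration") {
    long <- smp %>%
      select("cultivar_id", "replicate", "compound_id",
             value = "concentration_ug_per_kg")
    vars <- lib$compound_id
  } else {
    if (is.null(taxonomy)) {
      abort("the series feature block requires a taxonomy",
            class = "vitisaroma_validation_error")
    }
    memberships <- suppressWarnings(resolve_memberships(lib, taxonomy))
    oav <- compute_oav(smp, lib)
    prof <- bind_rows(
      series_values(oav, memberships, "primary"),
      series_values(oav, memberships, "secondary")
    )
    long <- prof %>%
      mutate(series = paste(.data$level, .data$series, sep = ":")) %>%
      select("cultivar_id", "replicate", "series", "value")
    names(long)[names(long) == "series"] <- "compound_id"
    vars <- sort(unique(long$compound_id))
  }

  if (!per_replicate) {
    n_rep <- long %>%
      distinct(.data$cultivar_id, .data$replicate) %>%
      count(.data$cultivar_id, name = "n_rep")
    long <- long %>%
      group_by(.data$cultivar_id, .data$compound_id) %>%
      summarise(value = sum(.data$value), .groups = "drop") %>%
      left_join(n_rep, by = "cultivar_id") %>%
      mutate(value = .data$value / .data$n_rep, replicate = NA_integer_) %>%
      select(-"n_rep")
  }
  keys <- distinct(long, .data$cultivar_id, .data$replicate) %>%
    arrange(.data$cultivar_id, .data$replicate)
  wide <- long %>%
    tidyr::pivot_wider(names_from = "compound_id", values_from = "value",
                       values_fill = 0)
  wide <- wide[match(
    paste(keys$cultivar_id, keys$replicate),
    paste(wide$cultivar_id, wide$replicate)), , drop = FALSE]
  present <- intersect(vars, names(wide))
  x <- matrix(0, nrow(wide), length(vars),
              dimnames = list(NULL, vars))
  x[, present] <- as.matrix(wide[, present, drop = FALSE])
  rownames(x) <- if (per_replicate) {
    paste(keys$cultivar_id, keys$replicate, sep = "/")
  } else {
    keys$cultivar_id
  }
  list(x = x, info = keys)
}

#' Train the consumer-liking pipeline
#'
#' End-to-end training on the scored ("popular") cultivar block:
#' (1) build cultivar-mean whole-berry features; (2) screen strong
#' multivariate outliers with PCA / Hotelling's T2 at the 99% limit and
#' remove them in a single pass; (3) choose the orthogonal-component count
#' by seven-fold cross-validation; (4) fit the OPLS model; (5) run the
#' permutation test. A model with cross-validated Q2Y at or below
#' `q2_good` (default 0.5, the conventional "good predictive ability"
#' line) is flagged ineffective: downstream key-compound selection is
#' blocked unless explicitly overridden.
#'
#' @param samples Sample tibble for the training cultivars (pulp + skin, or
#'   whole).
#' @param scores Tibble with columns `cultivar_id`, `liking_score` (1--5
#'   scale), one row per training cultivar.
#' @param library The compound library.
#' @param feature_block `"concentration"` (default) or `"series"`.
#' @param taxonomy Required for the series block.
#' @param skin_mass_fraction Whole-berry blend fraction.
#' @param folds Cross-validation folds (default 7); needs at least `folds`
#'   training cultivars.
#' @param n_ortho_max,min_improvement Component-selection rule (see
#'   [cross_validate_opls()]).
#' @param alpha Hotelling flagging level (default 0.01).
#' @param screen Run the outlier screen (default TRUE).
#' @param n_perm Permutations for validation (default 200; 0 skips the
#'   permutation test).
#' @param q2_good Effectiveness threshold on Q2Y.
#' @param seed Seed controlling folds and permutations.
#' @return An object of class `liking_pipeline`.
#' @export
train_liking_model <- function(samples, scores, library,
                               feature_block = c("concentration", "series"),
                               taxonomy = NULL, skin_mass_fraction = 0.2,
                               folds = 7, n_ortho_max = 9,
                               min_improvement = 0.01, alpha = 0.01,
                               screen = TRUE, n_perm = 200, q2_good = 0.5,
                               seed = 1) {
  feature_block <- match.arg(feature_block)
  assert_columns(scores, c("cultivar_id", "liking_score"), "scores")
  scores <- as_tibble(scores)
  if (any(!is.finite(scores$liking_score) | scores$liking_score < 1 |
            scores$liking_score > 5)) {
    abort("liking scores must lie on the 1-5 scale",
          class = "vitisaroma_validation_error")
  }
  if (nrow(scores) < folds) {
    abort(sprintf(
      "need at least %d scored training cultivars for %d-fold cross-validation (got %d)",
      folds, folds, nrow(scores)),
      class = "vitisaroma_validation_error")
  }
  feats <- liking_features(samples, library, feature_block, taxonomy,
                           skin_mass_fraction)
  missing <- setdiff(scores$cultivar_id, rownames(feats$x))
  if (length(missing) > 0) {
    abort(sprintf("no samples for scored cultivar(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vitisaroma_reference_error")
  }
  x <- feats$x[scores$cultivar_id, , drop = FALSE]
  y <- scores$liking_score

  screen_result <- NULL
  removed <- character(0)
  if (screen) {
    screen_result <- pca_hotelling_screen(x, alpha = alpha)
    removed <- screen_result$scores$row[screen_result$scores$flagged]
    if (length(removed) > 0) {
      keep <- !(rownames(x) %in% removed)
      if (sum(keep) < folds) {
        abort("outlier screening left fewer cultivars than folds",
              class = "vitisaroma_validation_error")
      }
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
  }

  cv <- withCallingHandlers(
    cross_validate_opls(x, y, folds = folds, n_ortho_max = n_ortho_max,
                        min_improvement = min_improvement, seed = seed),
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
  model <- withCallingHandlers(
    fit_opls(x, y, cv$chosen_n_ortho),
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
  model$cv <- list(folds = folds, q2y = cv$q2y, rmsecv = cv$rmsecv)

  permutation <- NULL
  if (n_perm > 0) {
    permutation <- opls_permutation(x, y, n_perm = n_perm,
                                    n_ortho = cv$chosen_n_ortho,
                                    folds = folds, seed = seed)
  }
  effective <- is.finite(cv$q2y) && cv$q2y > q2_good
  if (!effective) {
    warn(sprintf(
      "model ineffective: Q2Y = %.3f <= %.2f; key-compound selection is blocked unless overridden",
      cv$q2y, q2_good),
      class = "vitisaroma_model_ineffective")
  }
  structure(list(
    model = model,
    cv = cv,
    screen = screen_result,
    removed_cultivars = removed,
    permutation = permutation,
    effective = effective,
    feature_block = feature_block,
    taxonomy = taxonomy,
    skin_mass_fraction = skin_mass_fraction,
    q2_good = q2_good,
    training_cultivars = rownames(x),
    seed = seed
  ), class = "liking_pipeline")
}

#' @export
print.liking_pipeline <- function(x, ...) {
  cat(sprintf(
    "<liking_pipeline> %s features; %d training cultivars (%d removed as outliers)\n",
    x$feature_block, length(x$training_cultivars),
    length(x$removed_cultivars)))
  cat(sprintf("  model %s: R2Y %.3f | Q2Y %.3f | RMSECV %.4g | %s\n",
              x$model$n_components_label, x$model$stats$r2y, x$cv$q2y,
              x$cv$rmsecv,
              if (x$effective) "effective" else "INEFFECTIVE"))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation (n = %d): Q2 intercept %.3f, p = %.3g\n",
                x$permutation$n_perm, x$permutation$q2_intercept,
                x$permutation$p_value))
  }
  invisible(x)
}

#' Quality bin of a liking score
#'
#' The four aroma-quality groups on the 1--5 liking scale: poor below 3.5,
#' average in `[3.5, 4.0)`, good in `[4.0, 4.5]`, excellent above 4.5. The
#' published group definitions ("4.0-4.5", "> 4.5") leave the boundary
#' points open; the bins here close them deterministically so every finite
#' score maps to exactly one bin, with 4.5 counted as good.
#'
#' @param score Numeric vector of liking scores.
#' @return A factor with levels poor, average, good, excellent.
#' @export
quality_bin <- function(score) {
  cut(score, breaks = c(-Inf, 3.5, 4.0, 4.5, Inf),
      labels = c("poor", "average", "good", "excellent"),
      right = FALSE) -> bins
  # the published "good" band is closed at 4.5: reassign exact 4.5
  bins[!is.na(score) & score == 4.5] <- "good"
  bins
}

#' Predict consumer liking for unscored cultivars
#'
#' Each replicate's whole-berry profile is predicted separately and the
#' per-cultivar score is the mean of its replicate predictions; the quality
#' bin is assigned from the mean.
#'
#' @param pipeline A fitted [train_liking_model()] pipeline.
#' @param samples Sample tibble for the cultivars to predict.
#' @param library The compound library (must cover the model's variables
#'   for the concentration block).
#' @return A tibble with `cultivar_id`, `predicted_score`, `quality_bin`,
#'   `n_replicates` and a `replicate_scores` list-column.
#' @export
predict_liking <- function(pipeline, samples, library) {
  stopifnot(inherits(pipeline, "liking_pipeline"))
  feats <- liking_features(samples, library, pipeline$feature_block,
                           pipeline$taxonomy,
                           pipeline$skin_mass_fraction,
                           per_replicate = TRUE)
  preds <- predict(pipeline$model, feats$x)
  tibble(cultivar_id = feats$info$cultivar_id,
         replicate = feats$info$replicate,
         score = preds) %>%
    group_by(.data$cultivar_id) %>%
    summarise(predicted_score = mean(.data$score),
              n_replicates = n(),
              replicate_scores = list(.data$score),
              .groups = "drop") %>%
    mutate(quality_bin = quality_bin(.data$predicted_score)) %>%
    select("cultivar_id", "predicted_score", "quality_bin",
           "n_replicates", "replicate_scores")
}

#' Select key compounds by VIP
#'
#' Key compounds are the variables with VIP above the cutoff (default 1,
#' the greater-than-one rule), with their relationship direction taken from
#' the sign of the model regression vector and an `is_active` flag marking
#' whether the compound is aroma-active (pooled OAV > 1 in at least one
#' sample). Selection is blocked for an ineffective model (cross-validated
#' Q2Y at or below the effectiveness threshold) unless
#' `override_ineffective = TRUE`.
#'
#' @param pipeline A fitted pipeline with the concentration feature block.
#' @param oav OAV table from [compute_oav()] used for the activity flag.
#' @param vip_cutoff VIP selection cutoff (default 1).
#' @param type VIP variant passed to [vip()].
#' @param override_ineffective Allow selection from an ineffective model.
#' @return A tibble `compound_id`, `vip`, `direction`, `is_active`, sorted
#'   by decreasing VIP.
#' @export
select_key_compounds <- function(pipeline, oav, vip_cutoff = 1,
                                 type = "total",
                                 override_ineffective = FALSE) {
  stopifnot(inherits(pipeline, "liking_pipeline"))
  if (!pipeline$effective && !override_ineffective) {
    abort(sprintf(
      "model is ineffective (Q2Y = %.3f <= %.2f): key-compound selection blocked (set override_ineffective = TRUE to force)",
      pipeline$cv$q2y, pipeline$q2_good),
      class = "vitisaroma_model_ineffective")
  }
  scores <- vip(pipeline$model, type = type)
  active <- active_compounds(oav)$overall$compound_id
  scores %>%
    filter(.data$vip > vip_cutoff) %>%
    mutate(is_active = .data$variable %in% active) %>%
    select(compound_id = "variable", "vip", "direction", "is_active") %>%
    arrange(desc(.data$vip))
}

#' Assign aroma combinations
#'
#' Groups cultivars by the joint content of their liking-related key
#' volatiles. For each cultivar the whole-berry replicate-mean
#' concentrations of positively and negatively related key compounds are
#' summed into `(P, N)`; cultivars are partitioned into `n_groups` by
#' seeded k-means on the UV-scaled `(P, N)` plane, and groups are labelled
#' I, II, ... in increasing order of total key-compound content `P + N`.
#'
#' @param reports Liking reports from [predict_liking()] (or any tibble
#'   with `cultivar_id`), one row per cultivar to group.
#' @param key_compounds Key-compound table from [select_key_compounds()].
#' @param samples Sample tibble covering the report cultivars.
#' @param library The compound library.
#' @param n_groups Number of combinations (default 5).
#' @param skin_mass_fraction Whole-berry blend fraction.
#' @param seed Seed for k-means initialization.
#' @return `reports` with columns `positive_content`, `negative_content`
#'   and `aroma_combination` (factor I..) appended; the per-group summary
#'   is attached as attribute `"combination_summary"`.
#' @export
assign_aroma_combinations <- function(reports, key_compounds, samples,
                                      library, n_groups = 5,
                                      skin_mass_fraction = 0.2, seed = 1) {
  assert_columns(reports, "cultivar_id", "reports")
  assert_columns(key_compounds, c("compound_id", "direction"),
                 "key compounds")
  if (n_groups < 1) {
    abort("n_groups must be >= 1", class = "vitisaroma_validation_error")
  }
  if (nrow(reports) < n_groups) {
    abort(sprintf("fewer cultivars (%d) than groups (%d)",
                  nrow(reports), n_groups),
          class = "vitisaroma_validation_error")
  }
  feats <- liking_features(samples, library, "concentration",
                           skin_mass_fraction = skin_mass_fraction)
  missing <- setdiff(reports$cultivar_id, rownames(feats$x))
  if (length(missing) > 0) {
    abort(sprintf("no samples for cultivar(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vitisaroma_reference_error")
  }
  x <- feats$x[reports$cultivar_id, , drop = FALSE]
  pos <- key_compounds$compound_id[key_compounds$direction == "positive"]
  neg <- key_compounds$compound_id[key_compounds$direction == "negative"]
  p_sum <- rowSums(x[, intersect(pos, colnames(x)), drop = FALSE])
  n_sum <- rowSums(x[, intersect(neg, colnames(x)), drop = FALSE])

  if (n_groups == 1) {
    cluster <- rep(1L, nrow(reports))
  } else {
    pn <- cbind(P = p_sum, N = n_sum)
    keep <- apply(pn, 2, sd) > 0
    pn_scaled <- if (any(keep)) scale(pn[, keep, drop = FALSE]) else pn
    cluster <- with_seed(seed,
                         kmeans(pn_scaled, centers = n_groups,
                                nstart = 25)$cluster)
  }
  total <- p_sum + n_sum
  group_order <- order(vapply(seq_len(max(cluster)), function(g) {
    mean(total[cluster == g])
  }, numeric(1)))
  relabel <- match(cluster, group_order)
  labels <- roman_labels(n_groups)
  out <- reports %>%
    mutate(positive_content = unname(p_sum),
           negative_content = unname(n_sum),
           aroma_combination = factor(labels[relabel], levels = labels))
  summary <- out %>%
    group_by(.data$aroma_combination) %>%
    summarise(n_cultivars = n(),
              mean_positive = mean(.data$positive_content),
              mean_negative = mean(.data$negative_content),
              .groups = "drop")
  attr(out, "combination_summary") <- summary
  out
}

#' Hierarchical clustering of series profiles
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances of
#' UV-scaled values, both configurable) of replicate-mean aromatic-series
#' profiles, cut at `k` clusters, with the per-cluster mean series values
#' as a heatmap-ready matrix.
#'
#' @param series_profile Output of [series_values()]; it is filtered to
#'   `tissue` before clustering.
#' @param k Number of clusters (at most the number of cultivars).
#' @param tissue Tissue to cluster (default whole if present, else the
#'   single tissue in the profile).
#' @param method,metric Linkage and distance (defaults `ward.D2`,
#'   `euclidean`).
#' @return A list of class `hca_clusters`: `labels` (tibble `cultivar_id`,
#'   `cluster`), `means` (cluster x series tibble of mean values),
#'   `hclust`, `k`, `tissue`.
#' @export
hca_clusters <- function(series_profile, k, tissue = NULL,
                         method = "ward.D2", metric = "euclidean") {
  assert_columns(series_profile,
                 c("cultivar_id", "tissue", "replicate", "level", "series",
                   "value"), "series profile")
  tissues <- unique(series_profile$tissue)
  if (is.null(tissue)) {
    tissue <- if ("whole" %in% tissues) "whole" else tissues[1]
  }
  prof <- filter(series_profile, .data$tissue == !!tissue)
  if (nrow(prof) == 0) {
    abort(sprintf("no series data for tissue %s", tissue),
          class = "vitisaroma_validation_error")
  }
  means <- summarize_series(prof)
  wide <- means %>%
    select("cultivar_id", "series", "mean_value") %>%
    tidyr::pivot_wider(names_from = "series", values_from = "mean_value",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cultivar_id
  if (k > nrow(m)) {
    abort(sprintf("k (%d) exceeds the number of cultivars (%d)",
                  k, nrow(m)),
          class = "vitisaroma_validation_error")
  }
  scaled <- withCallingHandlers(
    uv_scale(m)$x,
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
  hc <- hclust(dist(scaled, method = metric), method = method)
  cl <- cutree(hc, k = k)
  cluster_means <- tibble(cultivar_id = rownames(m),
                          cluster = unname(cl)) %>%
    left_join(means %>% select("cultivar_id", "series", "mean_value"),
              by = "cultivar_id") %>%
    group_by(.data$cluster, .data$series) %>%
    summarise(mean_value = mean(.data$mean_value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "series", values_from = "mean_value")
  structure(list(
    labels = tibble(cultivar_id = rownames(m), cluster = unname(cl)),
    means = cluster_means,
    hclust = hc,
    k = k,
    tissue = tissue
  ), class = "hca_clusters")
}

#' @export
print.hca_clusters <- function(x, ...) {
  cat(sprintf("<hca_clusters> %s tissue, k = %d: sizes %s\n", x$tissue, x$k,
              paste(table(x$labels$cluster), collapse = ", ")))
  invisible(x)
}
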