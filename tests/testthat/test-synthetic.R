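test_that("panel generation is deterministic and respects class composition", {
  cfg <- cohort_config(seed = 9)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 100)
  # class histogram tracks the configured proportions within rounding
  counts <- table(p1$class)
  weights <- c(alcohol = 11, ester = 20, aldehyde = 14, ketone = 2,
               acid = 5, terpene = 30, C13_norisoprenoid = 3, C6 = 7)
  target <- weights / sum(weights) * 100
  expect_true(all(abs(counts[names(weights)] - target) <= 3))
  # thresholds span the configured log-uniform range
  expect_true(all(p1$threshold_ug_per_kg >= 0.1 &
                    p1$threshold_ug_per_kg <= 1e4))
  # every primary series is populated
  mem <- suppressWarnings(
    resolve_memberships(p1, default_aroma_taxonomy()))
  expect_setequal(unique(unlist(mem$primary_series)),
                  c("herbaceous", "floral", "fruity", "sweet", "spicy",
                    "roasty", "fatty", "earthy", "balsamic", "solvent"))
  expect_error(generate_panel(cohort_config(n_compounds = 7)),
               class = "vitisaroma_validation_error")
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_train = 8, n_test = 4, n_compounds = 20,
                       n_key_positive = 4, n_key_negative = 2, seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(c1$samples, c2$samples, tolerance = 1e-12)
  expect_equal(c1$ground_truth$scores, c2$ground_truth$scores,
               tolerance = 1e-12)
  expect_identical(c1$scores$cultivar_id, c2$scores$cultivar_id)
})

test_that("ground truth matches the configured key structure and scale", {
  co <- small_cohort(seed = 5)
  gt <- co$ground_truth$coefficients
  expect_equal(sum(gt$coefficient > 0), 6)
  expect_equal(sum(gt$coefficient < 0), 3)
  expect_true(all(co$ground_truth$scores$true_score >= 1 &
                    co$ground_truth$scores$true_score <= 5))
  expect_equal(nrow(co$scores), 14)
})

test_that("the noiseless limit reproduces the stored linear combination exactly", {
  cfg <- cohort_config(n_train = 10, n_test = 3, n_compounds = 20,
                       n_key_positive = 4, n_key_negative = 2,
                       noise_sd = 0, n_orthogonal_factors = 0,
                       replicate_cv = 0, seed = 31)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth
  # rebuild whole-berry concentrations from the emitted sample table
  feats <- liking_features(co$samples, co$panel,
                           skin_mass_fraction = cfg$skin_mass_fraction)
  x <- feats$x[gt$scores$cultivar_id, gt$coefficients$compound_id]
  z <- sweep(sweep(x, 2, gt$coefficients$mean, `-`), 2,
             gt$coefficients$sd, `/`)
  recomputed <- unname(gt$intercept +
    drop(z %*% gt$coefficients$effective_coefficient))
  expect_equal(recomputed, gt$scores$unclipped_score, tolerance = 1e-9)
})

test_that("esters concentrate in pulp relative to skin", {
  co <- generate_cohort(cohort_config(seed = 13))
  shares <- co$samples %>%
    dplyr::left_join(dplyr::select(co$panel, compound_id, class),
                     by = "compound_id") %>%
    dplyr::group_by(cultivar_id, tissue, replicate) %>%
    dplyr::summarise(
      ester_share = sum(concentration_ug_per_kg[class == "ester"]) /
        sum(concentration_ug_per_kg),
      .groups = "drop") %>%
    dplyr::group_by(tissue) %>%
    dplyr::summarise(mean_share = mean(ester_share), .groups = "drop")
  expect_gt(shares$mean_share[shares$tissue == "pulp"],
            shares$mean_share[shares$tissue == "skin"])
})

test_that("orthogonal factors are uncorrelated with the liking response", {
  co <- generate_cohort(cohort_config(seed = 17))
  orth <- co$ground_truth$orthogonal$scores
  scores <- co$ground_truth$scores
  for (a in unique(orth$factor)) {
    u <- orth$score[orth$factor == a][match(scores$cultivar_id,
      orth$cultivar_id[orth$factor == a])]
    expect_lt(abs(cor(u, scores$unclipped_score)), 1e-8)
  }
})

test_that("inject_outlier scales exactly one sample", {
  co <- small_cohort(seed = 3)
  out <- inject_outlier(co$samples, "P02", "skin", 1, 50)
  hit <- with(co$samples, cultivar_id == "P02" & tissue == "skin" &
                replicate == 1)
  expect_equal(out$concentration_ug_per_kg[hit],
               50 * co$samples$concentration_ug_per_kg[hit])
  expect_equal(out$concentration_ug_per_kg[!hit],
               co$samples$concentration_ug_per_kg[!hit])
  # identity at magnitude 1
  expect_equal(inject_outlier(co$samples, "P02", "skin", 1, 1),
               co$samples)
  # the inflated sample dominates total concentration
  totals <- out %>%
    dplyr::group_by(cultivar_id, tissue, replicate) %>%
    dplyr::summarise(total = sum(concentration_ug_per_kg),
                     .groups = "drop")
  top <- totals[which.max(totals$total), ]
  expect_equal(paste(top$cultivar_id, top$tissue, top$replicate),
               "P02 skin 1")
  expect_error(inject_outlier(co$samples, "ZZ", "pulp", 1, 2),
               class = "vitisaroma_reference_error")
})
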