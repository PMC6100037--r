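test_that("OAVs are element-wise concentration over threshold", {
  lib <- as_compound_library(tibble::tibble(
    compound_id = c("a", "b"), name = c("a", "b"),
    class = c("ester", "ester"), threshold_ug_per_kg = c(10, 1),
    descriptors = list("apple", "banana")))
  smp <- tibble::tibble(
    cultivar_id = "X", tissue = "pulp", replicate = 1L,
    compound_id = c("a", "b"),
    concentration_ug_per_kg = c(10, 0))
  oav <- compute_oav(smp, lib)
  expect_equal(oav$oav[oav$compound_id == "a"], 1.0)
  expect_equal(oav$oav[oav$compound_id == "b"], 0)
})

test_that("activity uses the strict greater-than rule and pools by tissue", {
  lib <- as_compound_library(tibble::tibble(
    compound_id = c("a", "b"), name = c("a", "b"),
    class = c("ester", "ester"), threshold_ug_per_kg = c(1, 1),
    descriptors = list("apple", "banana")))
  smp <- tibble::tibble(
    cultivar_id = "X", tissue = "pulp", replicate = 1L,
    compound_id = c("a", "b"),
    concentration_ug_per_kg = c(2, 0.5))
  act <- active_compounds(compute_oav(smp, lib))
  expect_equal(act$overall$compound_id, "a")
  # value exactly at the cutoff is NOT active for compounds
  smp$concentration_ug_per_kg <- c(1, 1)
  act2 <- active_compounds(compute_oav(smp, lib))
  expect_equal(nrow(act2$overall), 0)
})

test_that("active compound sets equal a brute-force filter on synthetic data", {
  co <- small_cohort(seed = 8)
  oav <- compute_oav(co$samples, co$panel)
  act <- active_compounds(oav)
  brute <- unique(oav$compound_id[oav$oav > 1])
  expect_setequal(act$overall$compound_id, brute)
  for (tis in c("pulp", "skin")) {
    brute_t <- unique(oav$compound_id[oav$oav > 1 & oav$tissue == tis])
    expect_setequal(
      act$per_tissue$compound_id[act$per_tissue$tissue == tis], brute_t)
  }
})

test_that("series values sum member OAVs, with full multi-membership", {
  tax <- default_aroma_taxonomy()
  lib <- as_compound_library(tibble::tibble(
    compound_id = c("t1", "t2"), name = c("t1", "t2"),
    class = c("terpene", "terpene"), threshold_ug_per_kg = c(1, 1),
    descriptors = list("rose", c("rose", "apple"))))
  smp <- tibble::tibble(
    cultivar_id = "X", tissue = "skin", replicate = 1L,
    compound_id = c("t1", "t2"),
    concentration_ug_per_kg = c(2, 3))
  oav <- compute_oav(smp, lib)
  mem <- resolve_memberships(lib, tax)
  sec <- series_values(oav, mem, "secondary")
  expect_equal(sec$value[sec$series == "rose"], 5)       # 2 + 3
  expect_equal(sec$value[sec$series == "apple"], 3)      # full OAV again
  prim <- series_values(oav, mem, "primary")
  expect_equal(prim$value[prim$series == "floral"], 5)
  expect_equal(prim$value[prim$series == "fruity"], 3)
})

test_that("OAV and series values are homogeneous of degree 1 in concentration", {
  co <- small_cohort(seed = 12)
  mem <- suppressWarnings(
    resolve_memberships(co$panel, default_aroma_taxonomy()))
  oav1 <- compute_oav(co$samples, co$panel)
  scaled <- co$samples
  scaled$concentration_ug_per_kg <- scaled$concentration_ug_per_kg * 3.7
  oav2 <- compute_oav(scaled, co$panel)
  expect_equal(oav2$oav, 3.7 * oav1$oav, tolerance = 1e-12)
  s1 <- series_values(oav1, mem, "primary")
  s2 <- series_values(oav2, mem, "primary")
  expect_equal(s2$value, 3.7 * s1$value, tolerance = 1e-12)
})

test_that("series values are monotone in member OAVs", {
  tax <- default_aroma_taxonomy()
  lib <- toy_library()
  mem <- resolve_memberships(lib, tax)
  smp <- toy_samples()
  base <- series_values(compute_oav(smp, lib), mem, "primary")
  bumped <- smp
  bumped$concentration_ug_per_kg[1] <- bumped$concentration_ug_per_kg[1] + 5
  after <- series_values(compute_oav(bumped, lib), mem, "primary")
  expect_true(all(after$value >= base$value - 1e-12))
})

test_that("single-descriptor taxonomies conserve total OAV across primary series", {
  # when every compound has exactly one descriptor, each OAV lands in
  # exactly one primary series, so series totals equal the OAV total
  withr::with_seed(19, {
    tax <- default_aroma_taxonomy()
    one_desc <- sample(tax$descriptor, 12)
    lib <- as_compound_library(tibble::tibble(
      compound_id = sprintf("s%02d", 1:12),
      name = sprintf("s%02d", 1:12),
      class = sample(c("ester", "terpene", "C6", "acid"), 12,
                     replace = TRUE),
      threshold_ug_per_kg = runif(12, 0.5, 50),
      descriptors = as.list(one_desc)))
    smp <- tidyr::crossing(
      cultivar_id = c("A", "B"), tissue = c("pulp", "skin"),
      replicate = 1:2, compound_id = lib$compound_id) %>%
      dplyr::mutate(concentration_ug_per_kg = runif(dplyr::n(), 0, 100))
  })
  oav <- compute_oav(smp, lib)
  prim <- series_values(oav, resolve_memberships(lib, tax), "primary")
  total_series <- prim %>%
    dplyr::group_by(cultivar_id, tissue, replicate) %>%
    dplyr::summarise(v = sum(value), .groups = "drop")
  total_oav <- oav %>%
    dplyr::group_by(cultivar_id, tissue, replicate) %>%
    dplyr::summarise(v = sum(oav), .groups = "drop")
  expect_equal(total_series$v, total_oav$v, tolerance = 1e-12)
})

test_that("series activity is inclusive at the cutoff", {
  prof <- tibble::tibble(
    cultivar_id = "A", tissue = "pulp", replicate = 1L,
    level = "secondary", series = c("rose", "apple", "honey"),
    value = c(1.0, 0.999, 0))
  act <- active_series(prof)
  expect_setequal(act$series, "rose")
  empty <- active_series(dplyr::mutate(prof, value = 0))
  expect_equal(nrow(empty), 0)
})

test_that("fingerprints are consistent with recomputed series sums", {
  co <- small_cohort(seed = 23)
  mem <- suppressWarnings(
    resolve_memberships(co$panel, default_aroma_taxonomy()))
  oav <- compute_oav(co$samples, co$panel)
  prim <- series_values(oav, mem, "primary")
  sec <- series_values(oav, mem, "secondary")
  fp <- build_fingerprint(prim, sec, "P01", halve_series = "rose")
  means <- summarize_series(dplyr::filter(prim, cultivar_id == "P01"))
  joined <- dplyr::inner_join(fp$primary, means,
                              by = c("tissue", "series"))
  expect_equal(joined$value, joined$mean_value, tolerance = 1e-12)
  # halving marks display metadata only; stored values are untouched
  if ("rose" %in% fp$secondary$series) {
    expect_true(all(
      fp$secondary$display_scale[fp$secondary$series == "rose"] == 0.5))
  }
  expect_error(build_fingerprint(
    dplyr::filter(prim, tissue == "pulp"), sec, "P01"),
    class = "vitisaroma_validation_error")
  # all-zero OAVs give an all-zero fingerprint
  zero <- oav %>% dplyr::mutate(oav = 0)
  fp0 <- build_fingerprint(series_values(zero, mem, "primary"),
                           series_values(zero, mem, "secondary"), "P01")
  expect_true(all(fp0$primary$value == 0))
  # JSON export round-trips the values
  js <- jsonlite::fromJSON(write_fingerprint(fp))
  expect_equal(js$cultivar_id, "P01")
  expect_equal(nrow(js$primary), nrow(fp$primary))
})
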