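test_that("a compound row parses into id, class, threshold and descriptors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,name,class,threshold_ug_per_kg,descriptors",
               "c1,hexanal,aldehyde,4.5,green|grass"), path)
  lib <- read_compound_library(path)
  expect_equal(nrow(lib), 1)
  expect_equal(lib$descriptors[[1]], c("green", "grass"))
  expect_equal(lib$threshold_ug_per_kg, 4.5)
})

test_that("invalid libraries are rejected with informative errors", {
  base <- tibble::tibble(
    compound_id = c("c1", "c2"), name = c("a", "b"),
    class = c("ester", "terpene"), threshold_ug_per_kg = c(1, 2),
    descriptors = list("apple", "rose"))

  zero_thr <- base
  zero_thr$threshold_ug_per_kg[2] <- 0
  expect_error(as_compound_library(zero_thr),
               class = "vitisaroma_validation_error")

  dup <- base
  dup$compound_id[2] <- "c1"
  expect_error(as_compound_library(dup),
               class = "vitisaroma_validation_error")

  bad_class <- base
  bad_class$class[1] <- "polyphenol"
  expect_error(as_compound_library(bad_class),
               class = "vitisaroma_validation_error")

  missing_col <- base[, -2]
  expect_error(as_compound_library(missing_col),
               class = "vitisaroma_format_error")
})

test_that("a generated 100-compound panel round-trips through CSV", {
  panel <- generate_panel(cohort_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_compound_library(panel, path)
  back <- read_compound_library(path)
  write_compound_library(back, path)
  back2 <- read_compound_library(path)
  expect_equal(back, panel, tolerance = 1e-12)
  expect_identical(back2, back)
})

test_that("membership resolution takes the per-descriptor union", {
  lib <- toy_library()
  tax <- default_aroma_taxonomy()
  mem <- resolve_memberships(lib, tax)
  # ethyl propionate: banana + apple + strawberry => fruity primary and the
  # three matching secondary series simultaneously
  i <- which(mem$compound_id == "c2")
  expect_equal(mem$primary_series[[i]], "fruity")
  expect_setequal(mem$secondary_series[[i]],
                  c("banana", "apple", "strawberry"))
  expect_equal(mem$primary_series[[which(mem$compound_id == "c1")]],
               "herbaceous")
})

test_that("memberships equal a brute-force per-descriptor union on random panels", {
  tax <- default_aroma_taxonomy()
  lookup_primary <- setNames(tax$primary_series, tax$descriptor)
  lookup_secondary <- setNames(tax$secondary_series, tax$descriptor)
  withr::with_seed(42, {
    for (rep in 1:4) {
      n <- 20
      descs <- lapply(seq_len(n), function(i) {
        sample(tax$descriptor, sample(0:4, 1))
      })
      lib <- as_compound_library(tibble::tibble(
        compound_id = sprintf("r%02d", seq_len(n)),
        name = as.character(seq_len(n)),
        class = sample(c("ester", "terpene", "C6"), n, replace = TRUE),
        threshold_ug_per_kg = runif(n, 0.1, 100),
        descriptors = descs))
      mem <- suppressWarnings(resolve_memberships(lib, tax))
      for (i in seq_len(n)) {
        d <- descs[[i]]
        prim <- unique(unname(lookup_primary[d]))
        sec <- unique(unlist(lookup_secondary[d]))
        expect_setequal(mem$primary_series[[i]],
                        if (length(prim)) prim else character(0))
        expect_setequal(mem$secondary_series[[i]],
                        if (length(sec)) sec else character(0))
      }
    }
  })
})

test_that("membership resolution is idempotent and descriptor-order independent", {
  tax <- default_aroma_taxonomy()
  lib1 <- as_compound_library(tibble::tibble(
    compound_id = "x", name = "x", class = "ester",
    threshold_ug_per_kg = 1,
    descriptors = list(c("apple", "banana", "rose"))))
  lib2 <- lib1
  lib2$descriptors <- list(c("rose", "banana", "apple"))
  m1 <- resolve_memberships(lib1, tax)
  m2 <- resolve_memberships(lib2, tax)
  expect_equal(m1$primary_series, m2$primary_series)
  expect_equal(m1$secondary_series, m2$secondary_series)
  expect_equal(resolve_memberships(lib1, tax), m1)
})

test_that("secondary memberships always sit under a matching primary", {
  tax <- default_aroma_taxonomy()
  parents <- secondary_parents(tax)
  panel <- generate_panel(cohort_config(seed = 4, n_compounds = 60))
  mem <- resolve_memberships(panel, tax)
  for (i in seq_len(nrow(mem))) {
    sec <- mem$secondary_series[[i]]
    if (length(sec) == 0) next
    needed <- unique(parents$parent[parents$secondary %in% sec])
    expect_true(all(needed %in% mem$primary_series[[i]]))
  }
})

test_that("unmapped descriptors and empty descriptor lists warn, not fail", {
  tax <- default_aroma_taxonomy()
  lib <- as_compound_library(tibble::tibble(
    compound_id = c("u1", "u2"), name = c("u1", "u2"),
    class = c("other", "other"), threshold_ug_per_kg = c(1, 1),
    descriptors = list("petrichor", character(0))))
  expect_warning(expect_warning(
    mem <- resolve_memberships(lib, tax),
    class = "vitisaroma_unmapped_descriptors"),
    class = "vitisaroma_empty_membership")
  expect_length(mem$primary_series[[1]], 0)
  expect_length(mem$primary_series[[2]], 0)
  expect_equal(mem$unmapped[[1]], "petrichor")
})
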