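#' Configuration of a synthetic volatile-profile cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' describe the study design the package emulates: a training block of 20
#' scored cultivars plus a test block of 19 unscored ones, triplicate
#' profiling of pulp and skin, a panel of ~100 volatiles across 8 chemical
#' classes, and a liking response on the 1--5 sensory scale driven by 17
#' positively and 9 negatively weighted key compounds.
#'
#' Log-scale variance components (`class_sd`, `compound_sd`,
#' `pathway_loading`, `orthogonal_loading`) are in log10 concentration
#' units. Key compounds co-vary through two latent "pathway" factors (one
#' per coefficient sign block), mimicking biosynthetically co-regulated
#' volatile families; this is what makes coefficient recovery from ~20
#' cultivars a well-posed problem.
#'
#' @param n_train,n_test Number of scored (training) and unscored (test)
#'   cultivars.
#' @param n_replicates Biological replicates per (cultivar, tissue).
#' @param n_compounds Size of the volatile panel (at least 8, one per class).
#' @param n_key_positive,n_key_negative Number of compounds with positive /
#'   negative liking coefficients.
#' @param noise_sd SD of Gaussian noise added to liking scores (1--5 scale).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise on concentrations.
#' @param n_orthogonal_factors Number of response-orthogonal latent factors
#'   injected into the concentration block only.
#' @param orthogonal_loading Log10-scale loading magnitude of orthogonal
#'   factors.
#' @param pathway_loading Log10-scale loading of the key-compound pathway
#'   factors.
#' @param class_sd,compound_sd Log10 SD of the per-cultivar chemical-class
#'   effect and of the per-(cultivar, compound) idiosyncratic effect.
#' @param liking_center,liking_gain Center and slope of the liking response
#'   on the standardized key-compound combination.
#' @param skin_mass_fraction Skin mass fraction used for the whole-berry
#'   blend underlying the liking signal.
#' @param zero_inflation Probability that a non-key compound is absent
#'   (not detected) in a cultivar.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_train = 20, n_test = 19, n_replicates = 3,
                          n_compounds = 100,
                          n_key_positive = 17, n_key_negative = 9,
                          noise_sd = 0.12, replicate_cv = 0.1,
                          n_orthogonal_factors = 2,
                          orthogonal_loading = 0.25,
                          pathway_loading = 0.55,
                          class_sd = 0.06, compound_sd = 0.05,
                          liking_center = 4, liking_gain = 0.45,
                          skin_mass_fraction = 0.2,
                          zero_inflation = 0.05,
                          seed = 1) {
  cfg <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
              n_replicates = as.integer(n_replicates),
              n_compounds = as.integer(n_compounds),
              n_key_positive = as.integer(n_key_positive),
              n_key_negative = as.integer(n_key_negative),
              noise_sd = noise_sd, replicate_cv = replicate_cv,
              n_orthogonal_factors = as.integer(n_orthogonal_factors),
              orthogonal_loading = orthogonal_loading,
              pathway_loading = pathway_loading,
              class_sd = class_sd, compound_sd = compound_sd,
              liking_center = liking_center, liking_gain = liking_gain,
              skin_mass_fraction = skin_mass_fraction,
              zero_inflation = zero_inflation,
              seed = as.integer(seed))
  if (cfg$n_train < 0 || cfg$n_test < 0 || cfg$n_train + cfg$n_test < 1) {
    abort("need at least one cultivar", class = "vitisaroma_validation_error")
  }
  if (cfg$n_replicates < 1) {
    abort("n_replicates must be >= 1", class = "vitisaroma_validation_error")
  }
  if (cfg$n_key_positive < 0 || cfg$n_key_negative < 0 ||
      cfg$n_key_positive + cfg$n_key_negative > cfg$n_compounds) {
    abort("n_key_positive + n_key_negative must be <= n_compounds",
          class = "vitisaroma_validation_error")
  }
  assert_scalar_number(cfg$noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(cfg$replicate_cv, "replicate_cv", lower = 0)
  assert_scalar_number(cfg$skin_mass_fraction, "skin_mass_fraction", 0, 1)
  assert_scalar_number(cfg$zero_inflation, "zero_inflation", 0, 1)
  structure(cfg, class = "cohort_config")
}

# study-like class composition of the panel (relative frequencies)
.class_weights <- c(alcohol = 11, ester = 20, aldehyde = 14, ketone = 2,
                    acid = 5, terpene = 30, C13_norisoprenoid = 3, C6 = 7)

# class-typical log10 abundance (ug/kg) and tissue partitioning:
# esters concentrate in pulp, terpenes in skin, C6 compounds form a high
# background in both; the remaining classes sit mostly in the skin
.class_log10_mean <- c(alcohol = 1.3, ester = 2.6, aldehyde = 1.6,
                       ketone = 0.9, acid = 1.1, terpene = 2.1,
                       C13_norisoprenoid = 0.4, C6 = 2.4, other = 1.0)
.pulp_mult <- c(alcohol = 0.6, ester = 1.7, aldehyde = 0.6, ketone = 0.6,
                acid = 0.6, terpene = 0.3, C13_norisoprenoid = 0.6,
                C6 = 1.3, other = 1.0)
.skin_mult <- c(alcohol = 1.4, ester = 0.3, aldehyde = 1.4, ketone = 1.4,
                acid = 1.4, terpene = 1.7, C13_norisoprenoid = 1.4,
                C6 = 1.3, other = 1.0)

# descriptor pools by chemical class (tokens of the default taxonomy)
.class_descriptors <- list(
  ester = c("banana", "apple", "strawberry", "pineapple", "grape", "fruity"),
  terpene = c("rose", "geranium", "lavender", "orange_flower", "citrus",
              "lemon", "orange", "flower"),
  C6 = c("green", "grass", "leafy", "cut_grass", "herbaceous"),
  aldehyde = c("fatty", "waxy", "green", "roasted"),
  alcohol = c("solvent", "ethereal", "varnish", "balsamic"),
  acid = c("fatty", "tallow", "earthy", "spice"),
  C13_norisoprenoid = c("violet", "rose", "honey", "sweet"),
  ketone = c("honey", "marshmallow", "sweet", "spice"),
  other = c("ethereal")
)

# one canonical descriptor per primary series, used to guarantee coverage
.primary_fallback <- c(herbaceous = "green", floral = "flower",
                       fruity = "fruity", sweet = "sweet", spicy = "spice",
                       roasty = "roasted", fatty = "fatty", earthy = "earthy",
                       balsamic = "balsamic", solvent = "solvent")

#' Generate a synthetic compound panel
#'
#' Allocates compounds across the eight grape-volatile chemical classes with
#' study-like proportions (terpenes and esters dominating), draws odor
#' thresholds log-uniformly over four orders of magnitude (0.1 to 10000
#' ug/kg) and assigns each compound one to three class-typical odor
#' descriptors from the taxonomy, forcing coverage of all ten primary
#' aromatic series.
#'
#' @param config A [cohort_config()].
#' @param taxonomy Taxonomy supplying the descriptor vocabulary (default:
#'   the shipped taxonomy).
#' @return A compound-library tibble.
#' @export
generate_panel <- function(config = cohort_config(),
                           taxonomy = default_aroma_taxonomy()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_compounds
  if (n < length(.class_weights)) {
    abort(sprintf("n_compounds must be >= %d to populate all classes",
                  length(.class_weights)),
          class = "vitisaroma_validation_error")
  }
  tax <- as_aroma_taxonomy(taxonomy)
  with_seed(config$seed, {
    # largest-remainder allocation with at least one compound per class
    target <- .class_weights / sum(.class_weights) * n
    counts <- pmax(floor(target), 1L)
    while (sum(counts) < n) {
      i <- which.max(target - counts)
      counts[i] <- counts[i] + 1L
    }
    while (sum(counts) > n) {
      ok <- counts > 1L
      i <- which(ok)[which.min((target - counts)[ok])]
      counts[i] <- counts[i] - 1L
    }
    classes <- rep(names(counts), counts)
    thresholds <- 10^runif(n, -1, 4)
    descriptors <- lapply(classes, function(cl) {
      pool <- .class_descriptors[[cl]]
      sample(pool, size = min(length(pool), sample(1:3, 1)))
    })
    # ensure every primary series is represented on the panel
    covered <- unique(tax$primary_series[
      match(unlist(descriptors), tax$descriptor)])
    for (p in setdiff(.primary_series, covered)) {
      i <- sample(n, 1)
      descriptors[[i]] <- unique(c(descriptors[[i]],
                                   unname(.primary_fallback[p])))
    }
    as_compound_library(tibble(
      compound_id = sprintf("c%03d", seq_len(n)),
      name = sprintf("synthetic %s %d", classes,
                     stats::ave(seq_len(n), classes, FUN = seq_along)),
      class = classes,
      threshold_ug_per_kg = thresholds,
      descriptors = descriptors
    ))
  })
}

#' Generate a synthetic cohort of volatile profiles with liking scores
#'
#' Emulates the statistical structure of a table-grape aroma study:
#' log-normal per-(cultivar, class) abundance with tissue bias (ester mass
#' concentrated in pulp, terpene mass in skin, a C6 background in both),
#' multiplicative replicate noise, and a consumer-liking response generated
#' as a clipped noisy linear function -- in unit-variance-scaled whole-berry
#' concentration space -- of the key compounds, with mixed-sign
#' coefficients. Response-orthogonal latent factors are added to the
#' concentration block only, so the generated X carries structured variation
#' that an orthogonal PLS model should isolate from the predictive part.
#'
#' Training ("P", popular/scored) cultivars receive observed liking scores;
#' test ("U", unfamiliar) cultivars have scores only in the ground truth.
#'
#' @param config A [cohort_config()].
#' @param panel A compound library, typically from [generate_panel()]. Must
#'   have `config$n_compounds` rows.
#' @return A list of class `aroma_cohort` with elements `samples` (long
#'   sample tibble, pulp and skin), `maturity`, `scores` (training block),
#'   `ground_truth` (coefficients, scalings, true scores, orthogonal
#'   structure), `panel`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            panel = generate_panel(config)) {
  stopifnot(inherits(config, "cohort_config"))
  lib <- as_compound_library(panel)
  K <- nrow(lib)
  if (K != config$n_compounds) {
    abort("panel size does not match config$n_compounds",
          class = "vitisaroma_validation_error")
  }
  n_cv <- config$n_train + config$n_test
  cultivars <- c(sprintf("P%02d", seq_len(config$n_train)),
                 sprintf("U%02d", seq_len(config$n_test)))
  role <- rep(c("train", "test"), c(config$n_train, config$n_test))
  classes <- lib$class

  with_seed(config$seed + 1L, {
    # per-compound log10 abundance level
    offset <- .class_log10_mean[classes] + rnorm(K, 0, 0.5)
    # per-cultivar structure in log10 space
    cls_eff <- matrix(runif_unit(n_cv * length(.classes)), n_cv) *
      config$class_sd
    colnames(cls_eff) <- .classes
    idio <- matrix(runif_unit(n_cv * K), n_cv, K) * config$compound_sd
    L <- cls_eff[, classes, drop = FALSE] + idio

    n_keys <- config$n_key_positive + config$n_key_negative
    keys <- if (n_keys > 0) sort(sample(K, n_keys)) else integer(0)
    pos <- head(keys, config$n_key_positive)
    neg <- setdiff(keys, pos)
    f_pos <- runif_unit(n_cv)
    f_neg <- runif_unit(n_cv)
    if (length(pos) > 0) L[, pos] <- L[, pos] + config$pathway_loading * f_pos
    if (length(neg) > 0) L[, neg] <- L[, neg] + config$pathway_loading * f_neg

    base <- sweep(10^L, 2, 10^offset, `*`)
    # not-detected compounds (non-key only, so the liking signal is intact)
    if (config$zero_inflation > 0 && length(keys) < K) {
      nonkey <- setdiff(seq_len(K), keys)
      drop_mask <- matrix(runif(n_cv * length(nonkey)) < config$zero_inflation,
                          n_cv, length(nonkey))
      base[, nonkey][drop_mask] <- 0
    }
    pulp <- sweep(base, 2, .pulp_mult[classes], `*`)
    skin <- sweep(base, 2, .skin_mult[classes], `*`)
    f <- config$skin_mass_fraction
    whole <- f * skin + (1 - f) * pulp

    # liking response from UV-scaled whole-berry key concentrations
    coefs <- numeric(K)
    if (length(pos) > 0) coefs[pos] <- runif(length(pos), 0.7, 1.3)
    if (length(neg) > 0) {
      cn <- runif(length(neg), 0.7, 1.3)
      if (length(pos) > 0) cn <- cn * sum(coefs[pos]) / sum(cn)
      coefs[neg] <- -cn
    }
    key_mean <- colMeans(whole[, keys, drop = FALSE])
    key_sd <- apply(whole[, keys, drop = FALSE], 2, sd)
    if (n_keys > 0 && any(key_sd == 0)) {
      key_sd[key_sd == 0] <- 1
    }
    z <- if (n_keys > 0) {
      drop(scale(whole[, keys, drop = FALSE], key_mean, key_sd) %*%
             coefs[keys])
    } else rep(0, n_cv)
    sd_z <- if (n_keys > 0 && sd(z) > 0) sd(z) else 1
    unclipped <- config$liking_center + config$liking_gain * z / sd_z +
      rnorm(n_cv, 0, config$noise_sd)
    true_scores <- pmin(5, pmax(1, unclipped))

    # response-orthogonal latent factors, added to X only
    orth_scores <- list()
    orth_loadings <- list()
    if (config$n_orthogonal_factors > 0) {
      nonkey <- setdiff(seq_len(K), keys)
      for (a in seq_len(config$n_orthogonal_factors)) {
        u <- runif_unit(n_cv)
        u <- if (sd(unclipped) > 0) residuals(lm(u ~ unclipped)) else u
        sub <- sort(sample(nonkey, max(1, round(0.3 * length(nonkey)))))
        lo <- runif_unit(length(sub)) * config$orthogonal_loading
        mult <- 10^outer(u, lo)
        pulp[, sub] <- pulp[, sub] * mult
        skin[, sub] <- skin[, sub] * mult
        orth_scores[[a]] <- tibble(factor = a, cultivar_id = cultivars,
                                   score = unname(u))
        orth_loadings[[a]] <- tibble(factor = a,
                                     compound_id = lib$compound_id[sub],
                                     loading = lo)
      }
    }

    # replicate noise: multiplicative log-normal with the configured CV
    sd_log10 <- sqrt(log(1 + config$replicate_cv^2)) / log(10)
    long <- vector("list", 2L * config$n_replicates)
    idx <- 1L
    for (tis in c("pulp", "skin")) {
      conc0 <- if (tis == "pulp") pulp else skin
      for (r in seq_len(config$n_replicates)) {
        noise <- if (sd_log10 > 0) {
          matrix(10^rnorm(n_cv * K, 0, sd_log10), n_cv, K)
        } else 1
        conc <- conc0 * noise
        long[[idx]] <- tibble(
          cultivar_id = rep(cultivars, K),
          tissue = tis,
          replicate = r,
          compound_id = rep(lib$compound_id, each = n_cv),
          concentration_ug_per_kg = as.vector(conc)
        )
        idx <- idx + 1L
      }
    }
    samples <- bind_rows(long) %>%
      filter(.data$concentration_ug_per_kg > 0) %>%
      arrange(.data$cultivar_id, .data$tissue, .data$replicate,
              .data$compound_id)

    maturity <- tibble(
      cultivar_id = cultivars,
      tss_brix = runif(n_cv, 16.1, 21.5),
      ta_g_per_l = runif(n_cv, 2.4, 4.6),
      ph = rnorm(n_cv, 3.6, 0.15),
      berry_weight_g = pmax(2, rnorm(n_cv, 8, 1.5))
    )

    ground_truth <- list(
      coefficients = tibble(
        compound_id = lib$compound_id[keys],
        coefficient = coefs[keys],
        effective_coefficient =
          config$liking_gain * coefs[keys] / sd_z,
        mean = unname(key_mean),
        sd = unname(key_sd)
      ),
      intercept = config$liking_center,
      scores = tibble(cultivar_id = cultivars, role = role,
                      unclipped_score = unclipped,
                      true_score = true_scores),
      orthogonal = list(scores = bind_rows(orth_scores),
                        loadings = bind_rows(orth_loadings))
    )
    structure(list(
      samples = samples,
      maturity = maturity,
      scores = tibble(cultivar_id = cultivars[role == "train"],
                      liking_score = true_scores[role == "train"]),
      ground_truth = ground_truth,
      panel = lib,
      config = config
    ), class = "aroma_cohort")
  })
}

#' @export
print.aroma_cohort <- function(x, ...) {
  cat(sprintf(
    "<aroma_cohort> %d train + %d test cultivars, %d compounds, %d replicates\n",
    x$config$n_train, x$config$n_test, x$config$n_compounds,
    x$config$n_replicates))
  cat(sprintf("  %d sample rows; %d key compounds (%d positive, %d negative)\n",
              nrow(x$samples), nrow(x$ground_truth$coefficients),
              x$config$n_key_positive, x$config$n_key_negative))
  invisible(x)
}

#' Multiply all concentrations of one sample
#'
#' Test fixture for outlier screening: scales every concentration of the
#' sample identified by (cultivar, tissue, replicate) by `magnitude`,
#' leaving all other samples untouched. `magnitude = 1` is the identity.
#'
#' @param samples A sample tibble.
#' @param cultivar_id,tissue,replicate Key of the sample to scale.
#' @param magnitude Strictly positive multiplier.
#' @return The modified sample tibble.
#' @export
inject_outlier <- function(samples, cultivar_id, tissue, replicate,
                           magnitude) {
  smp <- as_sample_table(samples)
  assert_scalar_number(magnitude, "magnitude", lower = 1e-12)
  hit <- smp$cultivar_id == cultivar_id & smp$tissue == tissue &
    smp$replicate == as.integer(replicate)
  if (!any(hit)) {
    abort(sprintf("no sample with key (%s, %s, %s)",
                  cultivar_id, tissue, replicate),
          class = "vitisaroma_reference_error")
  }
  smp$concentration_ug_per_kg[hit] <- smp$concentration_ug_per_kg[hit] *
    magnitude
  smp
}
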