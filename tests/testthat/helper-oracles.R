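# independent oracles and small fixture builders used across tests

# textbook one-component PLS1 (NIPALS), written independently of the package
# code path: UV scaling done by hand, no shared helpers
pls1_one_component <- function(x, y) {
  x <- as.matrix(x)
  mx <- colMeans(x)
  sx <- apply(x, 2, stats::sd)
  xs <- sweep(sweep(x, 2, mx, `-`), 2, sx, `/`)
  my <- mean(y)
  sy <- stats::sd(y)
  ys <- (y - my) / sy
  w <- drop(t(xs) %*% ys)
  w <- w / sqrt(sum(w * w))
  t <- drop(xs %*% w)
  q <- sum(t * ys) / sum(t * t)
  list(
    w = w, t = t, q = q,
    predict = function(newx) {
      ns <- sweep(sweep(as.matrix(newx), 2, mx, `-`), 2, sx, `/`)
      my + sy * drop(ns %*% w) * q
    }
  )
}

# VIP by direct application of the formula, from a model's raw pieces
vip_direct <- function(w_columns, ssy_per_component) {
  k <- nrow(w_columns)
  contrib <- sapply(seq_along(ssy_per_component), function(a) {
    wa <- w_columns[, a]
    ssy_per_component[a] * (wa / sqrt(sum(wa^2)))^2
  })
  sqrt(k * rowSums(contrib) / sum(ssy_per_component))
}

# a tiny hand-written compound library
toy_library <- function() {
  as_compound_library(tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    name = c("hexanal", "ethyl propionate", "linalool"),
    class = c("aldehyde", "ester", "terpene"),
    threshold_ug_per_kg = c(4.5, 10, 6),
    descriptors = list(c("green", "grass"),
                       c("banana", "apple", "strawberry"),
                       c("rose"))
  ))
}

# a tiny sample table over the toy library
toy_samples <- function() {
  tibble::tibble(
    cultivar_id = rep(c("A", "A", "B"), each = 3),
    tissue = rep(c("pulp", "skin", "pulp"), each = 3),
    replicate = 1L,
    compound_id = rep(c("c1", "c2", "c3"), 3),
    concentration_ug_per_kg = c(9, 20, 6, 4.5, 10, 12, 1, 2, 3)
  )
}

# small synthetic cohort used by the chemometrics tests
small_cohort <- function(seed = 1, ...) {
  cfg <- cohort_config(n_train = 14, n_test = 5, n_compounds = 30,
                       n_key_positive = 6, n_key_negative = 3,
                       seed = seed, ...)
  generate_cohort(cfg)
}

# cultivar-mean whole-berry matrix + training response of a cohort
cohort_xy <- function(cohort) {
  feats <- liking_features(cohort$samples, cohort$panel)
  list(x = feats$x[cohort$scores$cultivar_id, , drop = FALSE],
       y = cohort$scores$liking_score)
}

expect_no_zero_var_warning <- function(expr) {
  withCallingHandlers(expr,
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
}
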