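# cross-validation and permutation validation of OPLS models

# deterministic, response-balanced fold assignment: samples are sorted by y
# and fold labels are drawn within consecutive blocks, so every fold covers
# the response range
assign_folds <- function(y, folds, seed) {
  n <- length(y)
  if (folds > n) {
    abort(sprintf("folds (%d) exceeds the number of samples (%d)", folds, n),
          class = "vitisaroma_validation_error")
  }
  if (folds < 2) {
    abort("folds must be >= 2", class = "vitisaroma_validation_error")
  }
  with_seed(seed, {
    ord <- order(y, sample(n))      # random tie-break
    labels <- integer(n)
    pos <- 1L
    while (pos <= n) {
      block <- ord[pos:min(n, pos + folds - 1L)]
      labels[block] <- sample(folds, length(block))
      pos <- pos + folds
    }
    labels
  })
}

# PRESS-based Q2Y and RMSECV at a fixed orthogonal-component count, given a
# fold assignment; returns c(q2y, rmsecv), or NAs if any fold fails to fit
cv_press <- function(x, y, n_ortho, labels) {
  press <- 0
  for (f in sort(unique(labels))) {
    train <- labels != f
    fit <- withCallingHandlers(
      tryCatch(fit_opls(x[train, , drop = FALSE], y[train], n_ortho),
               error = function(e) NULL),
      vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    pred <- predict(fit, x[!train, , drop = FALSE])
    press <- press + sum((y[!train] - pred)^2)
  }
  c(1 - press / sum((y - mean(y))^2), sqrt(press / length(y)))
}

#' Cross-validate an OPLS model and choose the orthogonal-component count
#'
#' Seven-fold (by default) cross-validation with deterministic, seeded,
#' response-balanced fold assignment. In every fold the scaling and the
#' model are refitted on the training part only; squared prediction errors
#' on the held-out samples accumulate into PRESS. `Q2Y = 1 - PRESS / SS`
#' (total response sum of squares about the mean -- identical in raw and
#' scaled units) and `RMSECV = sqrt(PRESS / N)` on the original response
#' scale.
#'
#' The number of orthogonal components starts at 0 and grows while Q2Y
#' improves by more than `min_improvement` (default 0.01), up to
#' `n_ortho_max`; the last accepted count is returned as `chosen_n_ortho`.
#'
#' @param x Predictor matrix or data frame.
#' @param y Numeric response.
#' @param folds Number of folds (>= 2, <= number of samples).
#' @param n_ortho_max Largest orthogonal-component count to consider.
#' @param min_improvement Minimum Q2Y gain required to accept one more
#'   orthogonal component.
#' @param seed Seed for the fold assignment.
#' @return A list of class `opls_cv`: `results` tibble (`n_ortho`, `q2y`,
#'   `rmsecv`), `chosen_n_ortho`, `q2y`, `rmsecv` (at the chosen count),
#'   `folds`, `seed`, `fold_assignment`.
#' @export
cross_validate_opls <- function(x, y, folds = 7, n_ortho_max = 9,
                                min_improvement = 0.01, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  labels <- assign_folds(y, folds, seed)
  rank <- qr(scale(x[, apply(x, 2, sd) > 0, drop = FALSE]))$rank
  candidates <- 0:max(0, min(n_ortho_max, rank - 1))
  res <- vapply(candidates, function(a) cv_press(x, y, a, labels),
                numeric(2))
  results <- tibble(n_ortho = candidates, q2y = res[1, ], rmsecv = res[2, ])
  chosen <- candidates[1]
  best <- results$q2y[1]
  for (i in seq_along(candidates)[-1]) {
    if (is.na(results$q2y[i])) break
    if (results$q2y[i] - best > min_improvement) {
      chosen <- candidates[i]
      best <- results$q2y[i]
    } else {
      break
    }
  }
  structure(list(
    results = results,
    chosen_n_ortho = chosen,
    q2y = best,
    rmsecv = results$rmsecv[results$n_ortho == chosen],
    folds = folds,
    seed = seed,
    fold_assignment = labels
  ), class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf(
    "<opls_cv> %d-fold; chosen 1 + %d + 0 with Q2Y %.3f, RMSECV %.4g\n",
    x$folds, x$chosen_n_ortho, x$q2y, x$rmsecv))
  invisible(x)
}

#' Permutation validation of an OPLS model
#'
#' Guards against chance correlation and overfitting: the response is
#' randomly permuted `n_perm` times (default 200) and the model is refitted
#' and cross-validated under the identical configuration (same
#' orthogonal-component count and fold scheme). For each permutation the
#' absolute correlation of the permuted response with the original one is
#' recorded together with the resulting R2Y and Q2Y. Least-squares lines
#' through the (correlation, R2Y) and (correlation, Q2Y) points -- including
#' the unpermuted model at correlation 1 -- give the R2 and Q2 intercepts; a
#' valid model shows a clearly negative Q2 intercept, and every permuted
#' Q2Y below the original.
#'
#' @param x Predictor matrix or data frame.
#' @param y Numeric response.
#' @param n_perm Number of permutations (>= 2; default 200).
#' @param n_ortho Orthogonal-component count, fixed before permuting.
#' @param folds Cross-validation folds.
#' @param seed Seed for permutations and fold assignment.
#' @return A list of class `opls_permutation`: `results` tibble
#'   (`permutation`, `correlation`, `r2y`, `q2y`; permutation 0 is the
#'   unpermuted model), `r2_intercept`, `q2_intercept`, `original_r2y`,
#'   `original_q2y`, `p_value` (fraction of permuted Q2Y at or above the
#'   original, with the +1 continuity correction).
#' @export
opls_permutation <- function(x, y, n_perm = 200, n_ortho = 0, folds = 7,
                             seed = 1) {
  if (!is.numeric(n_perm) || n_perm < 2) {
    abort("n_perm must be >= 2", class = "vitisaroma_validation_error")
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  fit0 <- withCallingHandlers(
    fit_opls(x, y, n_ortho),
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
  labels0 <- assign_folds(y, folds, seed)
  q2_0 <- cv_press(x, y, n_ortho, labels0)[1]

  perms <- with_seed(seed + 1L, {
    purrr::map(seq_len(n_perm), function(i) {
      yp <- sample(y)
      fit <- withCallingHandlers(
        tryCatch(fit_opls(x, yp, n_ortho), error = function(e) NULL),
        vitisaroma_zero_variance = function(w)
          invokeRestart("muffleWarning"))
      labels <- assign_folds(yp, folds, seed + i)
      tibble(permutation = i, correlation = abs(cor(yp, y)),
             r2y = if (is.null(fit)) NA_real_ else fit$stats$r2y,
             q2y = cv_press(x, yp, n_ortho, labels)[1])
    })
  })
  results <- bind_rows(
    tibble(permutation = 0L, correlation = 1,
           r2y = fit0$stats$r2y, q2y = q2_0),
    bind_rows(perms)
  )
  fit_line <- function(val) {
    ok <- is.finite(results[[val]])
    unname(coef(lm(results[[val]][ok] ~ results$correlation[ok]))[1])
  }
  perm_q2 <- results$q2y[results$permutation > 0]
  structure(list(
    results = results,
    r2_intercept = fit_line("r2y"),
    q2_intercept = fit_line("q2y"),
    original_r2y = fit0$stats$r2y,
    original_q2y = q2_0,
    p_value = (sum(perm_q2 >= q2_0, na.rm = TRUE) + 1) / (n_perm + 1),
    n_perm = n_perm,
    n_ortho = n_ortho,
    folds = folds
  ), class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf(
    "<opls_permutation> n = %d; original Q2Y %.3f; intercepts R2 %.3f, Q2 %.3f; p = %.3g\n",
    x$n_perm, x$original_q2y, x$r2_intercept, x$q2_intercept, x$p_value))
  invisible(x)
}
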