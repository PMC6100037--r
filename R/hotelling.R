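#' PCA outlier screening with Hotelling's T-squared
#'
#' Screens samples for strong multivariate outliers before regression
#' modelling. The matrix is UV-scaled internally, a PCA is fitted, and each
#' sample's Hotelling distance over the retained components is
#' `T2_i = sum_a t_ia^2 / lambda_a` (score variances `lambda_a`). The control
#' limit is the F-distribution bound
#' `A (N - 1) / (N - A) * F(1 - alpha; A, N - A)`; samples above it are
#' flagged. The number of components is the smallest reaching the target
#' cumulative explained variance (default 0.8), capped (default 5) and
#' limited by the matrix rank.
#'
#' Screening is intended as a single pass: flag, remove, refit the
#' downstream model once (see [train_liking_model()]).
#'
#' @param x Numeric matrix or data frame, samples in rows (>= 3 samples).
#' @param alpha Flagging level (default 0.01, i.e. the 99% limit).
#' @param r2x_target Cumulative explained-variance target for choosing the
#'   number of components.
#' @param max_pc Cap on the number of components.
#' @param n_pc Optional explicit number of components (overrides the rule);
#'   more components than the matrix rank is an error.
#' @return A list of class `hotelling_screen`: `scores` tibble (`row`,
#'   `t2`, `flagged`), `limit`, `n_pc`, `alpha`, `r2x` (cumulative by
#'   component).
#' @export
pca_hotelling_screen <- function(x, alpha = 0.01, r2x_target = 0.8,
                                 max_pc = 5, n_pc = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) {
    abort("Hotelling screening needs at least 3 samples",
          class = "vitisaroma_validation_error")
  }
  assert_scalar_number(alpha, "alpha", 1e-6, 0.5)
  xs <- withCallingHandlers(
    uv_scale(x)$x,
    vitisaroma_zero_variance = function(w) invokeRestart("muffleWarning"))
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_pc)) {
    cum <- cumsum(ev) / sum(ev)
    n_pc <- min(which(cum >= r2x_target)[1], max_pc, rank)
    if (is.na(n_pc)) n_pc <- min(max_pc, rank)
  } else if (n_pc > rank) {
    abort(sprintf("requested %d components but rank is %d", n_pc, rank),
          class = "vitisaroma_validation_error")
  }
  if (n - n_pc < 2) {
    abort(sprintf(
      "too few samples (N = %d) for %d components: need N >= A + 2",
      n, n_pc), class = "vitisaroma_validation_error")
  }
  t_scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  lambda <- ev[seq_len(n_pc)]
  t2 <- rowSums(sweep(t_scores^2, 2, lambda, `/`))
  limit <- n_pc * (n - 1) / (n - n_pc) * qf(1 - alpha, n_pc, n - n_pc)
  rows <- rownames(x) %||% as.character(seq_len(n))
  structure(list(
    scores = tibble(row = rows, t2 = unname(t2),
                    flagged = unname(t2 > limit)),
    limit = limit,
    n_pc = n_pc,
    alpha = alpha,
    r2x = cumsum(ev) / sum(ev)
  ), class = "hotelling_screen")
}

#' @export
print.hotelling_screen <- function(x, ...) {
  cat(sprintf(
    "<hotelling_screen> %d samples, %d PC(s), %.0f%% limit = %.2f; %d flagged\n",
    nrow(x$scores), x$n_pc, 100 * (1 - x$alpha), x$limit,
    sum(x$scores$flagged)))
  invisible(x)
}

#' @rdname pca_hotelling_screen
#' @param x A `hotelling_screen` object (for `tidy()`).
#' @param ... Unused.
#' @export
tidy.hotelling_screen <- function(x, ...) x$scores
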