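#' Fit a single-response orthogonal PLS (OPLS) model
#'
#' Orthogonal projections to latent structures splits the X block into one
#' predictive component, aligned with the response, and `n_ortho` orthogonal
#' components that capture systematic X variation uncorrelated with y. Both
#' blocks are unit-variance scaled internally (the response too); errors are
#' reported back on the original response scale.
#'
#' The algorithm is the classical single-y sequence: the predictive weight
#' is `w = X'y` normalized to unit length; for each orthogonal component the
#' loading `p` of the current predictive score is stripped of its
#' w-component to give the orthogonal weight `w_o = p - (w'p) w`
#' (normalized), with score `t_o = X w_o` and loading `p_o`, after which X
#' is deflated by `t_o p_o'`. The final predictive score is `t = X w` on the
#' deflated matrix, with response loading `q = y't / t't`. With
#' `n_ortho = 0` the model is exactly one-component PLS1.
#'
#' @param x Numeric matrix or data frame of predictors (samples in rows,
#'   named columns).
#' @param y Numeric response vector (one value per row of `x`); must not be
#'   constant.
#' @param n_ortho Number of orthogonal components (>= 0; at most the rank of
#'   the scaled X minus one).
#' @return An object of class `opls` with scaling parameters, weights
#'   (`w`, unit norm), orthogonal weights/loadings/scores (`w_ortho`,
#'   `p_ortho`, `t_ortho`), predictive score/loading (`t`, `p`), response
#'   loading `q`, the regression vector `coefficients` in scaled space, and
#'   fit statistics `r2x`, `r2y`, `r2`, `rmsee` plus the component label
#'   `"1 + n_ortho + 0"`.
#' @export
fit_opls <- function(x, y, n_ortho = 0) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    abort("length(y) must equal nrow(x)",
          class = "vitisaroma_validation_error")
  }
  if (sd(y) == 0) {
    abort("response y is constant; no model can be fitted",
          class = "vitisaroma_validation_error")
  }
  if (!is.numeric(n_ortho) || n_ortho < 0 || n_ortho != round(n_ortho)) {
    abort("n_ortho must be a non-negative integer",
          class = "vitisaroma_validation_error")
  }
  sx <- uv_scale(x)
  xs <- sx$x
  my <- mean(y); sy <- sd(y)
  ys <- (y - my) / sy
  rank <- qr(xs)$rank
  if (n_ortho > rank - 1) {
    abort(sprintf(
      "n_ortho = %d exceeds rank(X) - 1 = %d", n_ortho, rank - 1),
      class = "vitisaroma_validation_error")
  }
  k <- ncol(xs)
  ssx0 <- sum(xs^2)
  ssy0 <- sum(ys^2)

  w <- drop(crossprod(xs, ys))
  w <- w / sqrt(sum(w^2))
  w_ortho <- p_ortho <- t_ortho <- NULL
  ssx_comp <- numeric(0)
  xd <- xs
  if (n_ortho > 0) {
    w_ortho <- matrix(0, k, n_ortho)
    p_ortho <- matrix(0, k, n_ortho)
    t_ortho <- matrix(0, nrow(xs), n_ortho)
    for (a in seq_len(n_ortho)) {
      t <- drop(xd %*% w)
      p <- drop(crossprod(xd, t)) / sum(t^2)
      wo <- p - sum(w * p) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) {
        abort(sprintf(
          "orthogonal component %d is degenerate (no orthogonal variation left)",
          a), class = "vitisaroma_validation_error")
      }
      wo <- wo / nwo
      to <- drop(xd %*% wo)
      po <- drop(crossprod(xd, to)) / sum(to^2)
      xd <- xd - tcrossprod(to, po)
      w_ortho[, a] <- wo
      p_ortho[, a] <- po
      t_ortho[, a] <- to
      ssx_comp <- c(ssx_comp, sum(to^2) * sum(po^2))
    }
  }
  t <- drop(xd %*% w)
  p <- drop(crossprod(xd, t)) / sum(t^2)
  q <- sum(ys * t) / sum(t^2)
  ssx_pred <- sum(t^2) * sum(p^2)

  # regression vector in scaled space: sequential deflation folded into w
  b <- w
  if (n_ortho > 0) {
    # x_deflated = x (I - w_o1 p_o1') ... so fold the operators from the left
    bmat <- diag(k)
    for (a in seq_len(n_ortho)) {
      bmat <- bmat %*% (diag(k) - tcrossprod(w_ortho[, a], p_ortho[, a]))
    }
    b <- drop(bmat %*% w)
  }
  b <- b * q

  fitted_scaled <- t * q
  fitted <- my + sy * fitted_scaled
  resid_raw <- y - fitted
  n <- nrow(xs)
  a_total <- 1 + n_ortho
  # y variance explained per component (scores are mutually orthogonal)
  ssy_comp <- vapply(seq_len(n_ortho), function(a) {
    sum(t_ortho[, a] * ys)^2 / sum(t_ortho[, a]^2)
  }, numeric(1))
  ssy_pred <- sum(t * ys)^2 / sum(t^2)

  structure(list(
    x_params = sx$params,
    y_mean = my, y_sd = sy,
    w = w, p = p, t = t, q = q,
    w_ortho = w_ortho, p_ortho = p_ortho, t_ortho = t_ortho,
    coefficients = b,
    n_ortho = n_ortho,
    n_components_label = sprintf("1 + %d + 0", n_ortho),
    ssy_components = c(predictive = ssy_pred,
                       if (n_ortho > 0) setNames(
                         ssy_comp, paste0("ortho", seq_len(n_ortho)))),
    variables = names(sx$params$mean),
    n = n,
    fitted = fitted,
    y = y,
    stats = list(
      r2x = (ssx_pred + sum(ssx_comp)) / ssx0,
      r2y = 1 - sum((ys - fitted_scaled)^2) / ssy0,
      r2 = cor(fitted, y)^2,
      rmsee = sqrt(sum(resid_raw^2) / max(1, n - 1 - a_total))
    )
  ), class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("<opls> %s latent variables, %d samples x %d variables\n",
              x$n_components_label, x$n, length(x$variables)))
  cat(sprintf("  R2X %.3f | R2Y %.3f | R2 %.3f | RMSEE %.4g\n",
              x$stats$r2x, x$stats$r2y, x$stats$r2, x$stats$rmsee))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV (%d-fold): Q2Y %.3f | RMSECV %.4g\n",
                x$cv$folds, x$cv$q2y, x$cv$rmsecv))
  }
  invisible(x)
}

#' Predict from an OPLS model
#'
#' New samples are scaled with the training parameters, their orthogonal
#' variation is removed component by component, and the remaining predictive
#' projection is back-transformed to the original response scale. Adding any
#' multiple of a model orthogonal direction to a new sample therefore leaves
#' its prediction unchanged.
#'
#' @param object An `opls` model.
#' @param newdata Matrix or data frame containing at least the model's
#'   variables (missing variables are an error listing their names).
#' @param ... Unused.
#' @return A numeric vector of predictions on the original response scale.
#' @export
predict.opls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$variables, colnames(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing model variable(s): %s",
                  paste(missing, collapse = ", ")),
          class = "vitisaroma_reference_error")
  }
  xs <- uv_scale(newdata, object$x_params)$x
  if (object$n_ortho > 0) {
    for (a in seq_len(object$n_ortho)) {
      to <- drop(xs %*% object$w_ortho[, a])
      xs <- xs - tcrossprod(to, object$p_ortho[, a])
    }
  }
  t_new <- drop(xs %*% object$w)
  drop(object$y_mean + object$y_sd * t_new * object$q)
}
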