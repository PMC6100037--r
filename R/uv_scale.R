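#' Unit-variance (UV) scaling
#'
#' Centers each variable and divides by its standard deviation, the standard
#' autoscaling used before PCA and (O)PLS of metabolite tables. Fitting
#' records per-variable means and SDs; applying uses stored parameters, so
#' that new data are always scaled with training-set statistics.
#' Zero-variance variables cannot be scaled and are dropped at fit time with
#' a warning (their names are recorded in the parameters).
#'
#' @param x A numeric matrix or data frame (samples in rows).
#' @param params Optional `uv_params` from a previous fit; when supplied the
#'   stored parameters are applied (columns missing from `x` are an error).
#' @return A list with `x` (the scaled matrix) and `params` (`uv_params`:
#'   `mean`, `sd`, `dropped`).
#' @export
uv_scale <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(params)) {
    mu <- colMeans(x)
    sigma <- apply(x, 2, sd)
    dropped <- colnames(x)[sigma == 0 | !is.finite(sigma)]
    if (length(dropped) > 0) {
      warn(sprintf("dropping zero-variance variable(s): %s",
                   paste(dropped, collapse = ", ")),
           class = "vitisaroma_zero_variance")
    }
    keep <- setdiff(colnames(x), dropped)
    params <- structure(
      list(mean = mu[keep], sd = sigma[keep], dropped = dropped),
      class = "uv_params")
  }
  stopifnot(inherits(params, "uv_params"))
  missing <- setdiff(names(params$mean), colnames(x))
  if (length(missing) > 0) {
    abort(sprintf("variable(s) required by scaling parameters are missing: %s",
                  paste(missing, collapse = ", ")),
          class = "vitisaroma_reference_error")
  }
  xs <- sweep(x[, names(params$mean), drop = FALSE], 2, params$mean, `-`)
  xs <- sweep(xs, 2, params$sd, `/`)
  list(x = xs, params = params)
}

#' Invert UV scaling
#'
#' @param x_scaled A matrix in scaled space (columns matching the parameters).
#' @param params A `uv_params` object.
#' @return The matrix on the original scale.
#' @export
uv_invert <- function(x_scaled, params) {
  stopifnot(inherits(params, "uv_params"))
  x <- sweep(as.matrix(x_scaled), 2, params$sd, `*`)
  sweep(x, 2, params$mean, `+`)
}
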