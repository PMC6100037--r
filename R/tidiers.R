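# broom-style tidiers

#' Tidy an OPLS model
#'
#' One row per retained variable: predictive weight, loading, regression
#' coefficient (scaled space) and VIP.
#'
#' @param x An `opls` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.opls <- function(x, ...) {
  v <- vip(x)
  tibble(
    variable = x$variables,
    weight = unname(x$w),
    loading = unname(x$p),
    coefficient = unname(x$coefficients),
    vip = v$vip,
    direction = v$direction
  )
}

#' One-row summary of an OPLS model
#'
#' @param x An `opls` model.
#' @param ... Unused.
#' @return A one-row tibble with the fit (and, when attached by the
#'   pipeline, cross-validation) statistics.
#' @export
glance.opls <- function(x, ...) {
  tibble(
    n = x$n,
    n_variables = length(x$variables),
    components = x$n_components_label,
    r2x = x$stats$r2x,
    r2y = x$stats$r2y,
    r2 = x$stats$r2,
    rmsee = x$stats$rmsee,
    q2y = if (!is.null(x$cv)) x$cv$q2y else NA_real_,
    rmsecv = if (!is.null(x$cv)) x$cv$rmsecv else NA_real_
  )
}

#' @rdname cross_validate_opls
#' @param x An `opls_cv` object.
#' @param ... Unused.
#' @export
tidy.opls_cv <- function(x, ...) x$results

#' @rdname opls_permutation
#' @param x An `opls_permutation` object.
#' @param ... Unused.
#' @export
tidy.opls_permutation <- function(x, ...) x$results

#' @rdname opls_permutation
#' @export
glance.opls_permutation <- function(x, ...) {
  tibble(
    n_perm = x$n_perm,
    original_r2y = x$original_r2y,
    original_q2y = x$original_q2y,
    r2_intercept = x$r2_intercept,
    q2_intercept = x$q2_intercept,
    p_value = x$p_value
  )
}

#' Tidy a fitted liking pipeline
#'
#' Per-variable table of the underlying OPLS model.
#'
#' @param x A `liking_pipeline`.
#' @param ... Unused.
#' @return A tibble (see [tidy.opls()]).
#' @export
tidy.liking_pipeline <- function(x, ...) tidy(x$model)

#' One-row summary of a fitted liking pipeline
#'
#' @param x A `liking_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble with fit, cross-validation, permutation and
#'   screening summaries.
#' @export
glance.liking_pipeline <- function(x, ...) {
  tibble(
    feature_block = x$feature_block,
    n_train = length(x$training_cultivars),
    n_removed = length(x$removed_cultivars),
    components = x$model$n_components_label,
    r2x = x$model$stats$r2x,
    r2y = x$model$stats$r2y,
    q2y = x$cv$q2y,
    rmsee = x$model$stats$rmsee,
    rmsecv = x$cv$rmsecv,
    q2_intercept = if (!is.null(x$permutation)) {
      x$permutation$q2_intercept
    } else NA_real_,
    effective = x$effective
  )
}
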