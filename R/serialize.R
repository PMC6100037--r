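# versioned JSON serialization of fitted OPLS models

.opls_json_version <- "1.0"

#' Serialize an OPLS model to JSON
#'
#' Writes every quantity needed to reproduce predictions (scaling
#' parameters, weights, loadings, response scaling, coefficients) together
#' with the fit statistics and a format version, as a JSON document.
#'
#' @param model An `opls` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_opls <- function(model, path) {
  stopifnot(inherits(model, "opls"))
  doc <- list(
    format = "vitisaroma-opls",
    version = .opls_json_version,
    variables = model$variables,
    x_mean = unname(model$x_params$mean),
    x_sd = unname(model$x_params$sd),
    x_dropped = model$x_params$dropped,
    y_mean = model$y_mean,
    y_sd = model$y_sd,
    w = unname(model$w),
    p = unname(model$p),
    q = model$q,
    n_ortho = model$n_ortho,
    w_ortho = if (model$n_ortho > 0) unclass(as.data.frame(model$w_ortho)),
    p_ortho = if (model$n_ortho > 0) unclass(as.data.frame(model$p_ortho)),
    coefficients = unname(model$coefficients),
    ssy_components = unname(model$ssy_components),
    n = model$n,
    stats = model$stats,
    cv = model$cv
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Read a serialized OPLS model
#'
#' Restores a model written by [write_opls()]; the result predicts
#' identically to the original (fitted scores and training data are not
#' stored).
#'
#' @param path Path to the JSON document.
#' @return An `opls` model (without `t`, `t_ortho`, `fitted`, `y`).
#' @export
read_opls <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "vitisaroma-opls")) {
    abort(sprintf("%s is not a serialized OPLS model", path),
          class = "vitisaroma_format_error")
  }
  k <- length(doc$variables)
  params <- structure(list(
    mean = setNames(doc$x_mean, doc$variables),
    sd = setNames(doc$x_sd, doc$variables),
    dropped = doc$x_dropped %||% character(0)
  ), class = "uv_params")
  to_mat <- function(x) {
    if (is.null(x)) return(NULL)
    matrix(unlist(x), nrow = k)
  }
  structure(list(
    x_params = params,
    y_mean = doc$y_mean, y_sd = doc$y_sd,
    w = setNames(doc$w, doc$variables),
    p = doc$p, q = doc$q,
    w_ortho = to_mat(doc$w_ortho),
    p_ortho = to_mat(doc$p_ortho),
    t = NULL, t_ortho = NULL,
    coefficients = setNames(doc$coefficients, doc$variables),
    n_ortho = doc$n_ortho,
    n_components_label = sprintf("1 + %d + 0", doc$n_ortho),
    ssy_components = doc$ssy_components,
    variables = doc$variables,
    n = doc$n,
    fitted = NULL, y = NULL,
    stats = doc$stats,
    cv = doc$cv
  ), class = "opls")
}
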