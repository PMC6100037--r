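#' Variable importance in projection (VIP)
#'
#' VIP summarizes how much each variable contributes to the latent
#' components, weighted by the response variance each component explains:
#' `VIP_j = sqrt( K * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )` with
#' `K` the number of variables. Because each component's weight vector has
#' unit norm, the mean of the squared VIPs is exactly 1, which motivates
#' the usual greater-than-one selection rule.
#'
#' `type = "total"` (default) sums over the predictive and all orthogonal
#' components; since orthogonal components explain essentially no response
#' variance, their SSY weights are near zero and the total differs from the
#' predictive-only variant (`type = "predictive"`) only through that small
#' residual y-correlation. Both variants satisfy mean(VIP^2) = 1.
#'
#' @param model A fitted [fit_opls()] model.
#' @param type `"total"` or `"predictive"`.
#' @return A tibble with `variable`, `vip`, `coefficient` (the model
#'   regression vector in scaled space) and `direction`
#'   (`"positive"`/`"negative"`).
#' @export
vip <- function(model, type = c("total", "predictive")) {
  stopifnot(inherits(model, "opls"))
  type <- match.arg(type)
  w_all <- cbind(model$w, model$w_ortho)
  ssy <- model$ssy_components
  if (type == "predictive") {
    w_all <- w_all[, 1, drop = FALSE]
    ssy <- ssy[1]
  }
  k <- nrow(w_all)
  # weight columns are unit-norm by construction; normalize defensively
  wn2 <- sweep(w_all^2, 2, colSums(w_all^2), `/`)
  v <- sqrt(k * drop(wn2 %*% ssy) / sum(ssy))
  tibble(
    variable = model$variables,
    vip = unname(v),
    coefficient = unname(model$coefficients),
    direction = if_else(model$coefficients >= 0, "positive", "negative")
  )
}
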