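#' Elastic-net penalty specification with adaptive weights
#'
#' Describes the penalty applied to the high-dimensional coefficient blocks
#' during the penalized EM: a shared tuning parameter `lambda` (the incidence
#' and latency penalties use a common value by default; a separate latency
#' value can be supplied), the elastic-net mixing parameter `alpha_enet`
#' (1 = lasso, 0 = ridge), per-coefficient adaptive L1 weights, and the number
#' of adaptive re-weighting rounds `k_adaptive`. With `k_adaptive = 1` all
#' weights are 1 and the penalty is the plain elastic net; with
#' `k_adaptive = 2` the adaptive elastic net; larger values give the
#' multi-step adaptive elastic net.
#'
#' @param lambda Nonnegative penalty level for the incidence block (and the
#'   latency block unless `lambda_latency` is given).
#' @param alpha_enet Mixing parameter in \[0, 1\].
#' @param lambda_latency Optional separate latency penalty level.
#' @param weights_incidence,weights_latency Optional positive (possibly
#'   `Inf`) adaptive weight vectors; `Inf` excludes a coefficient. Default 1.
#' @param k_adaptive Integer >= 1, number of adaptive rounds.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda, alpha_enet = 1, lambda_latency = NULL,
                         weights_incidence = NULL, weights_latency = NULL,
                         k_adaptive = 1L) {
  if (lambda < 0) abort("`lambda` must be nonnegative")
  if (alpha_enet < 0 || alpha_enet > 1) abort("`alpha_enet` must be in [0, 1]")
  if (k_adaptive < 1) abort("`k_adaptive` must be >= 1")
  if (!is.null(weights_incidence) && any(weights_incidence < 0)) {
    abort("adaptive weights must be nonnegative")
  }
  if (!is.null(weights_latency) && any(weights_latency < 0)) {
    abort("adaptive weights must be nonnegative")
  }
  structure(list(lambda = lambda,
                 lambda_latency = lambda_latency %||% lambda,
                 alpha_enet = alpha_enet,
                 weights_incidence = weights_incidence,
                 weights_latency = weights_latency,
                 k_adaptive = as.integer(k_adaptive)),
            class = "penalty_spec")
}

#' Adaptive elastic-net weights from previous-round coefficients
#'
#' The multi-step adaptive rule: the L1 weight of a coefficient at round `k`
#' is the reciprocal of its absolute estimate at round `k - 1`,
#' \eqn{w_j^{(k)} = 1 / |\hat b_{p,j}^{(k-1)}|}. Coefficients estimated as
#' exactly zero receive weight `Inf` under the default hard rule, which
#' excludes them from all later rounds (this is what sharpens selection and
#' cuts false positives); the `"epsilon"` alternative floors the denominator
#' at 1e-6 so nothing is ever excluded outright.
#'
#' @param coefs Numeric vector of previous-round coefficient estimates.
#' @param zero_rule `"hard"` (default) or `"epsilon"`.
#' @return Vector of weights, same length as `coefs`.
#' @export
#' @examples
#' adaptive_weights(c(0.5, 0, 1))  # 2, Inf, 1
adaptive_weights <- function(coefs, zero_rule = c("hard", "epsilon")) {
  zero_rule <- match.arg(zero_rule)
  if (zero_rule == "epsilon") return(1 / (abs(coefs) + 1e-6))
  ifelse(coefs == 0, Inf, 1 / abs(coefs))
}

# penalty value for one block on given coefficients
penalty_value <- function(coefs, lambda, alpha_enet, weights = NULL) {
  if (!length(coefs) || lambda == 0) return(0)
  w <- weights %||% rep(1, length(coefs))
  l1 <- sum(ifelse(coefs == 0, 0, w * abs(coefs)))
  lambda * ((1 - alpha_enet) / 2 * sum(coefs^2) + alpha_enet * l1)
}
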