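#' Uncured (incidence) probability under the logistic model
#'
#' \eqn{\pi(z) = e^{z^\top b} / (1 + e^{z^\top b})} with
#' \eqn{z^\top b = b_0 + z_u^\top b_u + z_p^\top b_p}. Evaluated through the
#' log-sum-exp form so large linear predictors saturate cleanly instead of
#' overflowing.
#'
#' @param z_u,z_p Incidence covariate vectors (the intercept is implicit).
#' @param params An [mcfm_params] object.
#' @return Probability of being susceptible (uncured), in (0, 1).
#' @export
#' @examples
#' mcfm_uncured_prob(params = mcfm_params(1, 1, 1, b0 = 0))  # 0.5
mcfm_uncured_prob <- function(z_u = numeric(), z_p = numeric(), params) {
  if (length(z_u) != length(params$b_u) || length(z_p) != length(params$b_p)) {
    abort("incidence covariate length does not match coefficient length")
  }
  eta <- params$b0 + sum(z_u * params$b_u) + sum(z_p * params$b_p)
  plogis(eta)
}

#' Laplace transform of the gamma frailty
#'
#' For a gamma frailty with mean 1 and variance \eqn{1/\theta},
#' \eqn{L_W(s) = E(e^{-Ws}) = (1 + s/\theta)^{-\theta}}, computed as
#' \eqn{\exp(-\theta \log(1 + s/\theta))}. As \eqn{\theta \to \infty} it tends
#' to \eqn{e^{-s}}, the degenerate (no-heterogeneity) limit.
#'
#' @param s Nonnegative argument (vectorized).
#' @param theta Positive frailty parameter; `Inf` gives the degenerate limit.
#' @return Values in (0, 1].
#' @export
#' @examples
#' mcfm_frailty_laplace(1, 1)      # 0.5
#' mcfm_frailty_laplace(1, 1e8)    # ~ exp(-1)
mcfm_frailty_laplace <- function(s, theta) {
  if (any(s < 0)) abort("`s` must be nonnegative")
  if (length(theta) != 1 || is.na(theta) || theta <= 0) {
    abort("`theta` must be a positive scalar")
  }
  if (is.infinite(theta)) return(exp(-s))
  exp(-theta * log1p(s / theta))
}

# log of the marginal uncured survival, from the log cumulative hazard
# log S_u = -theta * log1p(exp(log_H - log theta))
log_latency_surv <- function(log_H, theta) {
  if (is.infinite(theta)) return(-exp(log_H))
  -theta * softplus(log_H - log(theta))
}

#' Marginal survival of uncured subjects
#'
#' The gamma frailty marginalized out of the conditional Weibull survival:
#' \eqn{S(t \mid Y=1, x) = (1 + \alpha t^\gamma e^{x^\top \beta}/\theta)^{-\theta}}.
#'
#' @param t Nonnegative time(s).
#' @param x_u,x_p Latency covariate vectors.
#' @param params An [mcfm_params] object.
#' @return Survival probabilities in (0, 1]; 1 at `t = 0`.
#' @export
mcfm_latency_survival <- function(t, x_u = numeric(), x_p = numeric(), params) {
  if (any(t < 0)) abort("`t` must be nonnegative")
  if (length(x_u) != length(params$beta_u) ||
      length(x_p) != length(params$beta_p)) {
    abort("latency covariate length does not match coefficient length")
  }
  eta <- sum(x_u * params$beta_u) + sum(x_p * params$beta_p)
  log_H <- log(params$alpha) + params$gamma * log(t) + eta
  out <- exp(log_latency_surv(log_H, params$theta))
  out[t == 0] <- 1
  out
}

#' Population (improper) survival function of the mixture cure frailty model
#'
#' \eqn{S_{pop}(t \mid x, z) = 1 - \pi(z) + \pi(z)\,
#' (1 + \alpha t^\gamma e^{x^\top\beta}/\theta)^{-\theta}}. It plateaus at the
#' cure fraction \eqn{1 - \pi(z)} as \eqn{t \to \infty}, hence is improper.
#'
#' @inheritParams mcfm_latency_survival
#' @inheritParams mcfm_uncured_prob
#' @return Values in (0, 1]; 1 at `t = 0`.
#' @export
mcfm_population_survival <- function(t, z_u = numeric(), z_p = numeric(),
                                     x_u = numeric(), x_p = numeric(), params) {
  pi_z <- mcfm_uncured_prob(z_u, z_p, params)
  s_u <- mcfm_latency_survival(t, x_u, x_p, params)
  1 - pi_z + pi_z * s_u
}

# per-subject log-likelihood contributions on a cure_data object;
# returns list(ll, log_pi, log_1mpi, log_Su, log_H) for reuse by fitters
loglik_parts <- function(params, data) {
  eta_z <- linpred_incidence(params, data)
  eta_x <- linpred_latency(params, data)
  log_pi <- -softplus(-eta_z)      # log plogis(eta)
  log_1mpi <- -softplus(eta_z)
  log_H <- log(params$alpha) + params$gamma * log(data$time) + eta_x
  log_Su <- log_latency_surv(log_H, params$theta)
  theta <- params$theta
  # event density: pi * alpha*gamma*t^(g-1)*e^eta * (1+H/theta)^(-theta-1)
  if (is.infinite(theta)) {
    log_dens_tail <- -exp(log_H)
  } else {
    log_dens_tail <- (1 + 1 / theta) * log_Su  # (-theta-1)*log(1+H/theta)
  }
  log_h0x <- log(params$alpha) + log(params$gamma) +
    (params$gamma - 1) * log(data$time) + eta_x
  ll_event <- log_pi + log_h0x + log_dens_tail
  # censored: log(1 - pi + pi * Su), stable via log-sum-exp
  m <- pmax(log_1mpi, log_pi + log_Su)
  ll_cens <- m + log(exp(log_1mpi - m) + exp(log_pi + log_Su - m))
  ll <- ifelse(data$event == 1, ll_event, ll_cens)
  list(ll = ll, log_pi = log_pi, log_1mpi = log_1mpi,
       log_Su = log_Su, log_H = log_H, eta_z = eta_z, eta_x = eta_x)
}

#' Observed-data log-likelihood
#'
#' The right-censored observed log-likelihood of the Weibull mixture cure
#' frailty model: events contribute the improper population density
#' \eqn{\pi(z)\,\alpha\gamma t^{\gamma-1} e^{x^\top\beta}
#' (1 + \alpha t^\gamma e^{x^\top\beta}/\theta)^{-\theta-1}}, censored
#' subjects the population survival.
#'
#' @param params An [mcfm_params] object.
#' @param data A [cure_data] object.
#' @return The scalar log-likelihood.
#' @export
mcfm_loglik <- function(params, data) {
  check_params_data(params, data)
  sum(loglik_parts(params, data)$ll)
}
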