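# internal: standardize penalized blocks to zero mean / unit variance
# (population sd, n denominator); constant columns are left unscaled and
# excluded from selection by an Inf adaptive weight at fit time
standardize_blocks <- function(data) {
  std_one <- function(m) {
    if (!ncol(m)) return(list(m = m, mu = numeric(), sd = numeric()))
    mu <- colMeans(m)
    sdv <- sqrt(colMeans(m^2) - mu^2)
    keep <- sdv > 1e-12
    sdv[!keep] <- 1
    ms <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
    list(m = ms, mu = mu, sd = sdv, constant = !keep)
  }
  z <- std_one(data$z_p); x <- std_one(data$x_p)
  data_std <- data
  data_std$z_p <- z$m; data_std$x_p <- x$m
  list(data = data_std,
       std = list(z_mu = z$mu, z_sd = z$sd, z_const = z$constant,
                  x_mu = x$mu, x_sd = x$sd, x_const = x$constant))
}

# map standardized-space parameters back to the original covariate scale;
# the latency centering constant is absorbed into the Weibull scale alpha
destandardize_params <- function(params, std) {
  out <- params
  if (length(params$b_p)) {
    out$b_p <- params$b_p / std$z_sd
    out$b0 <- params$b0 - sum(params$b_p * std$z_mu / std$z_sd)
  }
  if (length(params$beta_p)) {
    out$beta_p <- params$beta_p / std$x_sd
    out$alpha <- params$alpha * exp(-sum(params$beta_p * std$x_mu / std$x_sd))
  }
  out
}

# inverse of destandardize_params: original-scale params -> standardized space
standardize_params <- function(params, std) {
  out <- params
  if (length(params$b_p)) {
    out$b_p <- params$b_p * std$z_sd
    out$b0 <- params$b0 + sum(params$b_p * std$z_mu)
  }
  if (length(params$beta_p)) {
    out$beta_p <- params$beta_p * std$x_sd
    out$alpha <- params$alpha * exp(sum(params$beta_p * std$x_mu))
  }
  out
}

# one EM pass at fixed penalty weights; everything in the (possibly
# standardized) space of `data`. The plain EM map is accelerated by a
# squared-extrapolation (SQUAREM-type) step guarded by the penalized
# observed log-likelihood: an extrapolated iterate is kept only after one
# stabilizing EM application and only if it does not decrease the
# objective, so the recorded trace stays nondecreasing.
em_round <- function(data, penalty, init, control) {
  control$quiet_mstep <- TRUE
  # cache the combined design matrices for the M-steps
  data$X_inc <- cbind(data$z_u, data$z_p)
  data$X_lat <- cbind(data$x_u, data$x_p)
  pen_val <- function(p) {
    penalty_value(p$b_p, penalty$lambda, penalty$alpha_enet,
                  penalty$weights_incidence) +
      penalty_value(p$beta_p, penalty$lambda_latency, penalty$alpha_enet,
                    penalty$weights_latency)
  }
  obj <- function(p) sum(loglik_parts(p, data)$ll) / data$n - pen_val(p)
  negligible <- FALSE
  em_map <- function(params) {
    ex <- e_step_core(params, data)
    p <- pmin(pmax(ex$p, .EPS_P), 1 - .EPS_P)
    inc <- mcfm_m_step_incidence(p, data, penalty,
                                 init = params, control = control)
    lat <- mcfm_m_step_latency(ex$c, data, penalty,
                               init = params, control = control)
    params$b0 <- inc$b0; params$b_u <- inc$b_u; params$b_p <- inc$b_p
    params$alpha <- lat$alpha; params$gamma <- lat$gamma
    params$beta_u <- lat$beta_u; params$beta_p <- lat$beta_p
    if (is.null(control$fix_theta)) {
      th <- mcfm_m_step_frailty(ex$a, ex$b_dig, data$event,
                                bounds = control$theta_bounds)
      params$theta <- as.numeric(th)
      negligible <<- isTRUE(attr(th, "negligible_frailty"))
    } else {
      params$theta <- control$fix_theta
    }
    params
  }
  flat <- function(p) {
    c(log(p$alpha), log(p$gamma),
      if (is.finite(p$theta)) log(p$theta) else 0,
      p$b0, p$b_u, p$b_p, p$beta_u, p$beta_p)
  }
  unflat <- function(v, proto) {
    k <- 3
    proto$alpha <- exp(min(v[1], 300)); proto$gamma <- exp(min(v[2], 5))
    if (is.finite(proto$theta) && is.null(control$fix_theta)) {
      proto$theta <- min(max(exp(v[3]), control$theta_bounds[1]),
                         control$theta_bounds[2])
    }
    proto$b0 <- v[k + 1]; k <- k + 1
    take <- function(len) { out <- v[k + seq_len(len)]; k <<- k + len; out }
    proto$b_u <- take(length(proto$b_u))
    proto$b_p <- take(length(proto$b_p))
    proto$beta_u <- take(length(proto$beta_u))
    proto$beta_p <- take(length(proto$beta_p))
    proto
  }

  params <- init
  trace <- numeric(0)
  ll_pen <- obj(params)
  converged <- FALSE
  n_map <- 0L
  while (n_map < control$max_iter) {
    p0 <- params
    p1 <- em_map(p0); ll1 <- obj(p1)
    p2 <- em_map(p1); ll2 <- obj(p2)
    n_map <- n_map + 2L
    if (!is.finite(ll2)) {
      abort("EM diverged (non-finite penalized log-likelihood)")
    }
    trace <- c(trace, ll1, ll2)
    accepted <- p2; ll_acc <- ll2
    r <- flat(p1) - flat(p0)
    vv <- (flat(p2) - flat(p1)) - r
    nv <- sqrt(sum(vv^2))
    if (nv > 1e-12 && n_map + 1L <= control$max_iter) {
      step <- -max(sqrt(sum(r^2)) / nv, 1)
      p_ext <- unflat(flat(p0) - 2 * step * r + step^2 * vv, p0)
      p3 <- tryCatch(em_map(p_ext), error = function(e) NULL)
      n_map <- n_map + 1L
      if (!is.null(p3)) {
        ll3 <- obj(p3)
        if (is.finite(ll3) && ll3 >= ll_acc) {
          accepted <- p3; ll_acc <- ll3
          trace <- c(trace, ll3)
        }
      }
    }
    params <- accepted
    if (abs(ll_acc - ll_pen) < control$tol * (abs(ll_pen) + 1e-10)) {
      ll_pen <- ll_acc; converged <- TRUE; break
    }
    ll_pen <- ll_acc
  }
  list(params = params, trace = trace, n_iter = n_map,
       converged = converged, negligible_frailty = negligible,
       penalized_loglik = ll_pen)
}

#' Fit the penalized mixture cure frailty model by EM
#'
#' Runs the penalized EM algorithm: alternating posterior expectations over
#' the latent cure status and frailty ([mcfm_e_step()]) with three separable
#' penalized M-steps (logistic incidence, Weibull-frailty latency, frailty
#' parameter), repeated for `k_adaptive` adaptive elastic-net rounds with the
#' L1 weights re-set to reciprocal absolute coefficients between rounds
#' ([adaptive_weights()]). Penalized covariate blocks are standardized
#' internally; all reported coefficients are on the original scale.
#'
#' @param data A [cure_data] object, or a data frame together with the
#'   column-role arguments of [cure_data()] passed through `...`.
#' @param lambda Elastic-net penalty level (shared between incidence and
#'   latency blocks unless `lambda_latency` is given).
#' @param alpha_enet Elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @param k_adaptive Number of adaptive re-weighting rounds (1 = plain
#'   elastic net, 2 = adaptive elastic net, the default).
#' @param lambda_latency Optional separate latency penalty level.
#' @param init Optional [mcfm_params] warm start (original scale).
#' @param control A list from [mcfm_control()].
#' @param ... Column-role arguments forwarded to [cure_data()] when `data`
#'   is a plain data frame.
#' @return An object of class `mcfm_fit` with elements `params`
#'   (an [mcfm_params] on the original scale), `support_incidence` /
#'   `support_latency` (indices of nonzero penalized coefficients),
#'   `loglik_trace` (list of per-iteration penalized observed log-likelihood
#'   vectors, one per adaptive round), `loglik`, `n_iter`, `converged`,
#'   `negligible_frailty` and the `penalty` in force at the final round.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' sim <- simulate_mcfm(mcfm_design(n = 150, p_penalized = 20, s = 4,
#'                                  block_size = 5), seed = 1)
#' fit <- fit_mcfm_em(sim, lambda = 0.05, alpha_enet = 1, k_adaptive = 1)
#' glance(fit)
fit_mcfm_em <- function(data, lambda = 0, alpha_enet = 1, k_adaptive = 2L,
                        lambda_latency = NULL, init = NULL,
                        control = mcfm_control(), ...) {
  if (is.data.frame(data)) data <- cure_data(data, ...)
  stopifnot(inherits(data, "cure_data"))
  if (!any(data$event == 1)) abort("cannot fit: no events in the data")

  if (control$standardize) {
    sb <- standardize_blocks(data)
    dstd <- sb$data; std <- sb$std
  } else {
    dstd <- data
    std <- list(z_mu = rep(0, ncol(data$z_p)), z_sd = rep(1, ncol(data$z_p)),
                z_const = rep(FALSE, ncol(data$z_p)),
                x_mu = rep(0, ncol(data$x_p)), x_sd = rep(1, ncol(data$x_p)),
                x_const = rep(FALSE, ncol(data$x_p)))
  }

  params <- if (is.null(init)) mcfm_init_params(dstd) else
    standardize_params(init, std)
  if (!is.null(control$fix_theta)) params$theta <- control$fix_theta

  base_w_inc <- rep(1, ncol(data$z_p)); base_w_inc[std$z_const] <- Inf
  base_w_lat <- rep(1, ncol(data$x_p)); base_w_lat[std$x_const] <- Inf
  w_inc <- base_w_inc; w_lat <- base_w_lat

  traces <- list(); total_iter <- 0L
  for (round in seq_len(k_adaptive)) {
    pen <- penalty_spec(lambda, alpha_enet, lambda_latency,
                        weights_incidence = w_inc, weights_latency = w_lat,
                        k_adaptive = 1L)
    res <- em_round(dstd, pen, params, control)
    params <- res$params
    traces[[round]] <- res$trace
    total_iter <- total_iter + res$n_iter
    if (round < k_adaptive) {
      w_inc <- pmax(adaptive_weights(params$b_p, control$zero_rule),
                    ifelse(is.infinite(base_w_inc), Inf, 0))
      w_lat <- pmax(adaptive_weights(params$beta_p, control$zero_rule),
                    ifelse(is.infinite(base_w_lat), Inf, 0))
    }
  }

  params_orig <- destandardize_params(params, std)
  structure(list(
    params = params_orig,
    params_std = params,
    std = std,
    support_incidence = which(params$b_p != 0),
    support_latency = which(params$beta_p != 0),
    loglik_trace = traces,
    penalized_loglik = res$penalized_loglik,
    loglik = mcfm_loglik(params_orig, data),
    n_iter = total_iter,
    converged = res$converged,
    negligible_frailty = res$negligible_frailty,
    penalty = penalty_spec(lambda, alpha_enet, lambda_latency,
                           weights_incidence = w_inc,
                           weights_latency = w_lat,
                           k_adaptive = as.integer(k_adaptive)),
    control = control,
    n = data$n,
    method = "penMCFM(EM)"
  ), class = "mcfm_fit")
}

#' @export
print.mcfm_fit <- function(x, ...) {
  cat("<mcfm_fit> ", x$method, "  n =", x$n, "\n")
  cat(sprintf("  lambda=%.4g alpha_enet=%.2g k_adaptive=%d\n",
              x$penalty$lambda, x$penalty$alpha_enet, x$penalty$k_adaptive))
  cat(sprintf("  alpha=%.4g gamma=%.4g theta=%.4g%s\n",
              x$params$alpha, x$params$gamma, x$params$theta,
              if (isTRUE(x$negligible_frailty)) " (negligible frailty)" else ""))
  cat(sprintf("  selected: %d incidence, %d latency; loglik %.4f; %d EM iters%s\n",
              length(x$support_incidence), length(x$support_latency),
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predictions from a fitted mixture cure frailty model
#'
#' @param object An `mcfm_fit`.
#' @param data A [cure_data] object (or data frame plus role arguments).
#' @param type `"uncured"` for \eqn{\hat\pi(z)}, `"risk"` for the latency
#'   linear predictor \eqn{x^\top\hat\beta}, `"survival"` for the population
#'   survival at the observed times.
#' @param ... Column-role arguments forwarded to [cure_data()].
#' @return A tibble with one row per subject and a `.pred` column.
#' @export
predict.mcfm_fit <- function(object, data, type = c("uncured", "risk", "survival"),
                             ...) {
  type <- match.arg(type)
  if (is.data.frame(data)) data <- cure_data(data, ...)
  check_params_data(object$params, data)
  parts <- loglik_parts(object$params, data)
  val <- switch(type,
    uncured = plogis(parts$eta_z),
    risk = parts$eta_x,
    survival = exp(parts$log_1mpi) + exp(parts$log_pi + parts$log_Su))
  tibble::tibble(.pred = val)
}
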