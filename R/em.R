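#' E-step posterior expectations of the latent cure status and frailty
#'
#' Given current parameters, computes for every subject the conditional
#' expectations that drive the EM: `p` = E(Y | data) (posterior probability
#' of being uncured; exactly 1 for events), `a` = E(W | data),
#' `b_dig` = E(log W | data) (involving the digamma function), and
#' `c` = E(WY | data), where W is the gamma frailty and Y the latent
#' uncured indicator.
#'
#' @param params An [mcfm_params] object.
#' @param data A [cure_data] object.
#' @return A tibble with columns `p`, `a`, `b_dig`, `c`, one row per subject.
#' @export
mcfm_e_step <- function(params, data) {
  check_params_data(params, data)
  tibble::as_tibble(e_step_core(params, data))
}

# hot-path E-step without validation or tibble construction
e_step_core <- function(params, data) {
  parts <- loglik_parts(params, data)
  delta <- data$event
  theta <- params$theta

  # posterior uncured probability for censored subjects
  m <- pmax(parts$log_1mpi, parts$log_pi + parts$log_Su)
  p_cens <- exp(parts$log_pi + parts$log_Su - m) /
    (exp(parts$log_1mpi - m) + exp(parts$log_pi + parts$log_Su - m))
  p <- ifelse(delta == 1, 1, p_cens)

  if (is.infinite(theta)) {
    # degenerate frailty: W == 1
    a <- rep(1, data$n)
    b_dig <- rep(0, data$n)
    cc <- p
  } else {
    # log(theta + alpha t^gamma e^{x'beta})
    log_th_H <- log(theta) + softplus(parts$log_H - log(theta))
    uncured_mean <- (delta + theta) * exp(-log_th_H)   # E(W | Y=1, data)
    a <- p * uncured_mean + (1 - p) * (delta + theta) / theta
    b_dig <- (1 - p) * (digamma(delta + theta) - log(theta)) +
      p * (digamma(delta + theta) - log_th_H)
    cc <- p * uncured_mean
  }
  list(p = p, a = a, b_dig = b_dig, c = cc)
}

#' Incidence M-step: penalized fractional-response logistic regression
#'
#' Minimizes the negative expected incidence log-likelihood
#' \deqn{-\frac1n \sum_i [p_i z_i^\top b - \log(1 + e^{z_i^\top b})]
#'  + \lambda\left[\frac{1-\alpha_{Enet}}{2}\|b_p\|_2^2 +
#'    \alpha_{Enet} \sum_j w_j |b_{p,j}|\right]}
#' over \eqn{b = (b_0, b_u, b_p)}, where the responses `p` are posterior
#' uncured probabilities in \[0, 1\] (not 0/1, so an off-the-shelf penalized
#' logistic solver does not apply). Solved by iteratively reweighted least
#' squares with an elastic-net coordinate-descent inner loop and a
#' step-halving safeguard; only `b_p` is penalized.
#'
#' @param p Posterior uncured probabilities, length n.
#' @param data A [cure_data] object.
#' @param penalty A [penalty_spec].
#' @param init Optional list with `b0`, `b_u`, `b_p` warm-start values.
#' @param control See [mcfm_control()].
#' @return A list with `b0`, `b_u`, `b_p`, the attained objective value
#'   `objective`, and `converged`.
#' @export
mcfm_m_step_incidence <- function(p, data, penalty, init = NULL,
                                  control = mcfm_control()) {
  stopifnot(length(p) == data$n, all(p >= 0 & p <= 1))
  X <- data$X_inc %||% cbind(data$z_u, data$z_p)
  n_u <- ncol(data$z_u); n_p <- ncol(data$z_p)
  w_ad <- penalty$weights_incidence %||% rep(1, n_p)
  l1 <- c(rep(0, n_u), penalty$lambda * penalty$alpha_enet * w_ad)
  l2 <- c(rep(0, n_u), rep(penalty$lambda * (1 - penalty$alpha_enet), n_p))

  beta <- c(init$b_u %||% rep(0, n_u), init$b_p %||% rep(0, n_p))
  beta[!is.finite(l1)] <- 0
  b0 <- init$b0 %||% 0

  obj <- function(b0, beta) {
    eta <- rep(b0, data$n)
    if (ncol(X)) eta <- eta + drop(X %*% beta)
    -mean(p * eta - softplus(eta)) +
      penalty_value(beta[seq_len(n_p) + n_u], penalty$lambda,
                    penalty$alpha_enet, w_ad)
  }
  f_old <- obj(b0, beta)
  converged <- FALSE
  for (it in seq_len(control$irls_max)) {
    eta <- rep(b0, data$n)
    if (ncol(X)) eta <- eta + drop(X %*% beta)
    mu <- plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (p - mu) / wts
    fit <- cd_enet(X, wts, z - eta, beta, b0, TRUE, l1, l2,
                   control$cd_tol, control$cd_max_sweeps)
    b0_new <- fit$icpt; beta_new <- fit$beta
    f_new <- obj(b0_new, beta_new)
    # safeguard: back-track toward the previous iterate if the surrogate
    # step overshoots the true objective
    step <- 1
    while ((is.na(f_new) || f_new > f_old + 1e-14) && step > 1e-10) {
      step <- step / 2
      b0_new <- b0 + step * (fit$icpt - b0)
      beta_new <- beta + step * (fit$beta - beta)
      f_new <- obj(b0_new, beta_new)
    }
    moved <- abs(f_old - f_new)
    b0 <- b0_new; beta <- beta_new; f_old <- f_new
    if (moved < control$mstep_tol) { converged <- TRUE; break }
  }
  if (!converged && !isTRUE(control$quiet_mstep)) {
    warn("incidence M-step: inner solver hit iteration cap")
  }
  list(b0 = b0,
       b_u = beta[seq_len(n_u)],
       b_p = beta[n_u + seq_len(n_p)],
       objective = f_old, converged = converged)
}

#' Latency M-step: penalized Weibull regression with frailty offsets
#'
#' Minimizes
#' \deqn{-\frac1n \sum_i [\delta_i \log(\alpha\gamma t_i^{\gamma-1}
#'   e^{x_i^\top\beta}) - c_i \alpha t_i^\gamma e^{x_i^\top\beta}]
#'  + \lambda\left[\frac{1-\alpha_{Enet}}{2}\|\beta_p\|_2^2 +
#'    \alpha_{Enet} \sum_l w_l |\beta_{p,l}|\right]}
#' over \eqn{(\alpha, \gamma, \beta_u, \beta_p)}, where `c` are the E-step
#' frailty-weighted uncured expectations entering as multiplicative offsets.
#' Alternates a profile update of \eqn{(\alpha, \gamma)} (closed form in
#' \eqn{\alpha}, 1-D optimization of \eqn{\log\gamma}) with an elastic-net
#' Poisson-type coordinate-descent update of \eqn{\beta}.
#'
#' @param c_exp Nonnegative E-step expectations E(WY | data), length n; at
#'   least one must be positive.
#' @inheritParams mcfm_m_step_incidence
#' @param init Optional list with `alpha`, `gamma`, `beta_u`, `beta_p`.
#' @return A list with `alpha`, `gamma`, `beta_u`, `beta_p`, `objective`,
#'   `converged`.
#' @export
mcfm_m_step_latency <- function(c_exp, data, penalty, init = NULL,
                                control = mcfm_control()) {
  stopifnot(length(c_exp) == data$n, all(c_exp >= 0))
  if (all(c_exp == 0)) abort("all E(WY) expectations are zero: no uncured mass")
  if (!any(data$event == 1)) abort("latency M-step requires at least one event")
  X <- data$X_lat %||% cbind(data$x_u, data$x_p)
  n_u <- ncol(data$x_u); n_p <- ncol(data$x_p)
  delta <- data$event
  logt <- log(data$time)
  logc <- ifelse(c_exp > 0, log(c_exp), -Inf)
  w_ad <- penalty$weights_latency %||% rep(1, n_p)
  lam <- penalty$lambda_latency
  l1 <- c(rep(0, n_u), lam * penalty$alpha_enet * w_ad)
  l2 <- c(rep(0, n_u), rep(lam * (1 - penalty$alpha_enet), n_p))

  beta <- c(init$beta_u %||% rep(0, n_u), init$beta_p %||% rep(0, n_p))
  beta[!is.finite(l1)] <- 0
  la <- log(init$alpha %||% 1)
  lg <- log(init$gamma %||% 1)
  nd <- sum(delta)

  pen <- function(beta) penalty_value(beta[n_u + seq_len(n_p)], lam,
                                      penalty$alpha_enet, w_ad)
  ev <- delta == 1
  smooth_obj <- function(la, lg, eta) {
    g <- exp(lg)
    log_mu <- logc + la + g * logt + eta
    -(sum((la + lg + (g - 1) * logt + eta)[ev]) - sum(exp(log_mu))) /
      data$n
  }
  eta <- if (ncol(X)) drop(X %*% beta) else numeric(data$n)
  f_old <- smooth_obj(la, lg, eta) + pen(beta)
  converged <- FALSE

  for (it in seq_len(control$irls_max)) {
    # (alpha, gamma): profile alpha out, optimize log gamma on a bracket
    prof <- function(lg) {
      g <- exp(lg)
      ls <- log_sum_exp(logc + g * logt + eta)
      la_hat <- log(nd) - ls
      smooth_obj(la_hat, lg, eta)
    }
    opt <- optimize(prof, interval = pmin(pmax(lg + c(-2, 2), -7), 5),
                    tol = 1e-12)
    if (opt$objective < prof(lg)) lg <- opt$minimum
    # keep the baseline inside a wide admissible box
    lg <- pmin(pmax(lg, -7), 5)
    la <- pmin(pmax(log(nd) - log_sum_exp(logc + exp(lg) * logt + eta),
                    -300), 300)

    # beta: penalized Poisson-type IRLS with offset log c + la + g log t
    g <- exp(lg)
    off <- logc + la + g * logt
    f_cur <- smooth_obj(la, lg, eta) + pen(beta)
    for (inner in seq_len(control$latency_inner %||% 3L)) {
      mu <- exp(pmin(off + eta, 700))
      wts <- pmin(pmax(mu, 1e-10), 1e10)
      # clip the working-response increment; the objective safeguard below
      # keeps descent exact even when the surrogate is crude
      z <- eta + pmin(pmax((delta - mu) / wts, -100), 100)
      fit <- cd_enet(X, wts, z - eta, beta, 0, FALSE, l1, l2,
                     control$cd_tol, control$cd_max_sweeps)
      beta_new <- fit$beta
      eta_new <- if (ncol(X)) drop(X %*% beta_new) else eta
      f_new <- smooth_obj(la, lg, eta_new) + pen(beta_new)
      step <- 1
      while ((is.na(f_new) || f_new > f_cur + 1e-14) && step > 1e-10) {
        step <- step / 2
        beta_new <- beta + step * (fit$beta - beta)
        eta_new <- if (ncol(X)) drop(X %*% beta_new) else eta
        f_new <- smooth_obj(la, lg, eta_new) + pen(beta_new)
      }
      beta <- beta_new; eta <- eta_new; f_cur <- f_new
    }
    moved <- abs(f_old - f_cur)
    f_old <- f_cur
    if (moved < control$mstep_tol) { converged <- TRUE; break }
  }
  if (!converged && !isTRUE(control$quiet_mstep)) {
    warn("latency M-step: inner solver hit iteration cap")
  }
  list(alpha = exp(la), gamma = exp(lg),
       beta_u = beta[seq_len(n_u)], beta_p = beta[n_u + seq_len(n_p)],
       objective = f_old, converged = converged)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Frailty M-step: update of the gamma frailty parameter
#'
#' Maximizes the expected frailty log-likelihood
#' \deqn{\sum_i [(\delta_i + \theta - 1) b_i - a_i \theta]
#'   + n(\theta\log\theta - \log\Gamma(\theta))}
#' over \eqn{\theta \in [10^{-4}, 10^6]}. The derivative
#' \eqn{n(\log\theta + 1 - \psi(\theta)) + \sum_i(b_i - a_i)} is strictly
#' decreasing (the objective is concave), so the update is a safeguarded 1-D
#' root search on the log scale; when no interior root exists the upper
#' bound is returned with a `negligible_frailty` attribute (frailty variance
#' \eqn{1/\theta} effectively zero, a homogeneous population).
#'
#' @param a,b_dig E-step expectations E(W | data) and E(log W | data).
#' @param event Event indicator vector (enters the objective through
#'   \eqn{\delta_i b_i}, not the derivative in \eqn{\theta}).
#' @param bounds Box for \eqn{\theta}.
#' @return The updated `theta`, with attribute `negligible_frailty`.
#' @export
mcfm_m_step_frailty <- function(a, b_dig, event, bounds = c(1e-4, 1e6)) {
  n <- length(a)
  stopifnot(length(b_dig) == n, length(event) == n)
  s <- sum(b_dig - a)
  dobj <- function(log_theta) {
    theta <- exp(log_theta)
    n * (log_theta + 1 - digamma(theta)) + s
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  if (dobj(hi) >= 0) {
    return(structure(bounds[2], negligible_frailty = TRUE))
  }
  if (dobj(lo) <= 0) {
    return(structure(bounds[1], negligible_frailty = FALSE))
  }
  root <- uniroot(dobj, c(lo, hi), tol = 1e-12)
  structure(exp(root$root), negligible_frailty = FALSE)
}

#' Initial parameter values for the EM
#'
#' Cox regression estimates for the unpenalized latency coefficients
#' \eqn{\beta_u}, moment estimates for the Weibull parameters
#' \eqn{(\alpha, \gamma)} from the observed event times (matching the
#' coefficient of variation for the shape, then the mean for the scale),
#' all remaining coefficients 0 and \eqn{\theta = 1}. If moment matching
#' fails (e.g. all event times equal), falls back to \eqn{\gamma = 1},
#' \eqn{\alpha = 1 / \bar t_{event}} with a warning.
#'
#' @param data A [cure_data] object with at least one event.
#' @return An [mcfm_params] object.
#' @export
mcfm_init_params <- function(data) {
  stopifnot(inherits(data, "cure_data"))
  if (!any(data$event == 1)) abort("initialization requires at least one event")
  te <- data$time[data$event == 1]

  wb <- tryCatch(weibull_moments(te), error = function(e) NULL)
  if (is.null(wb)) {
    warn("Weibull moment matching failed; falling back to gamma=1")
    wb <- list(alpha = 1 / mean(te), gamma = 1)
  }
  beta_u <- rep(0, ncol(data$x_u))
  if (ncol(data$x_u) > 0) {
    cox <- tryCatch(
      survival::coxph(survival::Surv(data$time, data$event) ~ data$x_u),
      error = function(e) NULL)
    if (!is.null(cox)) {
      cf <- coef(cox)
      cf[!is.finite(cf)] <- 0
      beta_u <- unname(cf)
    }
  }
  mcfm_params(alpha = wb$alpha, gamma = wb$gamma, theta = 1,
              b0 = 0, b_u = rep(0, ncol(data$z_u)),
              b_p = rep(0, ncol(data$z_p)),
              beta_u = beta_u, beta_p = rep(0, ncol(data$x_p)))
}

# moment estimates for S(t) = exp(-alpha t^gamma): match CV for the shape,
# then the mean for the scale
weibull_moments <- function(t_event) {
  m <- mean(t_event); s <- sd(t_event)
  if (!is.finite(s) || s <= 0 || m <= 0) abort("degenerate event times")
  cv2 <- (s / m)^2
  f <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
  k <- uniroot(f, c(0.08, 80), tol = 1e-10)$root
  scale_w <- m / gamma(1 + 1 / k)
  list(alpha = scale_w^(-k), gamma = k)
}

#' Control settings for the penalized EM and inner solvers
#'
#' @param tol Relative-change convergence tolerance on the penalized observed
#'   log-likelihood between EM iterations.
#' @param max_iter Maximum EM iterations per adaptive round.
#' @param irls_max Maximum outer IRLS iterations inside each M-step.
#' @param cd_tol,cd_max_sweeps Coordinate-descent stopping tolerance
#'   (max coefficient change) and sweep cap.
#' @param mstep_tol Objective-change tolerance terminating an M-step.
#' @param theta_bounds Box constraint for the frailty parameter.
#' @param fix_theta Optional fixed frailty parameter (skips the frailty
#'   M-step); use a large value or `Inf` for a frailty-free fit.
#' @param zero_rule Adaptive-weight rule for exactly-zero coefficients, see
#'   [adaptive_weights()].
#' @param standardize Standardize penalized covariate blocks internally
#'   (coefficients are always reported on the original scale).
#' @return A named list.
#' @export
mcfm_control <- function(tol = 1e-6, max_iter = 500L, irls_max = 15L,
                         cd_tol = 1e-8, cd_max_sweeps = 100L,
                         mstep_tol = 1e-11, theta_bounds = c(1e-4, 1e6),
                         fix_theta = NULL, zero_rule = "hard",
                         standardize = TRUE, latency_inner = 3L) {
  list(tol = tol, max_iter = as.integer(max_iter),
       irls_max = as.integer(irls_max), cd_tol = cd_tol,
       cd_max_sweeps = as.integer(cd_max_sweeps), mstep_tol = mstep_tol,
       theta_bounds = theta_bounds, fix_theta = fix_theta,
       zero_rule = zero_rule, standardize = standardize,
       latency_inner = as.integer(latency_inner))
}

#' Light-weight control for path and cross-validation fitting
#'
#' A generalized-EM variant of [mcfm_control()]: each M-step takes only a
#' few safeguarded inner steps instead of iterating to full stationarity.
#' Warm starts plus monotone inner steps preserve the EM ascent property,
#' while cutting the cost of fitting dozens of warm-started penalty levels
#' inside cross-validation. Final models should be refit with the default
#' control.
#'
#' @param ... Overrides passed on to [mcfm_control()].
#' @return A control list.
#' @export
mcfm_control_path <- function(...) {
  defaults <- list(tol = 1e-4, max_iter = 60L, irls_max = 2L,
                   cd_tol = 1e-6, cd_max_sweeps = 20L, mstep_tol = 1e-8,
                   latency_inner = 2L)
  do.call(mcfm_control, utils::modifyList(defaults, list(...)))
}
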