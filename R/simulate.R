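#' Simulation design for the high-dimensional mixture cure frailty model
#'
#' Describes the data-generating process used throughout the simulation
#' studies: a 3-level categorical unpenalized incidence covariate, i.i.d.
#' standard-normal unpenalized latency covariates, a shared block-correlated
#' Gaussian penalized block (within-block correlation \eqn{\rho^{|i-j|}}),
#' sparse equal-magnitude signals `v` placed one per block, Weibull baseline
#' \eqn{(\alpha, \gamma) = (1.25, 2.5)}, gamma frailty \eqn{\theta = 0.5},
#' and independent exponential censoring with rate `censor_rate`.
#'
#' @param n Number of subjects (default 500).
#' @param p_penalized Size of the shared penalized covariate block
#'   (default 1000).
#' @param n_x_u Number of standard-normal unpenalized latency covariates.
#' @param s Number of nonzero penalized coefficients per block vector.
#' @param v Common magnitude of the nonzero coefficients.
#' @param rho Within-block correlation base; pairwise correlation
#'   \eqn{\rho^{|i-j|}} inside each block, 0 across blocks.
#' @param block_size Block size of the covariance (default 50).
#' @param b0_bu Incidence intercept and the two dummy coefficients of the
#'   categorical covariate (reference = first level).
#' @param cat_probs Level probabilities of the categorical covariate.
#' @param beta_u_range Range of the uniform law for \eqn{\beta_u} (redrawn
#'   per dataset).
#' @param alpha,gamma,theta Weibull scale/shape and frailty parameter.
#' @param censor_rate Rate of the independent exponential censoring law
#'   (0 disables censoring).
#' @param signal_index_rule `"block_start"` places each signal at the first
#'   index of its block; `"spread"` at equally spaced indices.
#' @return A `mcfm_design` list.
#' @export
mcfm_design <- function(n = 500, p_penalized = 1000, n_x_u = 10, s = 20,
                        v = 0.5, rho = 0, block_size = 50,
                        b0_bu = c(-2, -1, 1), cat_probs = c(0.4, 0.35, 0.25),
                        beta_u_range = c(-3, 3), alpha = 1.25, gamma = 2.5,
                        theta = 0.5, censor_rate = 0.5,
                        signal_index_rule = c("block_start", "spread")) {
  signal_index_rule <- match.arg(signal_index_rule)
  if (abs(sum(cat_probs) - 1) > 1e-8) abort("`cat_probs` must sum to 1")
  n_blocks <- ceiling(p_penalized / block_size)
  if (s > n_blocks && signal_index_rule == "block_start") {
    abort("`s` exceeds the number of blocks under one-signal-per-block placement")
  }
  structure(list(n = n, p_penalized = p_penalized, n_x_u = n_x_u, s = s,
                 v = v, rho = rho, block_size = block_size, b0_bu = b0_bu,
                 cat_probs = cat_probs, beta_u_range = beta_u_range,
                 alpha = alpha, gamma = gamma, theta = theta,
                 censor_rate = censor_rate,
                 signal_index_rule = signal_index_rule),
            class = "mcfm_design")
}

#' Draw covariates and true parameters for a simulation design
#'
#' Realizes the covariate blocks and the true parameter vector of an
#' [mcfm_design]: the categorical incidence covariate (dummy-encoded, first
#' level as reference), standard-normal latency covariates, the shared
#' penalized Gaussian block sampled via a per-block Cholesky factor of the
#' \eqn{\rho^{|i-j|}} Toeplitz matrix, a fresh draw of \eqn{\beta_u}, and the
#' sparse signal vectors (signal `v` at one deterministic index per block).
#'
#' @param design An [mcfm_design].
#' @param seed Optional integer seed.
#' @return A list with `z_u`, `x_u`, `p_block` (the shared penalized matrix),
#'   `params` (true [mcfm_params]), `signal_index`, and `sigma_block` (the
#'   within-block correlation matrix, for error metrics).
#' @export
build_mcfm_design <- function(design, seed = NULL) {
  stopifnot(inherits(design, "mcfm_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n; P <- design$p_penalized; bs <- design$block_size

  lev <- sample.int(length(design$cat_probs), n, replace = TRUE,
                    prob = design$cat_probs)
  z_u <- cbind(as.numeric(lev == 2), as.numeric(lev == 3))
  colnames(z_u) <- c("zu_lvl2", "zu_lvl3")

  x_u <- if (design$n_x_u > 0) {
    m <- matrix(rnorm(n * design$n_x_u), n, design$n_x_u)
    colnames(m) <- paste0("xu", seq_len(design$n_x_u))
    m
  } else matrix(numeric(), n, 0)

  # block-diagonal Gaussian: one Cholesky per Toeplitz block
  n_blocks <- ceiling(P / bs)
  sigma_block <- design$rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
  chol_b <- chol(sigma_block)
  p_block <- matrix(rnorm(n * P), n, P)
  if (design$rho != 0 && P > 0) {
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1) * bs + 1):min(b * bs, P)
      if (length(idx) == bs) {
        p_block[, idx] <- p_block[, idx] %*% chol_b
      } else {
        sb <- sigma_block[seq_along(idx), seq_along(idx)]
        p_block[, idx] <- p_block[, idx] %*% chol(sb)
      }
    }
  }
  if (P > 0) colnames(p_block) <- paste0("p", seq_len(P))

  signal_index <- if (design$s == 0) integer() else
    switch(design$signal_index_rule,
           block_start = ((seq_len(design$s) - 1) * bs) + 1,
           spread = unique(round(seq(1, P, length.out = design$s))))
  coefs <- rep(0, P)
  coefs[signal_index] <- design$v

  beta_u <- runif(design$n_x_u, design$beta_u_range[1], design$beta_u_range[2])
  params <- mcfm_params(alpha = design$alpha, gamma = design$gamma,
                        theta = design$theta, b0 = design$b0_bu[1],
                        b_u = design$b0_bu[-1], b_p = coefs,
                        beta_u = beta_u, beta_p = coefs)
  list(z_u = z_u, x_u = x_u, p_block = p_block, params = params,
       signal_index = signal_index, sigma_block = sigma_block)
}

#' Inverse of the improper population CDF
#'
#' For an uncured draw \eqn{u < \pi(z)}, inverts
#' \eqn{F_{pop}(t) = \pi(z)\{1 - (1 + \alpha t^\gamma e^{x^\top\beta}/\theta)^{-\theta}\}}:
#' \deqn{F_{pop}^{-1}(u) = \{\theta \alpha^{-1} e^{-x^\top\beta}
#'   ([1 - u/\pi(z)]^{-1/\theta} - 1)\}^{1/\gamma}.}
#' The cured region \eqn{u \ge \pi(z)} has no finite quantile and is
#' rejected. Vectorized over `u`, `pi_z`, `eta_x`.
#'
#' @param u Uniform draws in \eqn{[0, \pi(z))}.
#' @param pi_z Uncured probabilities.
#' @param eta_x Latency linear predictors \eqn{x^\top\beta}.
#' @param params An [mcfm_params] (only `alpha`, `gamma`, `theta` are used).
#' @return Event times (0 at `u = 0`).
#' @export
mcfm_inverse_cdf <- function(u, pi_z, eta_x, params) {
  if (any(u < 0)) abort("`u` must be nonnegative")
  if (any(u >= pi_z)) {
    abort("`u` >= pi(z): the cured region has no finite quantile")
  }
  theta <- params$theta
  # expm1(-(1/theta) * log1p(-u/pi)) = (1-u/pi)^(-1/theta) - 1, stable
  inner <- if (is.infinite(theta)) -log1p(-u / pi_z) else
    expm1(-log1p(-u / pi_z) / theta)
  logt <- (ifelse(inner > 0, log(inner), -Inf) +
             (if (is.infinite(theta)) 0 else log(theta)) -
             log(params$alpha) - eta_x) / params$gamma
  exp(logt)
}

#' Simulate right-censored data from the Weibull mixture cure frailty model
#'
#' Inverse-CDF sampling adapted to the improper population survival
#' function: per subject, draw \eqn{u \sim U(0,1)}; if \eqn{u \ge \pi(z_i)}
#' the subject is cured (latent event time infinite), otherwise the event
#' time is \eqn{F_{pop}^{-1}(u)}. An independent exponential censoring time
#' is drawn with rate `censor_rate`; the observed time is the minimum and
#' cured subjects are always censored. Latent cure status is stored for
#' evaluation.
#'
#' @param design An [mcfm_design], or a list as returned by
#'   [build_mcfm_design()] (explicit covariates + true parameters).
#' @param seed Optional integer seed.
#' @return A [cure_data] object with `latent_cure`, and attributes
#'   `true_params`, `signal_index`, `sigma_block`, `pi_true` (true uncured
#'   probabilities per subject).
#' @export
#' @examples
#' d <- simulate_mcfm(mcfm_design(n = 200, p_penalized = 50, s = 1), seed = 7)
#' mean(1 - d$event)  # censoring fraction
simulate_mcfm <- function(design, seed = NULL) {
  if (inherits(design, "mcfm_design")) {
    if (!is.null(seed)) set.seed(seed)
    realized <- build_mcfm_design(design)
    censor_rate <- design$censor_rate
  } else {
    stopifnot(is.list(design), !is.null(design$params))
    if (!is.null(seed)) set.seed(seed)
    realized <- design
    censor_rate <- realized$censor_rate %||% 0.5
  }
  params <- realized$params
  z_u <- realized$z_u; x_u <- realized$x_u; p_block <- realized$p_block
  n <- nrow(p_block)

  eta_z <- params$b0 +
    (if (length(params$b_u)) drop(z_u %*% params$b_u) else 0) +
    drop(p_block %*% params$b_p)
  pi_z <- plogis(eta_z)
  eta_x <- (if (length(params$beta_u)) drop(x_u %*% params$beta_u) else 0) +
    drop(p_block %*% params$beta_p)

  u <- runif(n)
  cured <- u >= pi_z
  t_event <- rep(Inf, n)
  if (any(!cured)) {
    t_event[!cured] <- mcfm_inverse_cdf(u[!cured], pi_z[!cured],
                                        eta_x[!cured], params)
  }
  t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(is.finite(t_event) & t_event <= t_cens)
  # guard against a zero observed time (u numerically 0)
  time <- pmax(time, .Machine$double.xmin)

  df <- data.frame(time = time, status = event, z_u, x_u,
                   latent_cure = as.numeric(!cured), check.names = FALSE)
  if (ncol(p_block) > 0) df <- cbind(df, as.data.frame(p_block))
  pcols <- colnames(p_block) %||% character()
  out <- cure_data(df, time = "time", status = "status",
                   z_u = colnames(z_u), x_u = colnames(x_u),
                   z_p = pcols, x_p = pcols,
                   latent_cure = "latent_cure")
  attr(out, "true_params") <- params
  attr(out, "signal_index") <- realized$signal_index
  attr(out, "sigma_block") <- realized$sigma_block
  attr(out, "pi_true") <- pi_z
  out
}

#' Censoring and cure rates of simulated datasets
#'
#' @param datasets A [cure_data] with latent truth, or a list of them.
#' @return A tibble with `censoring_pct` (mean percentage of subjects with
#'   `status = 0`) and `cured_pct` (mean percentage latently cured),
#'   averaged over the datasets.
#' @export
summarize_rates <- function(datasets) {
  if (inherits(datasets, "cure_data")) datasets <- list(datasets)
  rates <- purrr::map(datasets, function(d) {
    if (is.null(d$latent_cure)) abort("dataset lacks latent cure status")
    c(cens = 100 * mean(1 - d$event), cure = 100 * mean(1 - d$latent_cure))
  })
  m <- do.call(rbind, rates)
  tibble::tibble(censoring_pct = mean(m[, "cens"]),
                 cured_pct = mean(m[, "cure"]))
}
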