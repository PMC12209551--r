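#' Parameter set of the Weibull mixture cure frailty model
#'
#' The full parameter state \eqn{\Lambda = (\alpha, \gamma, \theta, b, \beta)}:
#' Weibull baseline cumulative hazard \eqn{H_0(t) = \alpha t^\gamma} (scale
#' \eqn{\alpha > 0}, shape \eqn{\gamma > 0}), gamma frailty with mean 1 and
#' variance \eqn{1/\theta} (\eqn{\theta > 0}), logistic incidence coefficients
#' \eqn{b = (b_0, b_u, b_p)} and latency coefficients
#' \eqn{\beta = (\beta_u, \beta_p)}. There is no latency intercept; it is
#' absorbed by \eqn{\alpha}.
#'
#' @param alpha,gamma Weibull scale and shape, both strictly positive.
#' @param theta Frailty parameter, strictly positive (frailty variance
#'   \eqn{1/\theta}); `Inf` denotes the degenerate (frailty-free) limit.
#' @param b0 Incidence intercept.
#' @param b_u,b_p Unpenalized / penalized incidence coefficients.
#' @param beta_u,beta_p Unpenalized / penalized latency coefficients.
#' @return An object of class `mcfm_params`.
#' @export
#' @examples
#' mcfm_params(alpha = 1.25, gamma = 2.5, theta = 0.5, b0 = -2,
#'             b_u = c(-1, 1), beta_u = runif(3, -1, 1))
mcfm_params <- function(alpha, gamma, theta, b0 = 0,
                        b_u = numeric(), b_p = numeric(),
                        beta_u = numeric(), beta_p = numeric()) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a positive scalar")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a positive scalar")
  }
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    abort("`theta` must be a positive scalar (Inf = no frailty)")
  }
  structure(list(alpha = alpha, gamma = gamma, theta = theta,
                 b0 = as.numeric(b0),
                 b_u = as.numeric(b_u), b_p = as.numeric(b_p),
                 beta_u = as.numeric(beta_u), beta_p = as.numeric(beta_p)),
            class = "mcfm_params")
}

#' @export
print.mcfm_params <- function(x, ...) {
  cat(sprintf("<mcfm_params> alpha=%.4g gamma=%.4g theta=%.4g b0=%.4g\n",
              x$alpha, x$gamma, x$theta, x$b0))
  cat(sprintf("  b_u[%d] b_p[%d] (%d nonzero)  beta_u[%d] beta_p[%d] (%d nonzero)\n",
              length(x$b_u), length(x$b_p), sum(x$b_p != 0),
              length(x$beta_u), length(x$beta_p), sum(x$beta_p != 0)))
  invisible(x)
}

check_params_data <- function(params, data) {
  stopifnot(inherits(params, "mcfm_params"), inherits(data, "cure_data"))
  dims <- c(b_u = ncol(data$z_u), b_p = ncol(data$z_p),
            beta_u = ncol(data$x_u), beta_p = ncol(data$x_p))
  got <- c(b_u = length(params$b_u), b_p = length(params$b_p),
           beta_u = length(params$beta_u), beta_p = length(params$beta_p))
  if (any(dims != got)) {
    off <- names(dims)[dims != got]
    abort(paste0("coefficient/covariate dimension mismatch for: ",
                 paste(off, collapse = ", ")))
  }
  invisible(TRUE)
}

# linear predictors; z includes the implicit intercept
linpred_incidence <- function(params, data) {
  eta <- rep(params$b0, data$n)
  if (length(params$b_u)) eta <- eta + drop(data$z_u %*% params$b_u)
  if (length(params$b_p)) eta <- eta + drop(data$z_p %*% params$b_p)
  eta
}

linpred_latency <- function(params, data) {
  eta <- numeric(data$n)
  if (length(params$beta_u)) eta <- eta + drop(data$x_u %*% params$beta_u)
  if (length(params$beta_p)) eta <- eta + drop(data$x_p %*% params$beta_p)
  eta
}
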