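#' Tidy a fitted mixture cure frailty model
#'
#' @param x An `mcfm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `block` (one of
#'   `"baseline"`, `"frailty"`, `"incidence"`, `"incidence_pen"`,
#'   `"latency"`, `"latency_pen"`), `estimate` and `penalized`.
#' @export
tidy.mcfm_fit <- function(x, ...) {
  p <- x$params
  lab <- function(pref, k) if (k) paste0(pref, seq_len(k)) else character()
  tibble::tibble(
    term = c("alpha", "gamma", "theta", "b0",
             lab("b_u", length(p$b_u)), lab("b_p", length(p$b_p)),
             lab("beta_u", length(p$beta_u)),
             lab("beta_p", length(p$beta_p))),
    block = c("baseline", "baseline", "frailty", "incidence",
              rep("incidence", length(p$b_u)),
              rep("incidence_pen", length(p$b_p)),
              rep("latency", length(p$beta_u)),
              rep("latency_pen", length(p$beta_p))),
    estimate = c(p$alpha, p$gamma, p$theta, p$b0, p$b_u, p$b_p,
                 p$beta_u, p$beta_p),
    penalized = c(rep(FALSE, 4), rep(FALSE, length(p$b_u)),
                  rep(TRUE, length(p$b_p)), rep(FALSE, length(p$beta_u)),
                  rep(TRUE, length(p$beta_p))))
}

#' One-row summary of a fitted mixture cure frailty model
#'
#' @inheritParams tidy.mcfm_fit
#' @return A tibble with the method label, likelihood, selected-model sizes,
#'   Weibull and frailty parameters and convergence information.
#' @export
glance.mcfm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n, loglik = x$loglik,
    alpha = x$params$alpha, gamma = x$params$gamma, theta = x$params$theta,
    n_selected_incidence = length(x$support_incidence),
    n_selected_latency = length(x$support_latency),
    lambda = if (is.null(x$penalty)) NA_real_ else x$penalty$lambda,
    alpha_enet = if (is.null(x$penalty)) NA_real_ else x$penalty$alpha_enet,
    n_iter = x$n_iter, converged = x$converged,
    negligible_frailty = isTRUE(x$negligible_frailty))
}

#' Plot a fitted mixture cure frailty model
#'
#' For EM fits, the penalized observed log-likelihood trace per adaptive
#' round (the EM ascent diagnostic); for GMIFS fits, the observed
#' log-likelihood along the stagewise path with the selected point marked.
#'
#' @param object An `mcfm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcfm_fit <- function(object, ...) {
  tr <- purrr::imap(object$loglik_trace, function(v, r) {
    tibble::tibble(round = factor(r), iteration = seq_along(v), loglik = v)
  })
  df <- dplyr::bind_rows(tr)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                         y = .data$loglik,
                                         colour = .data$round)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration",
                  y = "penalized observed log-likelihood / n",
                  colour = "adaptive round",
                  title = object$method)
  if (!is.null(object$path)) {
    gg <- ggplot2::ggplot(object$path,
                          ggplot2::aes(x = .data$step, y = .data$loglik)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$selected_step,
                          linetype = "dashed") +
      ggplot2::labs(x = "stagewise step", y = "observed log-likelihood",
                    title = paste0(object$method, " (dashed: AIC-selected)"))
  }
  gg
}

#' Plot a cross-validation surface
#'
#' Cure-adjusted concordance against `lambda` (log scale), one line per
#' `alpha_enet`, with the selected pair marked.
#'
#' @param object An `mcfm_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcfm_cv <- function(object, ...) {
  ggplot2::ggplot(object$cv_table,
                  ggplot2::aes(x = .data$lambda, y = .data$cv_score,
                               colour = factor(.data$alpha_enet))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$best_lambda,
                        linetype = "dashed") +
    ggplot2::labs(x = "lambda", y = "CV cure-adjusted C-index",
                  colour = "alpha_enet")
}
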