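#' Elastic-net penalty path for the mixture cure frailty model
#'
#' Builds the decreasing sequence of candidate `lambda` values from the
#' penalized Cox regression of `(time, status, x_u, x_p)` — the unpenalized
#' latency covariates enter with zero penalty factor — using the
#' conventional path geometry: `n_lambda` values log-equispaced from
#' \eqn{\lambda_{max}} (the smallest value at which all penalized
#' coefficients of the null model are zero, i.e. the maximal absolute null
#' score divided by \eqn{n \max(\alpha_{Enet}, 0.001)}) down to
#' `min_ratio` \eqn{\times\ \lambda_{max}}.
#'
#' @param data A [cure_data] with at least one event.
#' @param n_lambda Path length (default 50).
#' @param alpha_enet Elastic-net mixing parameter.
#' @param min_ratio Ratio of the smallest to the largest path value;
#'   defaults to 0.01 when `p > n` and 0.0001 otherwise.
#' @return A strictly decreasing positive numeric vector.
#' @export
mcfm_lambda_path <- function(data, n_lambda = 50, alpha_enet = 1,
                             min_ratio = NULL) {
  stopifnot(inherits(data, "cure_data"))
  if (!any(data$event == 1)) abort("lambda path requires at least one event")
  X <- cbind(data$x_u, data$x_p)
  if (!ncol(data$x_p)) abort("no penalized latency covariates")
  if (is.null(min_ratio)) {
    min_ratio <- if (ncol(X) >= data$n) 0.01 else 1e-4
  }
  pf <- c(rep(0, ncol(data$x_u)), rep(1, ncol(data$x_p)))
  # run glmnet at its default path length purely to obtain lambda_max (the
  # null-model score bound), then lay out the requested log-spaced grid
  fit <- suppressWarnings(glmnet::glmnet(
    X, survival::Surv(data$time, data$event), family = "cox",
    alpha = max(alpha_enet, 0.001),
    lambda.min.ratio = min_ratio, penalty.factor = pf, standardize = TRUE))
  lam_max <- fit$lambda[1]
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

# fold assignment stratified by the event indicator so every fold keeps
# events; returns an integer vector in 1..K
stratified_folds <- function(event, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(event))
  for (g in unique(event)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  fold
}

# fit the EM along a decreasing lambda path with warm starts; the path is
# abandoned (remaining entries NULL) once a fit selects more than dfmax
# penalized latency coefficients, glmnet-style
em_path_fit <- function(data, lambdas, alpha_enet, k_adaptive, control,
                        dfmax = Inf) {
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (i in seq_along(lambdas)) {
    fit <- tryCatch(
      fit_mcfm_em(data, lambda = lambdas[i], alpha_enet = alpha_enet,
                  k_adaptive = k_adaptive, init = init, control = control),
      error = function(e) NULL)
    if (is.null(fit)) break  # unstable overfit end of the path
    fits[[i]] <- fit
    init <- fit$params
    if (length(fit$support_latency) > dfmax) break
  }
  fits
}

#' Cross-validated tuning of the penalized EM
#'
#' K-fold cross-validation over a `lambda` (and optionally `alpha_enet`)
#' grid, selecting the pair that maximizes the cure-adjusted concordance
#' index [c_index_cure()] on held-out folds. Folds are stratified by the
#' event indicator. Ties are broken toward the larger `lambda` (the sparser
#' model). The latency linear predictor is the held-out risk score and the
#' fitted incidence probabilities supply the censored-subject weights;
#' cure status is treated as known only for events.
#'
#' @param data A [cure_data].
#' @param lambda Candidate penalty values; defaults to [mcfm_lambda_path()].
#' @param alpha_enet Candidate mixing values (scalar or vector).
#' @param K Number of folds (default 4).
#' @param k_adaptive Adaptive rounds used in every fit.
#' @param control Control for the final refit, see [mcfm_control()].
#' @param path_control Control for the per-fold path fits; defaults to the
#'   light generalized-EM settings of [mcfm_control_path()].
#' @param dfmax Stop each fold's path once a fit selects more than this many
#'   penalized latency coefficients (remaining smaller `lambda` values are
#'   not scored).
#' @param seed Optional seed for the fold assignment.
#' @param refit Refit on the full data at the selected pair (default TRUE).
#' @return An object of class `mcfm_cv`: a list with `cv_table` (tibble of
#'   `lambda`, `alpha_enet`, `cv_score`, `n_selected_latency`), `best_lambda`,
#'   `best_alpha_enet`, `fold` assignments, and `fit` (the refit, if
#'   requested). Supports [autoplot()].
#' @export
cv_mcfm <- function(data, lambda = NULL, alpha_enet = 1, K = 4,
                    k_adaptive = 2L, control = mcfm_control(),
                    path_control = mcfm_control_path(), seed = NULL,
                    refit = TRUE, dfmax = Inf) {
  stopifnot(inherits(data, "cure_data"))
  if (K < 2) abort("`K` must be at least 2")
  fold <- stratified_folds(data$event, K, seed)
  if (any(tapply(data$event, fold, sum) == 0)) {
    abort("a fold has zero events; reduce K")
  }

  grids <- lapply(sort(unique(alpha_enet)), function(a) {
    lam <- lambda %||% mcfm_lambda_path(data, alpha_enet = a)
    tibble::tibble(alpha_enet = a, lambda = sort(lam, decreasing = TRUE))
  })

  score_one_alpha <- function(grid) {
    a <- grid$alpha_enet[1]
    scores <- matrix(NA_real_, nrow(grid), K)
    nsel <- matrix(NA_real_, nrow(grid), K)
    for (k in seq_len(K)) {
      train <- subset_cure_data(data, fold != k)
      test <- subset_cure_data(data, fold == k)
      fits <- em_path_fit(train, grid$lambda, a, k_adaptive, path_control,
                          dfmax = dfmax)
      for (i in seq_along(fits)) {
        if (is.null(fits[[i]])) next
        pr <- loglik_parts(fits[[i]]$params, test)
        scores[i, k] <- suppressWarnings(
          c_index_cure(test$time, test$event, pr$eta_x, plogis(pr$eta_z)))
        nsel[i, k] <- length(fits[[i]]$support_latency)
      }
    }
    grid$cv_score <- rowMeans(scores, na.rm = TRUE)
    grid$n_selected_latency <- rowMeans(nsel)
    grid
  }
  cv_table <- dplyr::bind_rows(lapply(grids, score_one_alpha))

  best <- cv_table |>
    dplyr::filter(!is.na(.data$cv_score)) |>
    dplyr::arrange(dplyr::desc(.data$cv_score), dplyr::desc(.data$lambda)) |>
    dplyr::slice(1)
  if (!nrow(best)) abort("cross-validation produced no defined scores")

  fit <- NULL
  if (refit) {
    fit <- fit_mcfm_em(data, lambda = best$lambda,
                       alpha_enet = best$alpha_enet,
                       k_adaptive = k_adaptive, control = control)
  }
  structure(list(cv_table = cv_table, best_lambda = best$lambda,
                 best_alpha_enet = best$alpha_enet, fold = fold,
                 K = K, fit = fit),
            class = "mcfm_cv")
}

#' @export
print.mcfm_cv <- function(x, ...) {
  cat("<mcfm_cv> ", x$K, "-fold cross-validation, ",
      nrow(x$cv_table), " candidates\n", sep = "")
  cat(sprintf("  best: lambda=%.5g alpha_enet=%.2g (cv C-cure %.4f)\n",
              x$best_lambda, x$best_alpha_enet,
              max(x$cv_table$cv_score, na.rm = TRUE)))
  invisible(x)
}

# row subset of a cure_data
subset_cure_data <- function(data, idx) {
  out <- data
  out$time <- data$time[idx]
  out$event <- data$event[idx]
  for (blk in c("z_u", "z_p", "x_u", "x_p")) {
    out[[blk]] <- data[[blk]][idx, , drop = FALSE]
  }
  if (!is.null(data$latent_cure)) out$latent_cure <- data$latent_cure[idx]
  if (!is.null(data$latent_frailty)) {
    out$latent_frailty <- data$latent_frailty[idx]
  }
  out$n <- length(out$time)
  out
}
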