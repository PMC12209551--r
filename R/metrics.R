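#' Harrell's concordance index for censored data
#'
#' The proportion of concordant pairs among evaluable pairs, with the
#' evaluable-pair indicator
#' \eqn{I_{i,j} = I[t_i < t_j, \delta_i = 1] + I[t_i = t_j, \delta_i = 1,
#' \delta_j = 0]} and strict inequality on the risk scores in the numerator
#' (score ties contribute 0). Higher scores are expected for shorter
#' survival.
#'
#' @param time,event Observed times and event indicators.
#' @param score Risk scores (e.g. the latency linear predictor
#'   \eqn{x^\top\hat\beta}).
#' @return The concordance in \[0, 1\], or `NA` with a warning when there
#'   are no evaluable pairs.
#' @export
#' @examples
#' c_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))  # 1
c_index <- function(time, event, score) {
  c_index_cure(time, event, score,
               uncured_prob = rep(1, length(time)),
               known_uncured = rep(TRUE, length(time)))
}

#' Cure-adjusted concordance index
#'
#' Weighted concordance for mixture cure models: each pair contribution is
#' weighted by the cure-status weight of the later subject,
#' \eqn{\vartheta_j y_j + (1 - \vartheta_j)\hat\pi(z_j)} — 1 for subjects
#' with known uncured status (events), the estimated uncured probability for
#' subjects whose status is unknown (censored), and 0 for known cured
#' subjects. Reduces exactly to [c_index()] when all weights are 1.
#'
#' @inheritParams c_index
#' @param uncured_prob Estimated uncured probabilities \eqn{\hat\pi(z)}.
#' @param known_uncured Logical (or 0/1): is the cure status known? Events
#'   always imply known uncured status. On real data censored subjects are
#'   unknown; simulated latent truth may optionally be exposed.
#' @param known_status For subjects with known status, the status itself
#'   (1 = uncured, 0 = cured); defaults to 1 (the event case).
#' @return The weighted concordance in \[0, 1\], or `NA` with a warning when
#'   the total pair weight is zero.
#' @export
c_index_cure <- function(time, event, score, uncured_prob,
                         known_uncured = event == 1,
                         known_status = rep(1, length(time))) {
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n,
            length(uncured_prob) == n)
  if (any(uncured_prob < 0 | uncured_prob > 1)) {
    abort("`uncured_prob` must lie in [0, 1]")
  }
  known <- as.logical(known_uncured) | event == 1
  wt <- ifelse(known, ifelse(event == 1, 1, known_status),
               uncured_prob)
  # evaluable pairs: I[t_i < t_j, d_i = 1] + I[t_i = t_j, d_i = 1, d_j = 0]
  ti <- matrix(time, n, n); tj <- t(ti)
  di <- matrix(event, n, n); dj <- t(di)
  I_ij <- (ti < tj & di == 1) + (ti == tj & di == 1 & dj == 0)
  diag(I_ij) <- 0
  wj <- matrix(wt, n, n, byrow = TRUE)
  si <- matrix(score, n, n); sj <- t(si)
  num <- sum((si > sj) * wj * I_ij)
  den <- sum(wj * I_ij)
  if (den == 0) {
    warn("no evaluable pairs with positive weight; concordance undefined")
    return(NA_real_)
  }
  num / den
}

#' Variable-selection accuracy of estimated sparse coefficients
#'
#' Sensitivity (share of true nonzeros estimated nonzero), specificity
#' (share of true zeros estimated zero), false positive rate
#' (share of true zeros estimated nonzero, = 1 - specificity) and the
#' selected-model size.
#'
#' @param true_coefs,est_coefs Equal-length numeric vectors.
#' @return A tibble with `sensitivity`, `specificity`, `fpr`, `n_selected`;
#'   entries are `NA` when their denominator is empty.
#' @export
selection_metrics <- function(true_coefs, est_coefs) {
  stopifnot(length(true_coefs) == length(est_coefs))
  nz <- true_coefs != 0
  sel <- est_coefs != 0
  sens <- if (any(nz)) mean(sel[nz]) else NA_real_
  spec <- if (any(!nz)) mean(!sel[!nz]) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec,
                 fpr = if (is.na(spec)) NA_real_ else 1 - spec,
                 n_selected = sum(sel))
}

#' Relative model error and estimation error against an oracle fit
#'
#' \deqn{RME = \frac{(\hat\beta - \beta)^\top \Sigma (\hat\beta - \beta)}
#'   {(\hat\beta^* - \beta)^\top \Sigma (\hat\beta^* - \beta)}, \qquad
#'   ERR = \frac{\|\hat\beta - \beta\|_2^2}{\|\hat\beta^* - \beta\|_2^2}}
#' where \eqn{\beta} is the truth, \eqn{\hat\beta^*} the oracle estimate
#' (an unpenalized fit restricted to the true support) and \eqn{\Sigma} the
#' covariate covariance. With \eqn{\Sigma = I} the two coincide.
#'
#' @param true_coefs,est_coefs,oracle_coefs Equal-length coefficient vectors.
#' @param sigma Covariate covariance matrix (or `NULL` for the identity).
#' @return A tibble with `rme` and `err` (`NA` with a warning if the oracle
#'   error is zero).
#' @export
rme_err <- function(true_coefs, est_coefs, oracle_coefs, sigma = NULL) {
  p <- length(true_coefs)
  stopifnot(length(est_coefs) == p, length(oracle_coefs) == p)
  d <- est_coefs - true_coefs
  d0 <- oracle_coefs - true_coefs
  quad <- function(v) {
    if (is.null(sigma)) sum(v^2) else drop(v %*% sigma %*% v)
  }
  den_r <- quad(d0); den_e <- sum(d0^2)
  if (den_r <= 0 || den_e <= 0) {
    warn("oracle estimate equals the truth; relative errors undefined")
    return(tibble::tibble(rme = NA_real_, err = NA_real_))
  }
  tibble::tibble(rme = quad(d) / den_r, err = sum(d^2) / den_e)
}

#' Bias and MSE of estimated uncured probabilities across replicates
#'
#' Averages first within each replicate dataset over subjects, then over
#' replicates: \eqn{Bias = M^{-1}\sum_k n^{-1}\sum_i (\hat\pi_k(z_i) -
#' \pi_k(z_i))} and the analogous mean of squared differences for the MSE.
#'
#' @param pi_true,pi_est Lists (one element per replicate) of per-subject
#'   uncured probability vectors, or single numeric vectors for one
#'   replicate.
#' @return A tibble with `bias` (signed) and `mse`.
#' @export
pi_bias_mse <- function(pi_true, pi_est) {
  if (is.numeric(pi_true)) pi_true <- list(pi_true)
  if (is.numeric(pi_est)) pi_est <- list(pi_est)
  stopifnot(length(pi_true) == length(pi_est))
  per <- purrr::map2(pi_true, pi_est, function(tr, es) {
    stopifnot(length(tr) == length(es))
    c(bias = mean(es - tr), mse = mean((es - tr)^2))
  })
  m <- do.call(rbind, per)
  tibble::tibble(bias = mean(m[, "bias"]), mse = mean(m[, "mse"]))
}

#' Prognostic risk score and median dichotomization
#'
#' Builds the linear prognostic risk score
#' \eqn{PRS_i = \hat\theta_1 x_{i1} + \dots + \hat\theta_{P^*} x_{iP^*}}
#' from (averaged) selected-feature coefficients, aligning features by name,
#' and splits subjects at the median score into high- and low-risk groups
#' (scores equal to the median go to the low-risk group). The group labels
#' are intended for downstream Kaplan-Meier / log-rank comparison.
#'
#' @param expression A data frame or matrix of feature values (subjects in
#'   rows, named feature columns).
#' @param coefs A named numeric vector of coefficients for the selected
#'   features; every name must match a column of `expression`.
#' @return A tibble with `score` and `group` (`"high"`/`"low"`); `group` is
#'   `NA` with a warning if all coefficients are zero.
#' @export
#' @examples
#' expr <- tibble::tibble(g1 = c(2, 1, 0, -1), g2 = c(1, 1, 0, 0))
#' prognostic_risk_score(expr, c(g1 = 1, g2 = -1))
prognostic_risk_score <- function(expression, coefs) {
  expression <- as.data.frame(expression)
  miss <- setdiff(names(coefs), names(expression))
  if (length(miss)) {
    abort(paste0("coefficients without matching features: ",
                 paste(miss, collapse = ", ")))
  }
  X <- as.matrix(expression[names(coefs)])
  score <- drop(X %*% coefs)
  if (all(coefs == 0)) {
    warn("all coefficients are zero; risk grouping undefined")
    return(tibble::tibble(score = score, group = NA_character_))
  }
  med <- median(score)
  tibble::tibble(score = score,
                 group = ifelse(score > med, "high", "low"))
}
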