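# oracle fit: unpenalized EM restricted to the true-support penalized
# columns, other penalized coefficients forced to zero; same initialization
# rules as the main fitter. Returns full-length b_p / beta_p vectors.
oracle_fit <- function(data, signal_index, control = mcfm_control()) {
  sub <- data
  sub$z_p <- data$z_p[, signal_index, drop = FALSE]
  sub$x_p <- data$x_p[, signal_index, drop = FALSE]
  fit <- fit_mcfm_em(sub, lambda = 0, k_adaptive = 1L, control = control)
  P1 <- ncol(data$z_p); P2 <- ncol(data$x_p)
  b_p <- rep(0, P1); b_p[signal_index] <- fit$params$b_p
  beta_p <- rep(0, P2); beta_p[signal_index] <- fit$params$beta_p
  list(fit = fit, b_p = b_p, beta_p = beta_p)
}

# full covariance of the shared penalized block implied by the design
design_sigma <- function(sigma_block, p) {
  bs <- nrow(sigma_block)
  sigma <- matrix(0, p, p)
  for (b in seq_len(ceiling(p / bs))) {
    idx <- ((b - 1) * bs + 1):min(b * bs, p)
    sigma[idx, idx] <- sigma_block[seq_along(idx), seq_along(idx)]
  }
  sigma
}

# all per-replicate performance metrics for one fitted model
replicate_metrics <- function(fit, data_train, data_test, truth) {
  p <- fit$params
  sel_b <- selection_metrics(truth$params$b_p, p$b_p)
  sel_beta <- selection_metrics(truth$params$beta_p, p$beta_p)
  err_b <- rme_err(truth$params$b_p, p$b_p, truth$oracle_b_p, truth$sigma)
  err_beta <- rme_err(truth$params$beta_p, p$beta_p, truth$oracle_beta_p,
                      truth$sigma)
  pr_tr <- loglik_parts(p, data_train)
  pr_te <- loglik_parts(p, data_test)
  pi_true_te <- truth$pi_true_test
  tibble::tibble(
    method = fit$method,
    c_cure_train = suppressWarnings(
      c_index_cure(data_train$time, data_train$event, pr_tr$eta_x,
                   plogis(pr_tr$eta_z))),
    c_cure_test = suppressWarnings(
      c_index_cure(data_test$time, data_test$event, pr_te$eta_x,
                   plogis(pr_te$eta_z))),
    sens_b = sel_b$sensitivity, spec_b = sel_b$specificity,
    fpr_b = sel_b$fpr, nsel_b = sel_b$n_selected,
    sens_beta = sel_beta$sensitivity, spec_beta = sel_beta$specificity,
    fpr_beta = sel_beta$fpr, nsel_beta = sel_beta$n_selected,
    rme_b = err_b$rme, err_b = err_b$err,
    rme_beta = err_beta$rme, err_beta = err_beta$err,
    pi_bias = mean(plogis(pr_te$eta_z) - pi_true_te),
    pi_mse = mean((plogis(pr_te$eta_z) - pi_true_te)^2))
}

#' Replicated simulation benchmark of the cure-model fitters
#'
#' Repeats, for `M` seeded replicates of an [mcfm_design]: simulate a
#' dataset, split it 80/20 into training and testing sets, tune the EM
#' fitter by K-fold cross-validation on the training set (when requested),
#' fit the requested methods, and evaluate selection accuracy, relative
#' model/estimation errors against the support-restricted oracle fit,
#' cure-adjusted concordance and uncured-probability bias/MSE on the test
#' set. Results are fully reproducible from `(design, seed)`.
#'
#' @param design An [mcfm_design].
#' @param M Number of replicate datasets.
#' @param methods Character subset of
#'   `c("penMCFM-EM", "penMCFM-GMIFS", "MCM-GMIFS", "penCox")`.
#' @param alpha_enet Mixing value(s) for the EM cross-validation grid.
#' @param K CV folds (default 4).
#' @param k_adaptive Adaptive rounds for the EM fits.
#' @param n_lambda Length of the CV lambda path.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param train_frac Training fraction of each replicate (default 0.8).
#' @param control,gmifs_ctrl Fitter controls.
#' @param path_control Control for the CV path fits.
#' @param dfmax Passed to [cv_mcfm()]: per-fold path stop once more than
#'   this many penalized latency coefficients are selected.
#' @return A tibble of per-replicate, per-method metrics (one row each);
#'   failed replicates are dropped with a warning counting them. Aggregate
#'   with e.g. `dplyr::summarise()`.
#' @export
benchmark_mcfm <- function(design, M = 20, methods = "penMCFM-EM",
                           alpha_enet = 0.5, K = 4, k_adaptive = 2L,
                           n_lambda = 50, seed = 1, train_frac = 0.8,
                           control = mcfm_control(),
                           gmifs_ctrl = gmifs_control(),
                           path_control = mcfm_control_path(),
                           dfmax = Inf) {
  stopifnot(inherits(design, "mcfm_design"))
  methods <- match.arg(methods,
                       c("penMCFM-EM", "penMCFM-GMIFS", "MCM-GMIFS", "penCox"),
                       several.ok = TRUE)
  run_one <- function(r) {
    dat <- simulate_mcfm(design, seed = seed + r)
    truth_params <- attr(dat, "true_params")
    pi_true <- attr(dat, "pi_true")
    sig_idx <- attr(dat, "signal_index")
    sigma <- design_sigma(attr(dat, "sigma_block"), ncol(dat$z_p))

    idx_train <- sort(sample.int(dat$n, round(train_frac * dat$n)))
    tr <- subset_cure_data(dat, idx_train)
    te <- subset_cure_data(dat, setdiff(seq_len(dat$n), idx_train))
    if (!any(tr$event == 1) || !any(te$event == 1)) {
      abort("replicate split produced a set without events")
    }
    orc <- oracle_fit(tr, sig_idx, control)
    truth <- list(params = truth_params, sigma = sigma,
                  oracle_b_p = orc$b_p, oracle_beta_p = orc$beta_p,
                  pi_true_test = pi_true[setdiff(seq_len(dat$n), idx_train)])

    rows <- list()
    if ("penMCFM-EM" %in% methods) {
      cv <- cv_mcfm(tr, alpha_enet = alpha_enet, K = K,
                    k_adaptive = k_adaptive, control = control,
                    path_control = path_control, dfmax = dfmax,
                    lambda = mcfm_lambda_path(tr, n_lambda = n_lambda,
                                              alpha_enet = alpha_enet[1]))
      rows <- c(rows, list(replicate_metrics(cv$fit, tr, te, truth)))
    }
    if ("penMCFM-GMIFS" %in% methods) {
      fit <- fit_mcfm_gmifs(tr, "penMCFM", control = gmifs_ctrl)
      rows <- c(rows, list(replicate_metrics(fit, tr, te, truth)))
    }
    if ("MCM-GMIFS" %in% methods) {
      fit <- fit_mcfm_gmifs(tr, "MCM", control = gmifs_ctrl)
      rows <- c(rows, list(replicate_metrics(fit, tr, te, truth)))
    }
    if ("penCox" %in% methods) {
      rows <- c(rows, list(pencox_metrics(tr, te, truth)))
    }
    dplyr::bind_rows(rows) |>
      dplyr::mutate(replicate = r, .before = 1)
  }
  results <- purrr::map(seq_len(M), function(r) {
    tryCatch(run_one(r), error = function(e) {
      warn(paste0("replicate ", r, " failed: ", conditionMessage(e)))
      NULL
    })
  })
  failed <- sum(purrr::map_lgl(results, is.null))
  if (failed > 0) warn(paste0(failed, " of ", M, " replicates failed"))
  dplyr::bind_rows(results)
}

# thin adapter around glmnet's penalized Cox with the one-standard-error
# lambda; latency-only comparator (no cure part), plain C-index
pencox_metrics <- function(tr, te, truth) {
  X <- cbind(tr$x_u, tr$x_p)
  pf <- c(rep(0, ncol(tr$x_u)), rep(1, ncol(tr$x_p)))
  cvfit <- glmnet::cv.glmnet(X, survival::Surv(tr$time, tr$event),
                             family = "cox", alpha = 1, penalty.factor = pf,
                             nfolds = 4)
  cf <- as.numeric(coef(cvfit, s = "lambda.1se"))
  beta_p <- cf[ncol(tr$x_u) + seq_len(ncol(tr$x_p))]
  sel <- selection_metrics(truth$params$beta_p, beta_p)
  err <- rme_err(truth$params$beta_p, beta_p, truth$oracle_beta_p,
                 truth$sigma)
  score_te <- drop(cbind(te$x_u, te$x_p) %*% cf)
  score_tr <- drop(X %*% cf)
  tibble::tibble(
    method = "penCox.1se",
    c_cure_train = suppressWarnings(c_index(tr$time, tr$event, score_tr)),
    c_cure_test = suppressWarnings(c_index(te$time, te$event, score_te)),
    sens_b = NA_real_, spec_b = NA_real_, fpr_b = NA_real_,
    nsel_b = NA_integer_,
    sens_beta = sel$sensitivity, spec_beta = sel$specificity,
    fpr_beta = sel$fpr, nsel_beta = sel$n_selected,
    rme_b = NA_real_, err_b = NA_real_,
    rme_beta = err$rme, err_beta = err$err,
    pi_bias = NA_real_, pi_mse = NA_real_)
}
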