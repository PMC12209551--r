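test_that("Harrell's C matches hand cases and an exhaustive-pairs oracle", {
  expect_equal(c_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(c_index(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(c_index(c(1, 2, 3, 4), c(1, 1, 0, 1), c(4, 3, 2, 1)), 1)
  set.seed(3)
  for (rep in 1:20) {
    n <- 15
    time <- sample(1:8, n, replace = TRUE)   # ties on purpose
    event <- rbinom(n, 1, 0.6)
    score <- rnorm(n)
    if (!any(event == 1)) next
    expect_equal(c_index(time, event, score),
                 brute_c_cure(time, event, score, rep(1, n)))
  }
})

test_that("the cure-adjusted C weights pairs by cure-status knowledge", {
  # all events: reduces exactly to Harrell's C
  set.seed(4)
  for (rep in 1:5) {
    n <- 12
    time <- rexp(n); score <- rnorm(n)
    expect_equal(c_index_cure(time, rep(1, n), score, runif(n)),
                 c_index(time, rep(1, n), score))
  }
  # censored subjects weighted by estimated uncured probability
  time <- c(1, 2, 3); event <- c(1, 0, 0); score <- c(3, 2, 1)
  pi_hat <- c(0.9, 0.5, 0.25)
  wt <- c(1, 0.5, 0.25)
  expect_equal(c_index_cure(time, event, score, pi_hat),
               brute_c_cure(time, event, score, wt))
  # zero total weight is undefined
  expect_warning(
    out <- c_index_cure(c(1, 2), c(0, 0), c(1, 2), c(0, 0)),
    "undefined")
  expect_true(is.na(out))
})

test_that("cure-adjusted C equals Harrell's C under unit weights", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(5:20, 1)
    time <- round(rexp(n), 2)
    event <- rbinom(n, 1, 0.5)
    score <- rnorm(n)
    if (!any(event == 1)) next
    expect_identical(
      suppressWarnings(c_index_cure(time, event, score, rep(1, n),
                                    known_uncured = rep(TRUE, n))),
      suppressWarnings(c_index(time, event, score)))
  }
})

test_that("selection metrics follow the indicator formulas", {
  expect_equal(selection_metrics(c(1, 2, 0, 0), c(1, 2, 0, 0)),
               tibble::tibble(sensitivity = 1, specificity = 1, fpr = 0,
                              n_selected = 2L))
  r0 <- selection_metrics(c(1, 2, 0, 0), rep(0, 4))
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$specificity, 1)
  expect_equal(r0$fpr, 0)
  # truth support {1,2}, estimate support {1,3}
  r <- selection_metrics(c(1, 1, 0, 0), c(2, 0, 3, 0))
  expect_equal(unlist(r[1, 1:3]),
               c(sensitivity = 0.5, specificity = 0.5, fpr = 0.5))
  expect_true(all(abs(r$fpr - (1 - r$specificity)) < 1e-12))
  # empty denominators are undefined, not 0
  expect_true(is.na(selection_metrics(c(0, 0), c(1, 0))$sensitivity))
})

test_that("relative model error and estimation error behave as ratios", {
  truth <- c(1, 0, -1, 0)
  oracle <- c(0.8, 0, -1.1, 0)
  expect_equal(rme_err(truth, oracle, oracle),
               tibble::tibble(rme = 1, err = 1))
  expect_equal(rme_err(truth, truth, oracle),
               tibble::tibble(rme = 0, err = 0))
  expect_warning(rme_err(truth, oracle, truth), "undefined")
  # with Sigma = I the two coincide for arbitrary inputs
  set.seed(6)
  for (rep in 1:20) {
    est <- rnorm(4); orc <- truth + rnorm(4, sd = 0.3)
    r_id <- rme_err(truth, est, orc, sigma = diag(4))
    r_null <- rme_err(truth, est, orc)
    expect_equal(r_id$rme, r_id$err)
    expect_equal(r_id$rme, r_null$rme)
  }
  # a non-identity Sigma separates them
  sig <- matrix(c(2, 0.5, 0.5, 1), 2)
  r <- rme_err(c(1, 0), c(0.5, 0.4), c(0.9, 0), sigma = sig)
  expect_false(isTRUE(all.equal(r$rme, r$err)))
})

test_that("uncured-probability bias and MSE average subjects then replicates", {
  pt <- list(c(0.2, 0.4), c(0.6, 0.8))
  expect_equal(pi_bias_mse(pt, pt), tibble::tibble(bias = 0, mse = 0))
  shifted <- lapply(pt, function(v) v + 0.1)
  r <- pi_bias_mse(pt, shifted)
  expect_equal(r$bias, 0.1, tolerance = 1e-12)
  expect_equal(r$mse, 0.01, tolerance = 1e-12)
  # naive double-loop oracle on random input
  set.seed(7)
  tr <- lapply(1:4, function(i) runif(6))
  es <- lapply(1:4, function(i) runif(6))
  acc_b <- acc_m <- 0
  for (k in 1:4) {
    sb <- sm <- 0
    for (i in 1:6) {
      sb <- sb + (es[[k]][i] - tr[[k]][i])
      sm <- sm + (es[[k]][i] - tr[[k]][i])^2
    }
    acc_b <- acc_b + sb / 6; acc_m <- acc_m + sm / 6
  }
  r2 <- pi_bias_mse(tr, es)
  expect_equal(r2$bias, acc_b / 4, tolerance = 1e-12)
  expect_equal(r2$mse, acc_m / 4, tolerance = 1e-12)
})

test_that("the prognostic risk score dichotomizes at the median", {
  expr <- tibble::tibble(g1 = c(2, 1, 0, -1), g2 = c(1, 1, 0, 0))
  r <- prognostic_risk_score(expr, c(g1 = 1, g2 = -1))
  expect_equal(r$score, c(1, 0, 0, -1))
  expect_equal(r$group, c("high", "low", "low", "low"))
  # single feature with unit coefficient reproduces the feature
  r1 <- prognostic_risk_score(expr["g1"], c(g1 = 1))
  expect_equal(r1$score, expr$g1)
  expect_warning(r0 <- prognostic_risk_score(expr, c(g1 = 0, g2 = 0)),
                 "undefined")
  expect_true(all(is.na(r0$group)))
  expect_error(prognostic_risk_score(expr, c(nope = 1)), "nope")
})

test_that("all metrics are invariant to subject permutation", {
  set.seed(8)
  n <- 25
  time <- rexp(n); event <- rbinom(n, 1, 0.5); score <- rnorm(n)
  pi_hat <- runif(n)
  perm <- sample(n)
  expect_equal(c_index_cure(time, event, score, pi_hat),
               c_index_cure(time[perm], event[perm], score[perm],
                            pi_hat[perm]))
  tr <- runif(n); es <- runif(n)
  expect_equal(pi_bias_mse(tr, es), pi_bias_mse(tr[perm], es[perm]))
})
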