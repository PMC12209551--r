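test_that("the inverse population CDF inverts the improper CDF exactly", {
  pars <- mcfm_params(alpha = 1.25, gamma = 2.5, theta = 0.5, b0 = 0.4)
  expect_equal(mcfm_inverse_cdf(0, 0.6, 0, pars), 0)
  # pi = 0.5, u = 0.25, theta = alpha = gamma = 1: forward check gives t = 1
  p1 <- mcfm_params(1, 1, 1)
  expect_equal(mcfm_inverse_cdf(0.25, 0.5, 0, p1), 1, tolerance = 1e-12)
  # round trip within 1e-10 for random admissible draws
  set.seed(17)
  for (rep in 1:20) {
    pars_r <- random_params(p1u = 0, p2u = 0)
    pi_z <- plogis(pars_r$b0)
    u <- runif(1, 0, pi_z * 0.999)
    eta <- rnorm(1)
    t <- mcfm_inverse_cdf(u, pi_z, eta, pars_r)
    H <- pars_r$alpha * t^pars_r$gamma * exp(eta)
    forward <- pi_z * (1 - (1 + H / pars_r$theta)^(-pars_r$theta))
    expect_equal(forward, u, tolerance = 1e-10)
  }
  expect_error(mcfm_inverse_cdf(0.7, 0.6, 0, pars), "cured region")
})

test_that("cured subjects are censored and all-cured designs have no events", {
  n <- 300
  pars <- mcfm_params(1, 1, 1, b0 = -1e4)   # pi = 0 for everyone
  real <- list(z_u = matrix(numeric(), n, 0), x_u = matrix(numeric(), n, 0),
               p_block = matrix(numeric(), n, 0), params = pars,
               censor_rate = 0.5)
  d <- simulate_mcfm(real, seed = 23)
  expect_true(all(d$event == 0))
  expect_true(all(d$latent_cure == 0))
  d2 <- simulate_mcfm(mcfm_design(n = 400, p_penalized = 20, s = 2, v = 1,
                                  block_size = 10), seed = 24)
  expect_true(all(d2$event[d2$latent_cure == 0] == 0))
})

test_that("uncensored latency draws match the closed-form survival (KS)", {
  n <- 1e4
  pars <- mcfm_params(alpha = 1.25, gamma = 2.5, theta = 0.5, b0 = 30)
  real <- list(z_u = matrix(numeric(), n, 0), x_u = matrix(numeric(), n, 0),
               p_block = matrix(numeric(), n, 0), params = pars,
               censor_rate = 0)
  d <- simulate_mcfm(real, seed = 41)
  expect_true(all(d$event == 1))
  tt <- sort(d$time)
  ks <- max(abs((1 - seq_len(n) / n) - mcfm_latency_survival(tt, params = pars)))
  expect_lt(ks, 0.02)
})

test_that("the empirical population survival matches the model pointwise", {
  n <- 1e5
  pars <- mcfm_params(alpha = 1.25, gamma = 2.5, theta = 0.5, b0 = 0.3)
  real <- list(z_u = matrix(numeric(), n, 0), x_u = matrix(numeric(), n, 0),
               p_block = matrix(numeric(), n, 0), params = pars,
               censor_rate = 0)
  d <- simulate_mcfm(real, seed = 42)
  for (g in seq(0.1, 3, by = 0.2)) {
    expect_equal(mean(d$time > g),
                 mcfm_population_survival(g, params = pars),
                 tolerance = 0.01)
  }
})

test_that("the penalized block has the block-Toeplitz correlation", {
  des0 <- mcfm_design(n = 1e4, p_penalized = 100, s = 2, rho = 0)
  r0 <- build_mcfm_design(des0, seed = 55)
  pick <- cbind(c(1, 3, 20, 51), c(2, 60, 70, 99))
  for (k in seq_len(nrow(pick))) {
    expect_lt(abs(cor(r0$p_block[, pick[k, 1]], r0$p_block[, pick[k, 2]])),
              0.1)
  }
  des5 <- mcfm_design(n = 1e4, p_penalized = 100, s = 2, rho = 0.5)
  r5 <- build_mcfm_design(des5, seed = 56)
  # adjacent within-block pairs: correlation ~ 0.5
  expect_equal(cor(r5$p_block[, 1], r5$p_block[, 2]), 0.5, tolerance = 0.03)
  expect_equal(cor(r5$p_block[, 61], r5$p_block[, 62]), 0.5, tolerance = 0.03)
  # across blocks: independent
  expect_lt(abs(cor(r5$p_block[, 50], r5$p_block[, 51])), 0.1)
})

test_that("signals sit one per block with equal magnitude", {
  des <- mcfm_design(n = 10, p_penalized = 1000, s = 20, v = 0.7)
  r <- build_mcfm_design(des, seed = 57)
  expect_equal(r$signal_index, seq(1, 951, by = 50))
  for (b in 1:20) {
    idx <- ((b - 1) * 50 + 1):(b * 50)
    expect_equal(sum(r$params$b_p[idx] != 0), 1)
    expect_equal(sum(r$params$beta_p[idx] != 0), 1)
  }
  expect_true(all(r$params$b_p[r$signal_index] == 0.7))
  expect_identical(r$params$b_p, r$params$beta_p)
})

test_that("summarize_rates reports censoring and cure percentages", {
  df <- data.frame(t = rexp(10) + 0.1, d = 1, y = 1)
  d_all_events <- cure_data(df, "t", "d", latent_cure = "y")
  r <- summarize_rates(d_all_events)
  expect_equal(r$censoring_pct, 0)
  expect_equal(r$cured_pct, 0)
  # the study design rates at both signal extremes (small replicate sets;
  # the full-scale check lives in the acceptance suite)
  set.seed(58)
  r05 <- summarize_rates(lapply(1:5, function(i)
    simulate_mcfm(mcfm_design(v = 0.5))))
  expect_equal(r05$censoring_pct, 85, tolerance = 0.04)
  expect_equal(r05$cured_pct, 76, tolerance = 0.04)
  r25 <- summarize_rates(lapply(1:5, function(i)
    simulate_mcfm(mcfm_design(v = 2.5))))
  expect_equal(r25$censoring_pct, 63, tolerance = 0.05)
  expect_equal(r25$cured_pct, 57, tolerance = 0.05)
})

test_that("simulation is deterministic under a seed", {
  d1 <- simulate_mcfm(mcfm_design(n = 50, p_penalized = 10, s = 1,
                                  block_size = 10), seed = 77)
  d2 <- simulate_mcfm(mcfm_design(n = 50, p_penalized = 10, s = 1,
                                  block_size = 10), seed = 77)
  expect_identical(d1$time, d2$time)
  expect_identical(unname(d1$z_p), unname(d2$z_p))
})
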