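test_that("E-step expectations match the closed forms and invariants", {
  # events are known uncured
  p <- mcfm_params(1, 1, 1, b0 = 0)
  d1 <- cure_data(data.frame(t = 2, d = 1), "t", "d")
  expect_equal(mcfm_e_step(p, d1)$p, 1)

  # pi = 0: cured for sure, prior-mean frailty
  p0 <- mcfm_params(1, 1, 1, b0 = -1e4)
  d0 <- cure_data(data.frame(t = 1, d = 0), "t", "d")
  ex0 <- mcfm_e_step(p0, d0)
  expect_equal(ex0$p, 0, tolerance = 1e-10)
  expect_equal(ex0$c, 0, tolerance = 1e-10)
  expect_equal(ex0$a, 1, tolerance = 1e-10)

  # censored at t=1 with alpha=gamma=theta=1, pi=0.5:
  # p = 1/3, a = 5/6, c = 1/6, b = digamma(1) - log(2)/3
  dc <- cure_data(data.frame(t = 1, d = 0), "t", "d")
  ex <- mcfm_e_step(p, dc)
  expect_equal(ex$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$a, 5 / 6, tolerance = 1e-12)
  expect_equal(ex$c, 1 / 6, tolerance = 1e-12)
  expect_equal(ex$b_dig, digamma(1) - log(2) / 3, tolerance = 1e-12)
})

test_that("E-step satisfies its order and Jensen invariants on random draws", {
  set.seed(8)
  for (rep in 1:10) {
    pars <- random_params(p1u = 0, p2u = 1)
    df <- data.frame(t = rexp(30) + 0.05, d = rbinom(30, 1, 0.5),
                     x = rnorm(30))
    ex <- mcfm_e_step(pars, cure_data(df, "t", "d", x_u = "x"))
    expect_true(all(ex$p[df$d == 1] == 1))
    expect_true(all(ex$p >= 0 & ex$p <= 1))
    expect_true(all(ex$c >= -1e-12 & ex$c <= ex$a + 1e-12))
    expect_true(all(ex$b_dig <= log(ex$a) + 1e-10))
  }
})

test_that("E-step agrees with an importance-sampling oracle over (Y, W)", {
  # sample the latent pair from its prior, weight by the observed-data
  # density, and compare the weighted means with the analytic expectations
  set.seed(12)
  N <- 2e5
  for (rep in 1:6) {
    pars <- random_params(p1u = 0, p2u = 0)
    t_i <- runif(1, 0.2, 2); delta <- rbinom(1, 1, 0.5)
    d <- cure_data(data.frame(t = t_i, d = delta), "t", "d")
    ex <- mcfm_e_step(pars, d)
    pi_z <- plogis(pars$b0)
    H <- pars$alpha * t_i^pars$gamma
    w <- rgamma(N, pars$theta, pars$theta)
    y <- rbinom(N, 1, pi_z)
    lik <- if (delta == 1) {
      y * w * H * exp(-w * H)       # density up to t-only factors
    } else {
      ifelse(y == 1, exp(-w * H), 1)
    }
    est <- function(g) sum(lik * g) / sum(lik)
    se <- function(g) {
      mu <- est(g)
      sqrt(sum((lik / sum(lik))^2 * (g - mu)^2))
    }
    expect_lt(abs(est(y) - ex$p), 3 * se(y) + 1e-8)
    expect_lt(abs(est(w) - ex$a), 3 * se(w) + 1e-8)
    expect_lt(abs(est(w * y) - ex$c), 3 * se(w * y) + 1e-8)
    expect_lt(abs(est(log(w)) - ex$b_dig), 3 * se(log(w)) + 1e-8)
  }
})

test_that("incidence M-step solves the fractional-response problem", {
  cd <- tiny_cure_data(n = 60, seed = 2)
  set.seed(3)
  p <- runif(60)
  # full shrinkage under a large lasso penalty
  big <- mcfm_m_step_incidence(p, cd, penalty_spec(10, alpha_enet = 1))
  expect_true(all(big$b_p == 0))
  # intercept-only closed form
  no_cov <- cure_data(data.frame(t = cd$time, d = cd$event), "t", "d")
  r0 <- mcfm_m_step_incidence(p, no_cov, penalty_spec(0))
  expect_equal(r0$b0, qlogis(mean(p)), tolerance = 1e-8)
  # unpenalized fit: stationarity and a derivative-free reference
  r <- mcfm_m_step_incidence(p, cd, penalty_spec(0))
  Z <- cbind(1, cd$z_u, cd$z_p)
  cf <- c(r$b0, r$b_u, r$b_p)
  mu <- plogis(drop(Z %*% cf))
  grad <- -drop(crossprod(Z, p - mu)) / cd$n
  expect_lt(max(abs(grad)), 1e-6)
  negobj <- function(b) {
    eta <- drop(Z %*% b)
    -mean(p * eta - log1p(exp(eta)))
  }
  ref <- optim(rep(0, ncol(Z)), negobj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  expect_lte(negobj(cf), ref$value + 1e-8)
})

test_that("latency M-step solves the penalized Weibull problem", {
  set.seed(31)
  n <- 50
  df <- data.frame(t = rexp(n) + 0.05, d = rbinom(n, 1, 0.6),
                   x1 = rnorm(n), x2 = rnorm(n))
  cd <- cure_data(df, "t", "d", x_u = c("x1", "x2"))
  cc <- runif(n, 0.2, 1.5)
  # full shrinkage
  cd_pen <- cure_data(df, "t", "d", x_p = c("x1", "x2"))
  big <- mcfm_m_step_latency(cc, cd_pen, penalty_spec(10, alpha_enet = 1))
  expect_true(all(big$beta_p == 0))
  # alpha stationarity at the optimum: alpha = sum(delta) / sum(c t^g e^eta)
  r <- mcfm_m_step_latency(cc, cd, penalty_spec(0))
  eta <- drop(cd$x_u %*% r$beta_u)
  expect_equal(r$alpha, sum(df$d) / sum(cc * df$t^r$gamma * exp(eta)),
               tolerance = 1e-6)
  # objective no worse than a derivative-free reference optimizer
  negobj <- function(par) {
    la <- par[1]; lg <- par[2]; b <- par[3:4]
    e <- drop(cd$x_u %*% b); g <- exp(lg)
    -(sum((la + lg + (g - 1) * log(df$t) + e)[df$d == 1]) -
        sum(cc * exp(la) * df$t^g * exp(e))) / n
  }
  ref <- optim(rep(0, 4), negobj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
  expect_lte(r$objective, ref$value + 1e-8)
  # degenerate input
  expect_error(mcfm_m_step_latency(rep(0, n), cd, penalty_spec(0)),
               "no uncured mass")
})

test_that("frailty M-step maximizes the expected frailty likelihood", {
  # all a=1, b=digamma(1), delta=0: derivative zero exactly at theta=1
  th <- mcfm_m_step_frailty(rep(1, 25), rep(digamma(1), 25), rep(0, 25))
  expect_equal(as.numeric(th), 1, tolerance = 1e-8)
  # homogeneous population: no interior root, upper bound flagged
  th_hi <- mcfm_m_step_frailty(rep(1, 25), rep(log(1), 25), rep(0, 25))
  expect_equal(as.numeric(th_hi), 1e6)
  expect_true(attr(th_hi, "negligible_frailty"))
  # grid-search oracle on random expectations
  set.seed(14)
  for (rep in 1:5) {
    n <- 40
    a <- rgamma(n, 2, 2)
    b <- log(a) - runif(n, 0.05, 1.5)   # Jensen-consistent
    delta <- rbinom(n, 1, 0.4)
    obj <- function(theta) {
      sum((delta + theta - 1) * b - a * theta) +
        n * (theta * log(theta) - lgamma(theta))
    }
    th <- as.numeric(mcfm_m_step_frailty(a, b, delta))
    grid <- exp(seq(log(1e-3), log(100), length.out = 4000))
    expect_gte(obj(th), max(vapply(grid, obj, numeric(1))) - 1e-6)
  }
})

test_that("adaptive weights follow the reciprocal rule with hard exclusion", {
  expect_equal(adaptive_weights(c(0.5, 0, 1)), c(2, Inf, 1))
  expect_equal(adaptive_weights(rep(1, 5)), rep(1, 5))
  expect_equal(adaptive_weights(c(0.5, 0), zero_rule = "epsilon"),
               c(1 / 0.500001, 1e6), tolerance = 1e-6)
})

test_that("initialization uses Cox estimates and Weibull moments", {
  set.seed(32)
  # event times from the Weibull with alpha=1, gamma=2 (S = exp(-t^2))
  te <- rweibull(1e5, shape = 2, scale = 1)
  wm <- frailcure:::weibull_moments(te)
  expect_equal(wm$alpha, 1, tolerance = 0.02)
  expect_equal(wm$gamma, 2, tolerance = 0.02)

  cd <- tiny_cure_data(n = 80, seed = 6)
  init <- mcfm_init_params(cd)
  expect_equal(init$theta, 1)
  expect_true(all(init$b_p == 0) && all(init$beta_p == 0) && init$b0 == 0)
  cox <- survival::coxph(survival::Surv(cd$time, cd$event) ~ cd$x_u)
  expect_equal(init$beta_u, unname(coef(cox)), tolerance = 1e-8)

  # no unpenalized latency covariates: empty beta_u
  cd0 <- cure_data(tiny_cure_df(30, 7), "t", "d")
  expect_length(mcfm_init_params(cd0)$beta_u, 0)

  all_cens <- cure_data(data.frame(t = rexp(10) + 0.1, d = 0), "t", "d")
  expect_error(mcfm_init_params(all_cens), "event")
})

test_that("a huge penalty reduces the fit to the unpenalized submodel", {
  d <- simulate_mcfm(mcfm_design(n = 250, p_penalized = 40, s = 2, v = 1,
                                 block_size = 20, n_x_u = 3,
                                 beta_u_range = c(-1, 1)), seed = 33)
  ctl <- mcfm_control(tol = 1e-8)
  f1 <- fit_mcfm_em(d, lambda = 1e4, alpha_enet = 1, k_adaptive = 1,
                    control = ctl)
  expect_length(f1$support_incidence, 0)
  expect_length(f1$support_latency, 0)
  tb <- as.data.frame(tibble::as_tibble(d))
  d0 <- cure_data(tb, time = "time", status = "status",
                  z_u = c("zu_lvl2", "zu_lvl3"), x_u = paste0("xu", 1:3))
  f0 <- fit_mcfm_em(d0, lambda = 0, k_adaptive = 1, control = ctl)
  expect_equal(f1$params$b0, f0$params$b0, tolerance = 1e-3)
  expect_equal(f1$params$b_u, f0$params$b_u, tolerance = 1e-3)
  expect_equal(f1$params$gamma, f0$params$gamma, tolerance = 1e-2)
})

test_that("the penalized observed log-likelihood trace is nondecreasing", {
  for (seed in c(51, 52, 53)) {
    d <- simulate_mcfm(mcfm_design(n = 150, p_penalized = 30, s = 2, v = 1.5,
                                   block_size = 15, n_x_u = 2,
                                   beta_u_range = c(-1, 1)), seed = seed)
    f <- fit_mcfm_em(d, lambda = 0.03, alpha_enet = 0.9, k_adaptive = 2)
    for (tr in f$loglik_trace) expect_true(all(diff(tr) >= -1e-8))
  }
})

test_that("fixing a huge frailty parameter matches the frailty-free fit", {
  d <- simulate_mcfm(mcfm_design(n = 250, p_penalized = 40, s = 2, v = 1,
                                 block_size = 20, n_x_u = 3,
                                 beta_u_range = c(-1, 1)), seed = 33)
  fA <- fit_mcfm_em(d, lambda = 0.1, alpha_enet = 1, k_adaptive = 1,
                    control = mcfm_control(fix_theta = 1e8))
  fB <- fit_mcfm_em(d, lambda = 0.1, alpha_enet = 1, k_adaptive = 1,
                    control = mcfm_control(fix_theta = Inf))
  expect_equal(fA$params$b_p, fB$params$b_p, tolerance = 1e-3)
  expect_equal(fA$params$beta_p, fB$params$beta_p, tolerance = 1e-3)
  expect_equal(fA$params$b_u, fB$params$b_u, tolerance = 1e-3)
  expect_equal(fA$params$beta_u, fB$params$beta_u, tolerance = 1e-3)
})

test_that("tidy, glance and predict expose the fit as tibbles", {
  d <- simulate_mcfm(mcfm_design(n = 120, p_penalized = 10, s = 1, v = 1.5,
                                 block_size = 10, n_x_u = 2,
                                 beta_u_range = c(-1, 1)), seed = 61)
  f <- fit_mcfm_em(d, lambda = 0.05, alpha_enet = 1, k_adaptive = 1)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4 + 2 + 10 + 2 + 10)
  expect_equal(sum(td$penalized), 20)
  gl <- glance(f)
  expect_equal(gl$n, 120)
  expect_s3_class(autoplot(f), "ggplot")
  pr <- predict(f, d, type = "uncured")
  expect_true(all(pr$.pred >= 0 & pr$.pred <= 1))
})
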