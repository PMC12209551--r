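# small reusable fixtures, all generated in code

# a tiny right-censored dataset with both covariate kinds
tiny_cure_df <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(t = rexp(n) + 0.05, d = rbinom(n, 1, 0.5),
             grp = sample(c("a", "b", "c"), n, replace = TRUE),
             age = rnorm(n), g1 = rnorm(n), g2 = rnorm(n), g3 = rnorm(n))
}

tiny_cure_data <- function(n = 40, seed = 1) {
  cure_data(tiny_cure_df(n, seed), time = "t", status = "d",
            z_u = "grp", x_u = "age",
            z_p = c("g1", "g2", "g3"), x_p = c("g1", "g2", "g3"))
}

# explicit toy generating process with a single latency signal
toy_realized <- function(n = 200, p = 5, signal = 2, seed = 21,
                         censor_rate = 0.3) {
  set.seed(seed)
  beta_p <- rep(0, p); beta_p[1] <- signal
  list(z_u = matrix(numeric(), n, 0),
       x_u = matrix(rnorm(n), n, 1, dimnames = list(NULL, "xu1")),
       p_block = matrix(rnorm(n * p), n, p,
                        dimnames = list(NULL, paste0("p", seq_len(p)))),
       params = mcfm_params(alpha = 1, gamma = 1.5, theta = 1, b0 = 0.5,
                            b_p = rep(0, p), beta_u = 0.5, beta_p = beta_p),
       censor_rate = censor_rate)
}

# random admissible parameter draw for property-style tests
random_params <- function(p1u = 2, p1p = 0, p2u = 1, p2p = 0) {
  mcfm_params(alpha = runif(1, 0.3, 3), gamma = runif(1, 0.5, 3),
              theta = runif(1, 0.2, 5), b0 = rnorm(1),
              b_u = rnorm(p1u, sd = 0.5), b_p = rnorm(p1p, sd = 0.5),
              beta_u = rnorm(p2u, sd = 0.5), beta_p = rnorm(p2p, sd = 0.5))
}

# brute-force weighted concordance, double loop, independent of the package
brute_c_cure <- function(time, event, score, wt) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    I_ij <- (time[i] < time[j] && event[i] == 1) +
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (I_ij == 0) next
    den <- den + wt[j] * I_ij
    if (score[i] > score[j]) num <- num + wt[j] * I_ij
  }
  if (den == 0) return(NA_real_)
  num / den
}
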