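test_that("log prior: support boundaries and exchangeability", {
  pr <- prior_config()
  st <- tiny_state()
  base <- log_prior(st$global, st$loci, pr)
  expect_true(is.finite(base))
  g <- st$global
  g$t_div <- pr$t_max + 1
  expect_identical(log_prior(g, st$loci, pr), -Inf)
  g <- st$global; g$sigma_w <- pr$sigma_max + 0.1
  expect_identical(log_prior(g, st$loci, pr), -Inf)
  g <- st$global; g$sigma_b <- -1
  expect_identical(log_prior(g, st$loci, pr), -Inf)
  bad <- st$loci; bad$theta_r[1] <- 0
  expect_identical(log_prior(st$global, bad, pr), -Inf)
  # invariant under permuting loci
  loci3 <- data.frame(theta_s = c(1, 2, 3), theta_r = c(3, 1, 2),
                      gamma_i = c(-1, 0, 2))
  expect_equal(log_prior(st$global, loci3, pr),
               log_prior(st$global, loci3[c(3, 1, 2), ], pr))
})

test_that("NIG prior component factorizes as inverse-gamma times normal", {
  pr <- prior_config(alpha_0 = 1.3, beta_0 = 0.7, mu_0 = -0.5, n_0 = 2)
  st <- tiny_state()
  st$loci <- st$loci[0, ]   # empty loci isolates the hyper component
  lp <- log_prior(st$global, st$loci, pr)
  # independent density implementation: inverse-gamma density of sigma_b^2
  # via the gamma density of 1/sigma_b^2 with Jacobian 1/v^2, times the
  # sigma_b -> sigma_b^2 Jacobian 2*sigma_b, times N(mu | mu_0, sigma_b^2/n_0)
  v <- st$global$sigma_b^2
  ref <- dgamma(1 / v, pr$alpha_0, rate = pr$beta_0, log = TRUE) - 2 * log(v) +
    log(2 * st$global$sigma_b) +
    dnorm(st$global$mu_gamma, pr$mu_0, st$global$sigma_b / sqrt(pr$n_0),
          log = TRUE) - log(pr$t_max) - log(pr$sigma_max)
  expect_equal(lp, ref, tolerance = 1e-12)
})

test_that("log likelihood: zero-count limit and relabeling invariance", {
  ctrl <- test_ctrl()
  cache <- tiny_cache(ctrl)
  pr <- prior_config()
  data <- tiny_data()
  data[, c("Ks", "Os", "Hs", "Kr", "Or", "Hr")] <- 0L
  st <- tiny_state()
  st$loci$theta_s <- st$loci$theta_r <- 1e-9
  ll <- log_likelihood(st$global, st$loci, data, ctrl, cache)
  # with all counts zero and tiny thetas, ll ~ -sum(lambda) ~ 0 from above
  expect_lt(ll, 0)
  expect_gt(ll, -1e-6)
  # relabeling loci together with their data leaves the likelihood unchanged
  data2 <- tiny_data()
  st2 <- tiny_state()
  st2$loci$gamma_i <- c(-2, 1)
  perm <- c(2, 1)
  ll1 <- log_likelihood(st2$global, st2$loci, data2, ctrl, cache)
  ll2 <- log_likelihood(st2$global, st2$loci[perm, ], data2[perm, ], ctrl, cache)
  expect_equal(ll1, ll2)
})

test_that("log posterior: empty data, vanishing theta_r, transcription oracle", {
  ctrl <- test_ctrl()
  cache <- tiny_cache(ctrl)
  pr <- prior_config()
  st <- tiny_state()
  empty <- tiny_data()[0, ]
  expect_equal(log_posterior(st$global, st$loci, empty, pr, ctrl, cache),
               log_prior(st$global, st$loci, pr))
  # theta_r -> 0 with Kr > 0 observed decreases the posterior
  data <- tiny_data()
  lo <- st$loci; lo$theta_r <- 1e-3
  lo2 <- st$loci; lo2$theta_r <- 1e-6
  expect_gt(log_posterior(st$global, lo, data, pr, ctrl, cache),
            log_posterior(st$global, lo2, data, pr, ctrl, cache))

  # double-implementation oracle: direct transcription of the joint density
  set.seed(11)
  for (r in 1:3) {
    g <- list(mu_gamma = rnorm(1), sigma_b = runif(1, 0.5, 3),
              sigma_w = runif(1, 0.2, 3), t_div = runif(1, 0.5, 5))
    lo <- data.frame(theta_s = runif(2, 0.5, 3), theta_r = runif(2, 0.5, 3),
                     gamma_i = rnorm(2, 0, 3))
    ref <- dgamma(1 / g$sigma_b^2, pr$alpha_0, rate = pr$beta_0, log = TRUE) -
      2 * log(g$sigma_b^2) + log(2 * g$sigma_b) +
      dnorm(g$mu_gamma, pr$mu_0, g$sigma_b / sqrt(pr$n_0), log = TRUE) -
      log(pr$t_max) - log(pr$sigma_max)
    for (i in 1:2) {
      e <- expected_table(lo$theta_s[i], lo$theta_r[i], lo$gamma_i[i],
                          g$sigma_w, g$t_div, data$m[i], data$n[i], ctrl, cache)
      cts <- c(data$Kr[i], data$Or[i], data$Hr[i],
               data$Ks[i], data$Os[i], data$Hs[i])
      lam <- pmax(e, ctrl$clip)
      ref <- ref + sum(cts * log(lam) - lam - lgamma(cts + 1)) +
        dnorm(lo$gamma_i[i], g$mu_gamma, g$sigma_b, log = TRUE) +
        dgamma(lo$theta_s[i], pr$alpha_s, rate = pr$beta_s, log = TRUE) +
        dgamma(lo$theta_r[i], pr$alpha_r, rate = pr$beta_r, log = TRUE)
    }
    expect_equal(log_posterior(g, lo, data, pr, ctrl, cache), ref,
                 tolerance = 1e-8)
  }
})

test_that("theta_s full conditional from the posterior is the stated gamma", {
  # grid-normalized conditional of theta_s (all else fixed) vs
  # Gamma(alpha_s + Ks + Os + Hs, beta_s + sum_j Lambda_j(0)/s(1))
  ctrl <- test_ctrl()
  cache <- tiny_cache(ctrl)
  pr <- prior_config()
  data <- tiny_data()
  st <- tiny_state()
  i <- 1L
  nu0 <- as.numeric(nu_eval(cache, 0, st$global$t_div,
                            cache_pair_index(cache, data$m[i], data$n[i])))
  shape <- pr$alpha_s + data$Ks[i] + data$Os[i] + data$Hs[i]
  rate <- pr$beta_s + sum(nu0)
  grid <- seq(0.05, 12, length.out = 200)
  lp <- vapply(grid, function(th) {
    lo <- st$loci; lo$theta_s[i] <- th
    log_posterior(st$global, lo, data, pr, ctrl, cache)
  }, 0)
  cond <- exp(lp - max(lp))
  cond <- cond / sum(cond)
  ref <- dgamma(grid, shape, rate = rate)
  ref <- ref / sum(ref)
  expect_lt(max(abs(cumsum(cond) - cumsum(ref))), 0.002)
})

test_that("likelihood orders divergence time correctly on simulated data", {
  ctrl <- test_ctrl()
  set.seed(4)
  des <- sim_design(L = 6, global_truth = c(mu_gamma = -2, sigma_b = 1,
                                            sigma_w = 0.5, t_div = 2.5),
                    seed = 4)
  sim <- generate_dataset(des, ctrl)
  cache <- lambda_cache(cbind(sim$data$m, sim$data$n), t_max = 20, ctrl = ctrl)
  st <- list(global = list(mu_gamma = -2, sigma_b = 1, sigma_w = 0.5,
                           t_div = 2.5),
             loci = data.frame(theta_s = sim$truth$loci$theta_s,
                               theta_r = sim$truth$loci$theta_r,
                               gamma_i = sim$truth$loci$gamma_m))
  ll_true <- log_likelihood(st$global, st$loci, sim$data, ctrl, cache)
  for (t_wrong in c(1, 5)) {
    g <- st$global; g$t_div <- t_wrong
    expect_gt(ll_true, log_likelihood(g, st$loci, sim$data, ctrl, cache))
  }
})
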