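make_state <- function(L = 3, seed = 1) {
  set.seed(seed)
  model_state(t = 1.2, mu_gamma = 0.8, sigma2 = 2.5,
              gamma = rnorm(L), theta_s = rgamma(L, 4, 1),
              theta_r = rgamma(L, 2, 1))
}

test_that("log prior matches an independently coded product of densities", {
  hy <- hyper_parameters(mu0 = 0.5, kappa0 = 2, a0 = 3, b0 = 4,
                         theta_s_shape = 2, theta_s_rate = 0.5,
                         theta_r_shape = 1.5, theta_r_rate = 0.7, t_max = 10)
  st <- make_state(4)
  # second implementation, written directly from the density formulas
  invgamma_ld <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  direct <- invgamma_ld(st$sigma2, hy$a0, hy$b0) +
    dnorm(st$mu_gamma, hy$mu0, sqrt(st$sigma2 / hy$kappa0), log = TRUE) +
    sum(dnorm(st$gamma, st$mu_gamma, sqrt(st$sigma2), log = TRUE)) +
    sum(dgamma(st$theta_s, 2, rate = 0.5, log = TRUE)) +
    sum(dgamma(st$theta_r, 1.5, rate = 0.7, log = TRUE)) +
    dunif(st$t, 0, 10, log = TRUE)
  expect_equal(log_prior(st, hy), direct, tolerance = 1e-10)
})

test_that("log prior returns -Inf outside the support", {
  hy <- hyper_parameters(t_max = 5)
  st <- make_state()
  st_bad <- st; st_bad$t <- 7
  expect_identical(log_prior(st_bad, hy), -Inf)
  st_bad <- st; st_bad$sigma2 <- -1
  expect_identical(log_prior(st_bad, hy), -Inf)
  st_bad <- st; st_bad$theta_s[2] <- 0
  expect_identical(log_prior(st_bad, hy), -Inf)
})

test_that("log likelihood equals the direct Poisson computation and is additive", {
  ctx <- quick_ctx()
  ds <- toy_dohrs(2)
  st <- make_state(2)
  ll <- log_likelihood(st, ds, ctx)
  direct <- 0
  for (i in 1:2) {
    lam <- expected_counts(
      locus_parameters(st$theta_s[i], st$theta_r[i], st$gamma[i],
                       ds$m[i], ds$n[i]), st$t, ctx)
    k <- as.numeric(ds[i, c("fixed_s", "poly_one_s", "poly_both_s",
                            "fixed_r", "poly_one_r", "poly_both_r")])
    direct <- direct + sum(dpois(k, unclass(lam), log = TRUE))
  }
  expect_equal(ll, direct, tolerance = 1e-10)
  # additivity across loci
  st1 <- model_state(st$t, st$mu_gamma, st$sigma2, st$gamma[1],
                     st$theta_s[1], st$theta_r[1])
  st2 <- model_state(st$t, st$mu_gamma, st$sigma2, st$gamma[2],
                     st$theta_s[2], st$theta_r[2])
  ll1 <- log_likelihood(st1, dohrs_dataset(as.data.frame(ds)[1, ]), ctx)
  ll2 <- log_likelihood(st2, dohrs_dataset(as.data.frame(ds)[2, ]), ctx)
  expect_equal(ll, ll1 + ll2, tolerance = 1e-10)
})

test_that("an all-zero table gives log likelihood minus the sum of means", {
  ctx <- quick_ctx()
  df <- as.data.frame(toy_dohrs(1))
  df[, 4:9] <- 0L
  ds <- dohrs_dataset(df)
  st <- make_state(1)
  lam <- expected_counts(
    locus_parameters(st$theta_s, st$theta_r, st$gamma, ds$m, ds$n), st$t, ctx)
  expect_equal(log_likelihood(st, ds, ctx), -sum(lam), tolerance = 1e-10)
})

test_that("the conjugate Gibbs block concentrates on degenerate input", {
  hy <- hyper_parameters()
  set.seed(4)
  draws <- replicate(100, unlist(gibbs_update_mean_variance(rep(3, 10000), hy)))
  expect_lt(abs(mean(draws["mu_gamma", ]) - 3), 0.05)
  expect_lt(median(draws["sigma2", ]), 0.01)
})

test_that("the conjugate Gibbs block matches closed-form posterior moments", {
  hy <- hyper_parameters(mu0 = 1, kappa0 = 2, a0 = 4, b0 = 6)
  set.seed(11)
  g <- rnorm(25, 2, 1.5)
  L <- length(g); gbar <- mean(g)
  kL <- hy$kappa0 + L
  muL <- (hy$kappa0 * hy$mu0 + L * gbar) / kL
  aL <- hy$a0 + L / 2
  bL <- hy$b0 + 0.5 * sum((g - gbar)^2) + hy$kappa0 * L * (gbar - hy$mu0)^2 / (2 * kL)
  n_draw <- 50000
  draws <- replicate(n_draw, unlist(gibbs_update_mean_variance(g, hy)))
  s2 <- draws["sigma2", ]; mu <- draws["mu_gamma", ]
  # closed-form: sigma2 ~ InvGamma(aL, bL); mu | sigma2 ~ N(muL, sigma2/kL)
  Es2 <- bL / (aL - 1)
  Vs2 <- bL^2 / ((aL - 1)^2 * (aL - 2))
  Vmu <- bL / (kL * (aL - 1))   # marginal t variance
  expect_lt(abs(mean(s2) - Es2), 3 * sqrt(Vs2 / n_draw) * 1.5)
  expect_lt(abs(mean(mu) - muL), 3 * sqrt(Vmu / n_draw))
  expect_lt(abs(var(mu) / Vmu - 1), 0.05)
  # permutation invariance: sufficient statistics fix the draw
  perm <- sample(seq_along(g))
  set.seed(99); d1 <- gibbs_update_mean_variance(g, hy)
  set.seed(99); d2 <- gibbs_update_mean_variance(g[perm], hy)
  expect_equal(d1, d2)
})

test_that("metropolis steps degenerate correctly and reject losslessly", {
  ctx <- quick_ctx()
  ds <- toy_dohrs(2)
  hy <- hyper_parameters(t_max = 5)
  st <- make_state(2)
  # near-zero proposal scale: always accepted, state essentially unchanged
  set.seed(8)
  n_acc <- 0
  for (r in 1:20) {
    out <- metropolis_step("gamma", st, ds, hy, scale = 1e-10, ctx = ctx,
                           locus = 1, likelihood = "constant")
    n_acc <- n_acc + out$accepted
    expect_lt(abs(out$state$gamma[1] - st$gamma[1]), 1e-8)
  }
  expect_equal(n_acc, 20)
  # rejected proposals leave the state bit-identical
  set.seed(12)
  saw_reject <- FALSE
  for (r in 1:50) {
    out <- metropolis_step("theta_s", st, ds, hy, scale = 6, ctx = ctx,
                           locus = 2, likelihood = "full")
    if (!out$accepted) {
      saw_reject <- TRUE
      expect_identical(out$state, st)
    }
  }
  expect_true(saw_reject)
  # t stays inside its prior support under reflection
  for (r in 1:30) {
    out <- metropolis_step("t", st, ds, hy, scale = 4, ctx = ctx,
                           likelihood = "constant")
    expect_gt(out$state$t, 0)
    expect_lt(out$state$t, 5)
    st <- out$state
  }
})

test_that("with constant likelihood the sampler recovers its priors", {
  # moderate hyperparameters so every marginal has testable moments
  hy <- hyper_parameters(mu0 = 0.5, kappa0 = 1, a0 = 3, b0 = 4,
                         theta_s_shape = 3, theta_s_rate = 1,
                         theta_r_shape = 2, theta_r_rate = 2, t_max = 4)
  ds <- toy_dohrs(3)
  set <- chain_settings(n_chains = 2, burn_in = 500, thin = 1,
                        n_retained = 4000, seed = 31)
  fit <- run_mcmc(ds, hy, set, ctx = quick_ctx(), likelihood = "constant")
  pooled <- do.call(rbind, fit$chains)
  # theta draws are exact conjugate Gibbs draws from the prior: compare the
  # full distribution to the gamma prior
  ks <- suppressWarnings(ks.test(pooled[, "theta_s_1"], pgamma, 3, 1))
  expect_gt(ks$p.value, 1e-3)
  ks2 <- suppressWarnings(ks.test(pooled[, "theta_r_2"], pgamma, 2, 2))
  expect_gt(ks2$p.value, 1e-3)
  # t is uniform on (0, 4): compare mean and spread at random-walk precision
  expect_lt(abs(mean(pooled[, "t"]) - 2), 0.4)
  expect_lt(abs(sd(pooled[, "t"]) - 4 / sqrt(12)), 0.3)
  qs <- quantile(pooled[, "t"], c(0.1, 0.5, 0.9))
  expect_equal(unname(qs), c(0.4, 2, 3.6), tolerance = 0.2)
  # gamma_1 marginal: mean should match mu0 within Monte-Carlo error
  expect_lt(abs(mean(pooled[, "gamma_1"]) - 0.5), 0.5)
})

test_that("gelman_rubin follows its closed form and flags disagreement", {
  x <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  # B = 0, so rhat = sqrt((n-1)/n) < 1
  expect_equal(gelman_rubin(x), sqrt(3 / 4), tolerance = 1e-12)
  set.seed(5)
  y <- list(rnorm(10000), rnorm(10000))
  expect_lt(gelman_rubin(y), 1.05)
  z <- list(rep(0, 100), rep(10, 100))
  expect_gt(gelman_rubin(z), 10)
  expect_error(gelman_rubin(list(1:10)), "at least 2 chains")
  expect_error(gelman_rubin(list(1:10, 1:5)), "equal lengths")
})

test_that("posterior summaries use pooled medians and central 95% intervals", {
  fit <- structure(list(chains = list(
    cbind(t = rep(2, 50)), cbind(t = rep(2, 50))
  )), class = "tdprf_fit")
  sm <- summarize_fit(fit)
  expect_equal(sm$median, 2)
  expect_equal(sm$q2.5, 2)
  expect_equal(sm$q97.5, 2)
  fit2 <- structure(list(chains = list(cbind(p = 1:50), cbind(p = 51:100))),
                    class = "tdprf_fit")
  sm2 <- summarize_fit(fit2)
  expect_equal(sm2$median, 50.5)
  expect_equal(sm2$q2.5, unname(quantile(1:100, 0.025)))
  expect_equal(sm2$q97.5, unname(quantile(1:100, 0.975)))
  expect_true(all(sm2$q2.5 <= sm2$median & sm2$median <= sm2$q97.5))
})

test_that("chain settings validate and the sampler is seed-deterministic", {
  expect_error(chain_settings(n_retained = 0), ">= 1")
  expect_error(chain_settings(thin = 0), ">= 1")
  ctx <- quick_ctx()
  ds <- toy_dohrs(2)
  set <- chain_settings(n_chains = 2, burn_in = 20, thin = 1, n_retained = 15,
                        seed = 77)
  f1 <- run_mcmc(ds, hyper_parameters(t_max = 4), set, ctx)
  f2 <- run_mcmc(ds, hyper_parameters(t_max = 4), set, ctx)
  expect_identical(f1$chains, f2$chains)
})
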