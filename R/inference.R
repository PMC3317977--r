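#' Hyperparameters of the hierarchical model
#'
#' The joint prior is the conjugate normal-inverse-gamma on
#' \eqn{(\mu_\gamma, \sigma^2)} -- \eqn{\sigma^2 \sim
#' \mathrm{InvGamma}(a_0, b_0)}, \eqn{\mu_\gamma \mid \sigma^2 \sim
#' N(\mu_0, \sigma^2/\kappa_0)} -- gamma priors on each scaled mutation
#' rate, and a uniform prior on the divergence time over \eqn{(0,
#' t_{\max})}.  The shape/rate/precision defaults are deliberately small
#' ("uninformative"); `t_max` is a fixed large bound.  For \eqn{\sigma^2}
#' the default is \eqn{a_0 = b_0 = 0.5} (a unit scaled-inverse-chi-squared
#' with one prior degree of freedom) rather than the
#' \eqn{\mathrm{InvGamma}(\epsilon, \epsilon)} limit, whose prior mass
#' concentrates near \eqn{\sigma^2 \approx \epsilon} and quietly favours
#' collapse of the selection hierarchy.
#'
#' @param mu0 Prior location of \eqn{\mu_\gamma}.
#' @param kappa0 Prior precision scaling of \eqn{\mu_\gamma} (> 0).
#' @param a0,b0 Inverse-gamma shape and scale for \eqn{\sigma^2} (> 0).
#' @param theta_s_shape,theta_s_rate Gamma prior for silent rates (> 0).
#' @param theta_r_shape,theta_r_rate Gamma prior for replacement rates (> 0).
#' @param t_max Upper bound of the uniform prior on divergence time (> 0).
#' @return An object of class `"hyper_parameters"`.
#' @export
hyper_parameters <- function(mu0 = 0, kappa0 = 0.01, a0 = 0.5, b0 = 0.5,
                             theta_s_shape = 0.01, theta_s_rate = 0.01,
                             theta_r_shape = 0.01, theta_r_rate = 0.01,
                             t_max = 20) {
  vals <- c(kappa0 = kappa0, a0 = a0, b0 = b0,
            theta_s_shape = theta_s_shape, theta_s_rate = theta_s_rate,
            theta_r_shape = theta_r_shape, theta_r_rate = theta_r_rate,
            t_max = t_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all hyperparameters (except mu0) must be strictly positive",
         call. = FALSE)
  }
  structure(as.list(c(mu0 = mu0, vals)), class = "hyper_parameters")
}

#' Model state of the hierarchical sampler
#'
#' @param t Divergence time in \eqn{(0, t_{\max})}.
#' @param mu_gamma,sigma2 Across-locus selection mean and variance.
#' @param gamma,theta_s,theta_r Per-locus parameter vectors (equal length).
#' @return An object of class `"model_state"`.
#' @export
model_state <- function(t, mu_gamma, sigma2, gamma, theta_s, theta_r) {
  L <- length(gamma)
  if (length(theta_s) != L || length(theta_r) != L) {
    stop("per-locus vectors must have equal length", call. = FALSE)
  }
  structure(list(t = t, mu_gamma = mu_gamma, sigma2 = sigma2,
                 gamma = gamma, theta_s = theta_s, theta_r = theta_r),
            class = "model_state")
}

#' Log prior density of a model state
#'
#' Sum of the log densities of the normal-inverse-gamma prior on
#' \eqn{(\mu_\gamma, \sigma^2)}, the normal population distribution of each
#' \eqn{\gamma_i}, the gamma priors on each \eqn{\theta}, and the uniform
#' prior on \eqn{t}.  States outside the support return `-Inf` (never an
#' error).
#'
#' @param state A [model_state()].
#' @param hyper A [hyper_parameters()].
#' @return Scalar log density.
#' @export
log_prior <- function(state, hyper) {
  s2 <- state$sigma2
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  if (!is.finite(state$t) || state$t <= 0 || state$t >= hyper$t_max) return(-Inf)
  if (any(state$theta_s <= 0) || any(state$theta_r <= 0)) return(-Inf)
  lp <- hyper$a0 * log(hyper$b0) - lgamma(hyper$a0) -
    (hyper$a0 + 1) * log(s2) - hyper$b0 / s2
  lp <- lp + stats::dnorm(state$mu_gamma, hyper$mu0, sqrt(s2 / hyper$kappa0),
                          log = TRUE)
  lp <- lp + sum(stats::dnorm(state$gamma, state$mu_gamma, sqrt(s2), log = TRUE))
  lp <- lp + sum(stats::dgamma(state$theta_s, hyper$theta_s_shape,
                               rate = hyper$theta_s_rate, log = TRUE))
  lp <- lp + sum(stats::dgamma(state$theta_r, hyper$theta_r_shape,
                               rate = hyper$theta_r_rate, log = TRUE))
  lp - log(hyper$t_max)
}

obs_matrices <- function(dataset) {
  list(s = as.matrix(dataset[, c("fixed_s", "poly_one_s", "poly_both_s")]),
       r = as.matrix(dataset[, c("fixed_r", "poly_one_r", "poly_both_r")]),
       m = dataset$m, n = dataset$n)
}

pois_ll <- function(counts, means) sum(counts * log(means) - means - lgamma(counts + 1))

#' Log likelihood of a DOHRS dataset
#'
#' Sum over loci and over the six table entries of the Poisson log
#' probability of the observed count at the mean given by
#' [expected_counts()] under the current state.
#'
#' @param state A [model_state()] with per-locus vectors matching the
#'   dataset.
#' @param dataset A [dohrs_dataset()].
#' @param ctx A [prf_context()] (defaults when `NULL`).
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(state, dataset, ctx = NULL) {
  if (is.null(ctx)) ctx <- prf_context()
  obs <- obs_matrices(dataset)
  L <- nrow(dataset)
  if (length(state$gamma) != L) {
    stop("state has per-locus vectors of length ", length(state$gamma),
         " but the dataset has ", L, " loci", call. = FALSE)
  }
  ll <- 0
  for (i in seq_len(L)) {
    fs <- unit_functionals(ctx, 0, state$t, obs$m[i], obs$n[i])
    fr <- unit_functionals(ctx, state$gamma[i], state$t, obs$m[i], obs$n[i])
    mu_s <- pmax(state$theta_s[i] * fs, 1e-12)
    mu_r <- pmax(state$theta_r[i] * fr, 1e-12)
    ll <- ll + pois_ll(obs$s[i, ], mu_s) + pois_ll(obs$r[i, ], mu_r)
  }
  ll
}

#' Exact Gibbs draw for the selection mean and variance
#'
#' Draws \eqn{(\mu_\gamma, \sigma^2)} from their normal-inverse-gamma full
#' conditional given the current per-locus selection coefficients: with
#' \eqn{L} loci and mean \eqn{\bar\gamma},
#' \eqn{\kappa_L = \kappa_0 + L}, \eqn{a_L = a_0 + L/2},
#' \eqn{b_L = b_0 + \frac12\sum(\gamma_i-\bar\gamma)^2 +
#' \frac{\kappa_0 L (\bar\gamma - \mu_0)^2}{2\kappa_L}}.
#'
#' @param gammas Numeric vector of current \eqn{\gamma_i} (length >= 1).
#' @param hyper A [hyper_parameters()].
#' @return List with `mu_gamma` and `sigma2`.
#' @export
gibbs_update_mean_variance <- function(gammas, hyper) {
  L <- length(gammas)
  if (L < 1) stop("need at least one selection coefficient", call. = FALSE)
  gbar <- mean(gammas)
  kL <- hyper$kappa0 + L
  muL <- (hyper$kappa0 * hyper$mu0 + L * gbar) / kL
  aL <- hyper$a0 + L / 2
  bL <- hyper$b0 + 0.5 * sum((gammas - gbar)^2) +
    hyper$kappa0 * L * (gbar - hyper$mu0)^2 / (2 * kL)
  sigma2 <- 1 / stats::rgamma(1, shape = aL, rate = bL)
  mu_gamma <- stats::rnorm(1, muL, sqrt(sigma2 / kL))
  list(mu_gamma = mu_gamma, sigma2 = sigma2)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' One Metropolis-Hastings update of a single block
#'
#' Updates one block of the state -- the divergence time `t` (Gaussian
#' random walk reflected into \eqn{(0, t_{\max})}), one `gamma_i` (Gaussian
#' random walk), or one `theta_s_i` / `theta_r_i` (log-scale Gaussian
#' random walk with Jacobian) -- targeting `log_prior + log_likelihood`.
#' With `likelihood = "constant"` the data term is dropped, so the chain
#' targets the prior (used for sampler-correctness checks).
#'
#' @param block One of `"t"`, `"gamma"`, `"theta_s"`, `"theta_r"`.
#' @param state A [model_state()].
#' @param dataset A [dohrs_dataset()].
#' @param hyper A [hyper_parameters()].
#' @param scale Proposal scale (> 0 on the block's proposal space).
#' @param ctx A [prf_context()].
#' @param locus Locus index for the per-locus blocks.
#' @param likelihood `"full"` or `"constant"`.
#' @return List with the (possibly updated) `state` and logical `accepted`.
#' @export
metropolis_step <- function(block = c("t", "gamma", "theta_s", "theta_r"),
                            state, dataset, hyper, scale, ctx = NULL,
                            locus = 1L, likelihood = c("full", "constant")) {
  block <- match.arg(block)
  likelihood <- match.arg(likelihood)
  if (is.null(ctx)) ctx <- prf_context()
  const_lik <- identical(likelihood, "constant")
  loglik <- function(s) if (const_lik) 0 else log_likelihood(s, dataset, ctx)
  prop <- state
  log_jac <- 0
  if (block == "t") {
    prop$t <- reflect_into(state$t + stats::rnorm(1, 0, scale), 0, hyper$t_max)
  } else if (block == "gamma") {
    prop$gamma[locus] <- state$gamma[locus] + stats::rnorm(1, 0, scale)
  } else {
    slot <- block
    new <- state[[slot]][locus] * exp(stats::rnorm(1, 0, scale))
    prop[[slot]][locus] <- new
    log_jac <- log(new) - log(state[[slot]][locus])
  }
  la <- (log_prior(prop, hyper) + loglik(prop)) -
    (log_prior(state, hyper) + loglik(state)) + log_jac
  if (is.finite(la) && log(stats::runif(1)) < la) {
    list(state = prop, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

#' MCMC chain settings
#'
#' Defaults follow the reference analysis: 20,000 burn-in iterations, then
#' 10,000 retained samples taken every 10 iterations, in 4 chains started
#' from overdispersed draws.
#'
#' @param n_chains Number of chains (>= 1; >= 2 for Gelman-Rubin).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param n_retained Retained samples per chain.
#' @param seed Master seed; chain seeds derive from it.
#' @param t_scale,gamma_scale Initial random-walk proposal scales.
#' @param adapt Tune proposal scales during burn-in (frozen afterwards).
#' @return An object of class `"chain_settings"`.
#' @export
chain_settings <- function(n_chains = 4, burn_in = 20000, thin = 10,
                           n_retained = 10000, seed = 1,
                           t_scale = 0.2, gamma_scale = 1, adapt = TRUE) {
  if (n_retained < 1) stop("`n_retained` must be >= 1", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  if (burn_in < 0) stop("`burn_in` must be >= 0", call. = FALSE)
  if (n_chains < 1) stop("`n_chains` must be >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_retained = as.integer(n_retained),
                 seed = as.integer(seed), t_scale = t_scale,
                 gamma_scale = gamma_scale, adapt = isTRUE(adapt)),
            class = "chain_settings")
}

# overdispersed but numerically bounded starting values
draw_init <- function(L, hyper) {
  s2 <- min(max(1 / stats::rgamma(1, hyper$a0, rate = hyper$b0), 0.25), 25)
  mu <- stats::rnorm(1, hyper$mu0, 3)
  model_state(
    t = stats::runif(1, 0.02 * hyper$t_max, 0.15 * hyper$t_max),
    mu_gamma = mu, sigma2 = s2,
    gamma = pmin(pmax(stats::rnorm(L, mu, sqrt(s2)), -12), 12),
    theta_s = pmin(pmax(stats::rgamma(L, hyper$theta_s_shape,
                                      rate = hyper$theta_s_rate), 0.05), 50),
    theta_r = pmin(pmax(stats::rgamma(L, hyper$theta_r_shape,
                                      rate = hyper$theta_r_rate), 0.05), 50)
  )
}

# Poisson log-likelihood of one locus class given unit functionals
class_ll <- function(counts, theta, f) {
  mu <- pmax(theta * f, 1e-12)
  sum(counts * log(mu) - mu)
}

run_one_chain <- function(obs, hyper, settings, ctx, const_lik, init, verbose) {
  L <- length(obs$m)
  state <- init
  n_iter <- settings$burn_in + settings$thin * settings$n_retained
  scale_g <- rep(settings$gamma_scale, L)
  scale_t <- settings$t_scale
  scale_c <- 0.4   # log-scale width of the group scale move
  scale_d <- 0.5   # width of the group translation move
  acc <- c(gamma = 0, t = 0, scale = 0, shift = 0)
  prop_cnt <- c(gamma = 0, t = 0, scale = 0, shift = 0)
  win_acc <- acc
  win_cnt <- acc

  # log density of the normal-inverse-gamma block (mu_gamma, sigma2, gammas)
  nig_logpdf <- function(mu, s2, gam) {
    -(hyper$a0 + 1) * log(s2) - hyper$b0 / s2 +
      stats::dnorm(mu, hyper$mu0, sqrt(s2 / hyper$kappa0), log = TRUE) +
      sum(stats::dnorm(gam, mu, sqrt(s2), log = TRUE))
  }

  Fs <- matrix(0, L, 3)
  Fr <- matrix(0, L, 3)
  refresh <- function(t) {
    for (i in seq_len(L)) {
      Fs[i, ] <<- unit_functionals(ctx, 0, t, obs$m[i], obs$n[i])
      Fr[i, ] <<- unit_functionals(ctx, state$gamma[i], t, obs$m[i], obs$n[i])
    }
  }
  if (!const_lik) refresh(state$t)

  keep <- matrix(NA_real_, settings$n_retained, 3 + 3 * L)
  colnames(keep) <- c("t", "mu_gamma", "sigma2",
                      paste0("gamma_", seq_len(L)),
                      paste0("theta_s_", seq_len(L)),
                      paste0("theta_r_", seq_len(L)))
  kept <- 0L

  # during the first third of burn-in the selection variance is floored at 1,
  # so the per-locus gammas first migrate to their likelihood positions
  # before the hierarchy is allowed to shrink them (the centred
  # normal-inverse-gamma funnel otherwise deadlocks at sigma2 near 0);
  # discarded with the rest of burn-in, the post-burn-in kernel is exact
  warm <- settings$burn_in %/% 3

  for (it in seq_len(n_iter)) {
    # 1. conjugate Gibbs for the selection hyper-block
    gd <- gibbs_update_mean_variance(state$gamma, hyper)
    state$mu_gamma <- gd$mu_gamma
    state$sigma2 <- if (it <= warm) max(gd$sigma2, 1) else gd$sigma2
    sd_g <- sqrt(state$sigma2)

    # 2. random-walk Metropolis on each gamma_i
    for (i in seq_len(L)) {
      g_new <- state$gamma[i] + stats::rnorm(1, 0, scale_g[i])
      la <- stats::dnorm(g_new, state$mu_gamma, sd_g, log = TRUE) -
        stats::dnorm(state$gamma[i], state$mu_gamma, sd_g, log = TRUE)
      fr_new <- NULL
      if (!const_lik) {
        fr_new <- unit_functionals(ctx, g_new, state$t, obs$m[i], obs$n[i])
        la <- la + class_ll(obs$r[i, ], state$theta_r[i], fr_new) -
          class_ll(obs$r[i, ], state$theta_r[i], Fr[i, ])
      }
      prop_cnt["gamma"] <- prop_cnt["gamma"] + 1
      win_cnt["gamma"] <- win_cnt["gamma"] + 1
      if (is.finite(la) && log(stats::runif(1)) < la) {
        state$gamma[i] <- g_new
        if (!const_lik) Fr[i, ] <- fr_new
        acc["gamma"] <- acc["gamma"] + 1
        win_acc["gamma"] <- win_acc["gamma"] + 1
      }
    }

    # 2b. group moves through the (mu, sigma2, gamma) funnel.  Single-site
    # updates deadlock once sigma2 collapses (every gamma move then pays a
    # huge prior penalty), so propose deterministic rescalings/translations
    # of the whole selection block with the matching Jacobian.  They cost a
    # full sweep of PDE solves, so they run every other iteration.
    if (it %% 2 == 0) {
    # (i) scale move: gamma' = mu + c(gamma - mu), sigma2' = c^2 sigma2
    dlt <- stats::rnorm(1, 0, scale_c)
    cc <- exp(dlt)
    g_new <- state$mu_gamma + cc * (state$gamma - state$mu_gamma)
    s2_new <- cc^2 * state$sigma2
    la <- nig_logpdf(state$mu_gamma, s2_new, g_new) -
      nig_logpdf(state$mu_gamma, state$sigma2, state$gamma) + (L + 2) * dlt
    Fr_new <- NULL
    if (!const_lik && is.finite(la)) {
      Fr_new <- matrix(0, L, 3)
      for (i in seq_len(L)) {
        Fr_new[i, ] <- unit_functionals(ctx, g_new[i], state$t,
                                        obs$m[i], obs$n[i])
        la <- la + class_ll(obs$r[i, ], state$theta_r[i], Fr_new[i, ]) -
          class_ll(obs$r[i, ], state$theta_r[i], Fr[i, ])
      }
    }
    prop_cnt["scale"] <- prop_cnt["scale"] + 1
    win_cnt["scale"] <- win_cnt["scale"] + 1
    if (is.finite(la) && log(stats::runif(1)) < la) {
      state$gamma <- g_new
      state$sigma2 <- s2_new
      if (!const_lik) Fr <- Fr_new
      acc["scale"] <- acc["scale"] + 1
      win_acc["scale"] <- win_acc["scale"] + 1
    }
    # (ii) translation move: mu' = mu + d, gamma' = gamma + d
    dd <- stats::rnorm(1, 0, scale_d)
    g_new <- state$gamma + dd
    mu_new <- state$mu_gamma + dd
    la <- stats::dnorm(mu_new, hyper$mu0,
                       sqrt(state$sigma2 / hyper$kappa0), log = TRUE) -
      stats::dnorm(state$mu_gamma, hyper$mu0,
                   sqrt(state$sigma2 / hyper$kappa0), log = TRUE)
    Fr_new <- NULL
    if (!const_lik && is.finite(la)) {
      Fr_new <- matrix(0, L, 3)
      for (i in seq_len(L)) {
        Fr_new[i, ] <- unit_functionals(ctx, g_new[i], state$t,
                                        obs$m[i], obs$n[i])
        la <- la + class_ll(obs$r[i, ], state$theta_r[i], Fr_new[i, ]) -
          class_ll(obs$r[i, ], state$theta_r[i], Fr[i, ])
      }
    }
    prop_cnt["shift"] <- prop_cnt["shift"] + 1
    win_cnt["shift"] <- win_cnt["shift"] + 1
    if (is.finite(la) && log(stats::runif(1)) < la) {
      state$gamma <- g_new
      state$mu_gamma <- mu_new
      if (!const_lik) Fr <- Fr_new
      acc["shift"] <- acc["shift"] + 1
      win_acc["shift"] <- win_acc["shift"] + 1
    }
    }

    # 3. conjugate Gibbs for each theta (means are linear in theta)
    if (const_lik) {
      state$theta_s <- stats::rgamma(L, hyper$theta_s_shape,
                                     rate = hyper$theta_s_rate)
      state$theta_r <- stats::rgamma(L, hyper$theta_r_shape,
                                     rate = hyper$theta_r_rate)
    } else {
      state$theta_s <- stats::rgamma(L, hyper$theta_s_shape + rowSums(obs$s),
                                     rate = hyper$theta_s_rate + rowSums(Fs))
      state$theta_r <- stats::rgamma(L, hyper$theta_r_shape + rowSums(obs$r),
                                     rate = hyper$theta_r_rate + rowSums(Fr))
    }

    # 4. random-walk Metropolis on t, reflected into (0, t_max)
    t_new <- reflect_into(state$t + stats::rnorm(1, 0, scale_t), 0, hyper$t_max)
    prop_cnt["t"] <- prop_cnt["t"] + 1
    win_cnt["t"] <- win_cnt["t"] + 1
    if (const_lik) {
      state$t <- t_new
      acc["t"] <- acc["t"] + 1
      win_acc["t"] <- win_acc["t"] + 1
    } else {
      Fs_new <- matrix(0, L, 3)
      Fr_new <- matrix(0, L, 3)
      la <- 0
      for (i in seq_len(L)) {
        Fs_new[i, ] <- unit_functionals(ctx, 0, t_new, obs$m[i], obs$n[i])
        Fr_new[i, ] <- unit_functionals(ctx, state$gamma[i], t_new,
                                        obs$m[i], obs$n[i])
        la <- la + class_ll(obs$s[i, ], state$theta_s[i], Fs_new[i, ]) -
          class_ll(obs$s[i, ], state$theta_s[i], Fs[i, ]) +
          class_ll(obs$r[i, ], state$theta_r[i], Fr_new[i, ]) -
          class_ll(obs$r[i, ], state$theta_r[i], Fr[i, ])
      }
      if (is.finite(la) && log(stats::runif(1)) < la) {
        state$t <- t_new
        Fs <- Fs_new
        Fr <- Fr_new
        acc["t"] <- acc["t"] + 1
        win_acc["t"] <- win_acc["t"] + 1
      }
    }

    # adapt proposal scales during burn-in only
    if (settings$adapt && it <= settings$burn_in && it %% 50 == 0) {
      rg <- win_acc["gamma"] / max(win_cnt["gamma"], 1)
      rt <- win_acc["t"] / max(win_cnt["t"], 1)
      rc <- win_acc["scale"] / max(win_cnt["scale"], 1)
      rd <- win_acc["shift"] / max(win_cnt["shift"], 1)
      scale_g <- pmin(pmax(scale_g * exp(0.8 * (rg - 0.3)), 1e-3), 5)
      scale_t <- min(max(scale_t * exp(0.8 * (rt - 0.3)), 1e-4), 1)
      scale_c <- min(max(scale_c * exp(0.8 * (rc - 0.3)), 0.01), 2)
      scale_d <- min(max(scale_d * exp(0.8 * (rd - 0.3)), 0.01), 3)
      win_acc[] <- 0
      win_cnt[] <- 0
    }

    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0 &&
        kept < settings$n_retained) {
      kept <- kept + 1L
      keep[kept, ] <- c(state$t, state$mu_gamma, state$sigma2,
                        state$gamma, state$theta_s, state$theta_r)
    }
    if (verbose && it %% 500 == 0) {
      message(sprintf("iter %d/%d t=%.3f mu=%.2f s2=%.2f acc(g)=%.2f acc(t)=%.2f",
                      it, n_iter, state$t, state$mu_gamma, state$sigma2,
                      acc["gamma"] / max(prop_cnt["gamma"], 1),
                      acc["t"] / max(prop_cnt["t"], 1)))
    }
  }
  list(draws = keep[seq_len(kept), , drop = FALSE],
       acceptance = acc / pmax(prop_cnt, 1),
       scales = list(gamma = scale_g, t = scale_t))
}

#' Run the hierarchical MCMC sampler
#'
#' Metropolis-within-Gibbs sampler for the time-dependent Poisson random
#' field model: exact normal-inverse-gamma Gibbs updates for
#' \eqn{(\mu_\gamma, \sigma^2)}, random-walk Metropolis for each
#' \eqn{\gamma_i} and for \eqn{t} (reflected at the prior bounds), and
#' exact conjugate gamma Gibbs draws for every \eqn{\theta} (the Poisson
#' means are linear in \eqn{\theta}).  Chains start from overdispersed
#' draws and proposal scales are tuned only during burn-in.
#'
#' @param dataset A [dohrs_dataset()].
#' @param hyper A [hyper_parameters()].
#' @param settings A [chain_settings()].
#' @param ctx A [prf_context()] shared by all chains (created with defaults
#'   when `NULL`).
#' @param likelihood `"full"`, or `"constant"` to target the prior only
#'   (sampler validation).
#' @param init Optional [model_state()] used as the starting point of every
#'   chain (defaults to fresh overdispersed draws per chain).
#' @param verbose Print progress.
#' @return An object of class `"tdprf_fit"`: list with `chains` (one draw
#'   matrix per chain), `acceptance`, `settings`, `hyper`, `n_loci`,
#'   `locus_ids`.
#' @export
run_mcmc <- function(dataset, hyper = hyper_parameters(),
                     settings = chain_settings(), ctx = NULL,
                     likelihood = c("full", "constant"), init = NULL,
                     verbose = FALSE) {
  likelihood <- match.arg(likelihood)
  validate_dohrs(dataset)
  if (is.null(ctx)) ctx <- prf_context()
  obs <- obs_matrices(dataset)
  L <- length(obs$m)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max, settings$n_chains)
  chains <- vector("list", settings$n_chains)
  acc <- vector("list", settings$n_chains)
  for (c_idx in seq_len(settings$n_chains)) {
    set.seed(chain_seeds[c_idx])
    st0 <- if (is.null(init)) draw_init(L, hyper) else init
    res <- run_one_chain(obs, hyper, settings, ctx,
                         const_lik = identical(likelihood, "constant"),
                         init = st0, verbose = verbose)
    chains[[c_idx]] <- res$draws
    acc[[c_idx]] <- res$acceptance
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  structure(list(chains = chains, acceptance = acc, settings = settings,
                 hyper = hyper, n_loci = L, locus_ids = dataset$locus_id),
            class = "tdprf_fit")
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Classical \eqn{\hat R} from between- and within-chain variances:
#' \eqn{\hat R = \sqrt{\left(\frac{n-1}{n} W + \frac{B}{n}\right) / W}}.
#'
#' @param draws A list of numeric vectors (one per chain, equal lengths >=
#'   2, at least 2 chains) or a matrix with one column per chain.
#' @return The scalar statistic.
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- lapply(seq_len(ncol(draws)), function(j) draws[, j])
  M <- length(draws)
  if (M < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(draws))
  if (length(n) != 1 || n < 2) {
    stop("chains must have equal lengths >= 2", call. = FALSE)
  }
  means <- vapply(draws, mean, 0)
  vars <- vapply(draws, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary of an MCMC fit
#'
#' Pooled post-burn-in medians and central 95% credible intervals per
#' parameter, with the Gelman-Rubin statistic attached (NA for a single
#' chain).
#'
#' @param fit A `"tdprf_fit"` from [run_mcmc()].
#' @return A data frame with columns `parameter`, `median`, `q2.5`,
#'   `q97.5`, `rhat`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "tdprf_fit"))
  if (length(fit$chains) == 0 || nrow(fit$chains[[1]]) == 0) {
    stop("fit contains no draws", call. = FALSE)
  }
  pooled <- do.call(rbind, fit$chains)
  pars <- colnames(pooled)
  rhat <- if (length(fit$chains) >= 2 && nrow(fit$chains[[1]]) >= 2) {
    vapply(pars, function(p) {
      gelman_rubin(lapply(fit$chains, function(ch) ch[, p]))
    }, 0)
  } else {
    rep(NA_real_, length(pars))
  }
  data.frame(
    parameter = pars,
    median = apply(pooled, 2, stats::median),
    q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975, names = FALSE),
    rhat = rhat,
    row.names = NULL
  )
}

#' @export
print.tdprf_fit <- function(x, ...) {
  cat(sprintf("<tdprf_fit: %d chains x %d draws, %d loci>\n",
              length(x$chains), nrow(x$chains[[1]]), x$n_loci))
  invisible(x)
}
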