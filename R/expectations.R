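#' Solver context for DOHRS expectations
#'
#' Bundles the frequency grid, the quadrature rule and a cache of backward
#' solutions keyed by (selection coefficient, sample size).  Because every
#' DOHRS mean is linear in its mutation rate, the cache stores unit-rate
#' functionals; repeated likelihood evaluations during MCMC then reuse one
#' Crank-Nicolson solve per (\eqn{\gamma}, sample size) pair, and all
#' divergence times up to the solved horizon are served from the retained
#' intermediate time levels.
#'
#' @param n_grid Interior nodes of the frequency grid.
#' @param dt Crank-Nicolson time step.
#' @param quad_order Nodes per quadrature panel (see [freq_rule()]).
#' @param eps Truncation frequency of the singular-endpoint quadrature.
#' @param concentration Sinh grid-stretching parameter.
#' @param cache_max Maximum number of cached (\eqn{\gamma}, k) entries;
#'   least-recently-used entries are evicted beyond this.
#' @param gamma_quantum Selection coefficients are rounded to this lattice
#'   before solving, and solutions are cached per lattice point.  The
#'   default keeps \eqn{\gamma} effectively continuous; a coarser quantum
#'   (e.g. 0.01, far below any posterior spread of interest) lets MCMC
#'   proposals reuse cached solves.
#' @return An environment of class `"prf_context"`.
#' @export
prf_context <- function(n_grid = 400, dt = 1e-3, quad_order = 24,
                        eps = 1e-8, concentration = 6, cache_max = 200,
                        gamma_quantum = 1e-6) {
  ctx <- new.env(parent = emptyenv())
  ctx$gamma_quantum <- gamma_quantum
  ctx$grid <- frequency_grid(n_grid, dt, concentration)
  ctx$rule <- freq_rule(order = quad_order, eps = eps)
  st <- probe_stencil(ctx$grid, ctx$rule$nodes)
  # probes: all quadrature nodes, then the two interior nodes nearest 0
  # (exact grid nodes, used to extrapolate the slope of u at the origin)
  ctx$probe_left <- c(st$left, 1L, 2L)
  ctx$probe_w <- c(st$w, 0, 0)
  ctx$n_quad <- length(ctx$rule$nodes)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$stamps <- new.env(parent = emptyenv())
  ctx$cache_max <- cache_max
  ctx$n_entries <- 0
  ctx$tick <- 0
  ctx$solves <- 0
  class(ctx) <- "prf_context"
  ctx
}

#' @export
print.prf_context <- function(x, ...) {
  cat(sprintf("<prf_context: %d interior nodes, dt = %g, %d quadrature nodes, %d cached solves>\n",
              x$grid$n_interior, x$grid$dt, x$n_quad,
              length(ls(x$cache))))
  invisible(x)
}

entry_key <- function(gamma, k) {
  sprintf("g%+.6f|k%d", gamma, as.integer(k))
}

# slope at x = 0 of a function with u(0) = 0, from its values at the two
# grid nodes nearest the origin (quadratic extrapolation)
origin_slope <- function(u1, u2, x1, x2) {
  (x2^2 * u1 - x1^2 * u2) / (x1 * x2 * (x2 - x1))
}

cum_trap <- function(v, dt) c(0, cumsum((v[-length(v)] + v[-1]) / 2 * dt))

# assemble a cache entry from the probe blocks of its two payoff systems
# (A: x^k with boundary values (0,1); B: (1-x)^k with boundary values (1,0))
build_entry <- function(ctx, gamma, k, probesA, probesB, finalA, finalB,
                        n_steps) {
  P <- ctx$n_quad
  x1 <- ctx$grid$x[1]; x2 <- ctx$grid$x[2]
  dt <- ctx$grid$dt
  # slope of u at the origin for the payoffs vanishing there: x^k and the
  # polymorphism payoff 1 - x^k - (1-x)^k (both have u(t, 0) = 0)
  vA <- origin_slope(probesA[, P + 1L], probesA[, P + 2L], x1, x2)
  vP <- origin_slope(1 - probesA[, P + 1L] - probesB[, P + 1L],
                     1 - probesA[, P + 2L] - probesB[, P + 2L], x1, x2)
  list(gamma = gamma, k = as.integer(k), n_steps = n_steps,
       probesA = probesA, probesB = probesB,
       finalA = finalA, finalB = finalB,
       vA = vA, vP = vP, IA = cum_trap(vA, dt), IP = cum_trap(vP, dt),
       gq = spectrum_shape(ctx$rule$nodes, gamma))
}

# fetch (creating or extending as needed) the cache entries for
# (gamma, k in ks), solved horizon >= t; all payoff systems needing work are
# evolved in one batched Crank-Nicolson call
ensure_entries <- function(ctx, gamma, ks, t) {
  gamma <- round(gamma / ctx$gamma_quantum) * ctx$gamma_quantum
  dt <- ctx$grid$dt
  need <- max(1L, as.integer(ceiling(t / dt - 1e-9)))
  nk <- length(ks)
  keys <- character(nk)
  entries <- vector("list", nk)
  horizons <- integer(nk)
  for (j in seq_len(nk)) {
    keys[j] <- entry_key(gamma, ks[j])
    e <- get0(keys[j], envir = ctx$cache, inherits = FALSE)
    entries[j] <- list(e)
    horizons[j] <- if (is.null(e)) -1L else e$n_steps
  }
  names(entries) <- as.character(ks)
  if (all(horizons >= need)) {
    # hot path: everything cached at sufficient horizon
    ctx$tick <- ctx$tick + 1
    for (key in keys) assign(key, ctx$tick, envir = ctx$stamps)
    return(entries)
  }
  for (h in unique(horizons[horizons < need])) {
    sel <- which(horizons == h)
    kk <- ks[sel]
    P <- ctx$n_quad + 2L
    if (h < 0) {
      x <- ctx$grid$x
      u0 <- do.call(cbind, lapply(kk, function(k) cbind(x^k, (1 - x)^k)))
      add <- need
    } else {
      u0 <- do.call(cbind, lapply(entries[sel],
                                  function(e) cbind(e$finalA, e$finalB)))
      add <- need - h
    }
    rows <- generator_rows(ctx$grid, gamma)
    res <- cn_evolve(rows$lo, rows$di, rows$up, u0,
                     bc_left = rep(c(0, 1), length(kk)),
                     bc_right = rep(c(1, 0), length(kk)),
                     dt = dt, n_steps = add, n_euler = 0L,
                     probe_left = ctx$probe_left, probe_w = ctx$probe_w)
    ctx$solves <- ctx$solves + 2 * length(kk)
    for (j in seq_along(kk)) {
      pa <- res$probes[, ((2 * j - 2) * P + 1):((2 * j - 1) * P), drop = FALSE]
      pb <- res$probes[, ((2 * j - 1) * P + 1):((2 * j) * P), drop = FALSE]
      fa <- res$final[, 2 * j - 1]
      fb <- res$final[, 2 * j]
      if (h >= 0) {
        e0 <- entries[[sel[j]]]
        pa <- rbind(e0$probesA, pa[-1, , drop = FALSE])
        pb <- rbind(e0$probesB, pb[-1, , drop = FALSE])
      }
      e <- build_entry(ctx, gamma, kk[j], pa, pb, fa, fb, need)
      entries[[sel[j]]] <- e
      if (h < 0) ctx$n_entries <- ctx$n_entries + 1
      assign(keys[sel[j]], e, envir = ctx$cache)
    }
  }
  ctx$tick <- ctx$tick + 1
  for (key in keys) assign(key, ctx$tick, envir = ctx$stamps)
  if (ctx$n_entries > ctx$cache_max) prune_cache(ctx)
  entries
}

# evict least-recently-used entries down to 60% of capacity (chunked, so
# the scan cost is amortised over many insertions)
prune_cache <- function(ctx) {
  keys <- ls(ctx$cache)
  if (length(keys) <= ctx$cache_max) return(invisible())
  stamps <- vapply(keys, function(k) {
    s <- get0(k, envir = ctx$stamps, inherits = FALSE)
    if (is.null(s)) 0 else s
  }, numeric(1))
  # never evict the neutral (silent-class) entries: they are shared by all loci
  neutral <- startsWith(keys, "g+0.000000")
  drop_order <- keys[!neutral][order(stamps[!neutral])]
  n_drop <- length(keys) - as.integer(0.6 * ctx$cache_max)
  drop <- utils::head(drop_order, n_drop)
  rm(list = drop, envir = ctx$cache)
  rm(list = drop, envir = ctx$stamps)
  ctx$n_entries <- length(keys) - length(drop)
  invisible()
}

# linear interpolation helpers over the stored time levels (level j is time
# (j-1)*dt)
level_weights <- function(t, dt, n_levels) {
  pos <- t / dt
  j <- floor(pos + 1e-9)
  j <- min(max(j, 0), n_levels - 2)
  w <- pos - j
  if (w < 0) w <- 0
  if (w > 1) w <- 1
  list(j = as.integer(j) + 1L, w = w)
}

entry_slice <- function(e, t, dt, n_quad) {
  lw <- level_weights(t, dt, nrow(e$probesA))
  j <- lw$j; w <- lw$w
  iq <- seq_len(n_quad)
  if (w == 0) {
    a <- e$probesA[j, iq]
    b <- e$probesB[j, iq]
    IA <- e$IA[j]; IP <- e$IP[j]
  } else {
    a <- (1 - w) * e$probesA[j, iq] + w * e$probesA[j + 1L, iq]
    b <- (1 - w) * e$probesB[j, iq] + w * e$probesB[j + 1L, iq]
    IA <- (1 - w) * e$IA[j] + w * e$IA[j + 1L]
    IP <- (1 - w) * e$IP[j] + w * e$IP[j + 1L]
  }
  # a, b obey the discrete maximum principle up to roundoff; only p needs
  # guarding against tiny negative values near the endpoints
  p <- 1 - a - b
  p[p < 0] <- 0
  list(a = a, b = b, p = p, IA = IA, IP = IP)
}

#' Unit-rate DOHRS functionals
#'
#' The three expected DOHRS counts of one mutation class, per unit scaled
#' mutation rate: `fixed` (fixed differences), `poly_one` (polymorphic in
#' exactly one sample) and `poly_both` (polymorphic in both samples).  Each
#' combines a legacy term (equilibrium spectrum at the split, propagated
#' independently down the two daughter lineages and sampled with `m` and
#' `n` sequences) and a new-mutation term (mutational influx after the
#' split, integrated over its age); multiply by \eqn{\theta} to get the
#' Poisson means.
#'
#' @param ctx A [prf_context()].
#' @param gamma Scaled selection coefficient (0 for silent sites).
#' @param t Scaled divergence time (> 0).
#' @param m,n Sample sizes.
#' @return Named numeric vector `c(fixed, poly_one, poly_both)`.
#' @export
unit_functionals <- function(ctx, gamma, t, m, n) {
  stopifnot(inherits(ctx, "prf_context"))
  if (!is.finite(t) || t <= 0) stop("`t` must be positive", call. = FALSE)
  dt <- ctx$grid$dt
  nq <- ctx$n_quad
  w <- ctx$rule$weights
  ks <- unique(c(m, n))
  entries <- ensure_entries(ctx, gamma, ks, t)
  em <- entries[[as.character(m)]]
  en <- entries[[as.character(n)]]
  sm <- entry_slice(em, t, dt, nq)
  sn <- if (n == m) sm else entry_slice(en, t, dt, nq)
  g <- em$gq
  fixed <- sum(w * g * (sm$a * sn$b + sm$b * sn$a)) + 0.5 * (sm$IA + sn$IA)
  poly_one <- sum(w * g * (sm$p * (1 - sn$p) + (1 - sm$p) * sn$p)) +
    0.5 * (sm$IP + sn$IP)
  poly_both <- sum(w * g * (sm$p * sn$p))
  c(fixed = fixed, poly_one = poly_one, poly_both = poly_both)
}

#' Expected DOHRS counts for one locus
#'
#' The six Poisson means of a DOHRS table at divergence time `t`: fixed
#' differences, sites polymorphic in one sample, and sites polymorphic in
#' both samples, for silent sites (neutral, rate \eqn{\theta_s}) and
#' replacement sites (selection \eqn{\gamma}, rate \eqn{\theta_r}).  Each
#' mean sums the legacy-polymorphism contribution (sites segregating at the
#' split, whose frequency then diffuses independently in the two species)
#' and the new-mutation contribution (influx \eqn{\theta/2} per species per
#' unit time since the split).  Every mean is clamped below at `1e-12` so
#' that Poisson log-likelihoods stay finite at extreme parameters.
#'
#' @param params A [locus_parameters()] object.
#' @param t Scaled divergence time (> 0).
#' @param ctx A [prf_context()]; created with defaults when `NULL`.
#' @return An object of class `"expected_dohrs"`: named numeric vector with
#'   entries `fixed_s`, `poly_one_s`, `poly_both_s`, `fixed_r`,
#'   `poly_one_r`, `poly_both_r`.
#' @export
expected_counts <- function(params, t, ctx = NULL) {
  stopifnot(inherits(params, "locus_parameters"))
  if (is.null(ctx)) ctx <- prf_context()
  fs <- unit_functionals(ctx, 0, t, params$m, params$n)
  fr <- unit_functionals(ctx, params$gamma, t, params$m, params$n)
  out <- c(params$theta_s * fs, params$theta_r * fr)
  names(out) <- c("fixed_s", "poly_one_s", "poly_both_s",
                  "fixed_r", "poly_one_r", "poly_both_r")
  out <- pmax(out, 1e-12)
  class(out) <- "expected_dohrs"
  out
}

#' @export
print.expected_dohrs <- function(x, ...) {
  cat("Expected DOHRS counts (Poisson means):\n")
  print(unclass(x), ...)
  invisible(x)
}
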