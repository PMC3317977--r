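test_that("the discrete generator kills constants and neutral linears", {
  g <- frequency_grid(50, 1e-3)
  expect_equal(generator_apply(rep(2, 52), 1.7, g), rep(0, 52))
  # gamma = 0: L x = 0 (the martingale property, exact for the 3-point stencil)
  Lx <- generator_apply(g$x_full, 0, g)
  expect_lt(max(abs(Lx)), 1e-10)
})

test_that("x(1-x) is an eigenfunction of the neutral generator with eigenvalue -1", {
  g <- frequency_grid(80, 1e-3)
  fv <- g$x_full * (1 - g$x_full)
  Lf <- generator_apply(fv, 0, g)
  i <- 2:(g$n_interior + 1)
  expect_equal(Lf[i] / fv[i], rep(-1, length(i)), tolerance = 1e-10)
})

test_that("generator_apply validates its inputs", {
  expect_error(frequency_grid(2), ">= 3")
  g <- frequency_grid(10)
  expect_error(generator_apply(rep(1, 5), 0, g), "full grid")
  expect_error(generator_apply(c(rep(1, 11), NA), 0, g), "finite")
})

test_that("constants are invariant under the backward evolution", {
  g <- frequency_grid(100, 1e-3)
  for (gam in c(0, 3)) {
    s <- solve_backward(function(x) rep(1, length(x)), gam, 0.7, g)
    expect_lt(max(abs(s$values - 1)), 1e-8)
  }
})

test_that("the neutral diffusion preserves the identity payoff (martingale)", {
  g <- frequency_grid(400, 1e-3)
  s <- solve_backward(function(x) x, 0, 0.5, g)
  expect_lt(max(abs(s$values[nrow(s$values), ] - g$x_full)), 1e-4)
})

test_that("the neutral eigenfunction decays at the generator's rate", {
  g <- frequency_grid(400, 1e-3)
  f <- function(x) x * (1 - x)
  # eigenvalue of the discrete operator, read off by applying the generator
  fv <- f(g$x_full)
  lam <- generator_apply(fv, 0, g)[200] / fv[200]
  s <- solve_backward(f, 0, 1, g)
  u1 <- s$values[nrow(s$values), ]
  expect_equal(max(abs(u1 - exp(lam * 1) * fv)) / max(fv), 0, tolerance = 0.01)
})

test_that("the solution respects the maximum principle", {
  g <- frequency_grid(200, 1e-3)
  payoffs <- list(function(x) x^2, function(x) x^5, function(x) sin(pi * x))
  for (f in payoffs) {
    for (gam in c(-2, 0, 2)) {
      s <- solve_backward(f, gam, 0.4, g)
      expect_gte(min(s$values), min(f(g$x_full)) - 1e-8)
      expect_lte(max(s$values), max(f(g$x_full)) + 1e-8)
    }
  }
})

test_that("solving in two stages equals solving in one (semigroup property)", {
  g <- frequency_grid(150, 1e-3)
  f <- function(x) x^3
  gam <- 1.5
  direct <- solve_backward(f, gam, 0.6, g)
  stage1 <- solve_backward(f, gam, 0.3, g)
  u_mid <- stage1$values[nrow(stage1$values), ]
  # restart payoff hits the same grid nodes exactly, so no interpolation error
  f_mid <- approxfun(g$x_full, u_mid)
  stage2 <- solve_backward(f_mid, gam, 0.3, g)
  expect_lt(max(abs(stage2$values[nrow(stage2$values), ] -
                      direct$values[nrow(direct$values), ])), 1e-6)
})

test_that("refinement converges at second order on the eigenfunction test", {
  f <- function(x) x * (1 - x)
  err <- function(J, dt) {
    g <- frequency_grid(J, dt)
    s <- solve_backward(f, 0, 1, g)
    max(abs(s$values[nrow(s$values), ] - exp(-1) * f(g$x_full)))
  }
  e1 <- err(100, 4e-3)
  e2 <- err(200, 2e-3)
  expect_gte(log2(e1 / e2), 1.8)
})

test_that("spatial refinement converges at second order for a selected payoff", {
  # reference solution on a fine grid; coarser grids compared at their own
  # nodes via interpolation of the reference
  f <- function(x) x^5
  gam <- 1
  g_ref <- frequency_grid(800, 5e-4)
  u_ref <- solve_backward(f, gam, 0.5, g_ref)
  ref_fun <- approxfun(g_ref$x_full,
                       u_ref$values[nrow(u_ref$values), ])
  err <- function(J) {
    g <- frequency_grid(J, 5e-4)
    s <- solve_backward(f, gam, 0.5, g)
    max(abs(s$values[nrow(s$values), ] - ref_fun(g$x_full)))
  }
  order_obs <- log2(err(50) / err(100))
  expect_gte(order_obs, 1.8)
})

test_that("the neutral discrete generator is symmetric under the speed measure", {
  g <- frequency_grid(25, 1e-3)
  J <- g$n_interior
  L <- matrix(0, J + 2, J + 2)
  for (j in seq_len(J + 2)) {
    e <- numeric(J + 2)
    e[j] <- 1
    L[, j] <- generator_apply(e, 0, g)
  }
  Li <- L[2:(J + 1), 2:(J + 1)]
  x <- g$x
  hm <- x - g$x_full[seq_len(J)]
  hp <- g$x_full[seq_len(J) + 2] - x
  w <- (hm + hp) / (x * (1 - x))   # discrete speed measure
  M <- diag(w) %*% Li
  expect_lt(max(abs(M - t(M))), 1e-10)
})

test_that("transition expectations reduce to direct integrals at small times", {
  g <- frequency_grid(200, 1e-3)
  r <- freq_rule(24)
  beta22 <- function(x) 6 * x * (1 - x)
  expect_equal(
    transition_expectation(function(x) x^2, beta22, 0, 1e-6, g, r),
    0.3, tolerance = 1e-4)
  expect_equal(
    transition_expectation(function(x) rep(1, length(x)), beta22, 3, 0.5, g, r),
    1, tolerance = 1e-6)
  expect_equal(
    transition_expectation(function(x) x, function(x) rep(1, length(x)),
                           0, 0.8, g, r),
    0.5, tolerance = 1e-4)
  expect_error(
    transition_expectation(function(x) x, function(x) x - 0.5, 0, 0.5, g, r),
    "negative")
})

test_that("neutral absorption from a symmetric start splits evenly", {
  g <- frequency_grid(200, 1e-3)
  af <- absorption_flux(0, c(0.05, 1, 2), g, initial = 0.5)
  expect_equal(af$absorbed0, af$absorbed1, tolerance = 0.01)
  # no instantaneous absorption from an interior start
  expect_lt(af$absorbed1[1], 1e-3)
})

test_that("the influx fixation flux approaches the classical rate constant", {
  g <- frequency_grid(400, 1e-3)
  for (gam in c(1, 2)) {
    fp <- absorption_flux(gam, 6, g, initial = "influx")$flux1
    fm <- absorption_flux(-gam, 6, g, initial = "influx")$flux1
    expect_equal(fp / fm, exp(2 * gam), tolerance = 0.02)
    expect_equal(fp, 2 * gam / (1 - exp(-2 * gam)), tolerance = 0.02)
  }
})
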