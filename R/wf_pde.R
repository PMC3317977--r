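#' Discretisation grid for the Wright-Fisher frequency space
#'
#' Interior nodes are sinh-spaced so that they concentrate near the
#' absorbing endpoints 0 and 1, where frequency spectra and sampling
#' probabilities vary fastest.  The endpoints themselves are kept as
#' boundary points: both the diffusion and the drift coefficient of the
#' Wright-Fisher generator vanish there, so the backward solution is frozen
#' at its payoff value on the boundary.
#'
#' @param n_interior Number of interior nodes (>= 3).
#' @param dt Time step of the Crank-Nicolson scheme, in diffusion time units
#'   (one unit = \eqn{N_e} haploid generations).
#' @param concentration Sinh stretching parameter; larger values push more
#'   nodes toward the endpoints.  0 gives a uniform grid.
#' @return An object of class `"frequency_grid"` with elements `x` (interior
#'   nodes), `x_full` (including 0 and 1), `dt`, `n_interior`,
#'   `concentration`.
#' @export
frequency_grid <- function(n_interior = 400, dt = 1e-3, concentration = 6) {
  stopifnot(n_interior >= 3, dt > 0, concentration >= 0)
  xi <- seq_len(n_interior) / (n_interior + 1)
  if (concentration == 0) {
    x <- xi
  } else {
    x <- 0.5 * (1 + sinh(concentration * (xi - 0.5)) / sinh(concentration / 2))
  }
  structure(
    list(x = x, x_full = c(0, x, 1), dt = dt,
         n_interior = as.integer(n_interior), concentration = concentration),
    class = "frequency_grid"
  )
}

# Tridiagonal rows of the discrete generator
#   L u = 1/2 x(1-x) u'' + gamma x(1-x) u'
# at the interior nodes, using 3-point finite differences on the
# (non-uniform) grid.  Row i couples (x_{i-1}, x_i, x_{i+1}) with the
# boundary points at the ends.
generator_rows <- function(grid, gamma) {
  x <- grid$x
  xf <- grid$x_full
  J <- length(x)
  hm <- x - xf[seq_len(J)]
  hp <- xf[seq_len(J) + 2L] - x
  a <- 0.5 * x * (1 - x)
  b <- gamma * x * (1 - x)
  d1l <- -hp / (hm * (hm + hp))
  d1c <- (hp - hm) / (hm * hp)
  d1r <- hm / (hp * (hm + hp))
  d2l <- 2 / (hm * (hm + hp))
  d2c <- -2 / (hm * hp)
  d2r <- 2 / (hp * (hm + hp))
  list(lo = a * d2l + b * d1l,
       di = a * d2c + b * d1c,
       up = a * d2r + b * d1r)
}

#' Apply the Wright-Fisher generator to grid values
#'
#' Computes the spatial operator of the backward Kolmogorov equation,
#' \eqn{L f = \frac12 x(1-x) f'' + \gamma x(1-x) f'}, by second-order finite
#' differences at the interior nodes.  The result is 0 at the boundary
#' entries (the generator is degenerate at 0 and 1).
#'
#' @param f_values Values of `f` on the full grid (`grid$x_full`), length
#'   `n_interior + 2`.
#' @param gamma Scaled selection coefficient (\eqn{\gamma = N_e s}).
#' @param grid A [frequency_grid()].
#' @return Numeric vector on the full grid: `L f` at interior nodes, 0 at
#'   the two boundary entries.
#' @export
generator_apply <- function(f_values, gamma, grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  J <- grid$n_interior
  if (J < 3) stop("grid must have at least 3 interior nodes", call. = FALSE)
  if (length(f_values) != J + 2L) {
    stop("`f_values` must be given on the full grid (boundaries included)",
         call. = FALSE)
  }
  if (!all(is.finite(f_values))) stop("`f_values` must be finite", call. = FALSE)
  rows <- generator_rows(grid, gamma)
  i <- seq_len(J) + 1L
  out <- numeric(J + 2L)
  out[i] <- rows$lo * f_values[i - 1L] + rows$di * f_values[i] +
    rows$up * f_values[i + 1L]
  out
}

# Interpolation stencils (0-based left index + weight) for probing the full
# grid solution at arbitrary frequencies by linear interpolation.
probe_stencil <- function(grid, at) {
  xf <- grid$x_full
  idx <- findInterval(at, xf, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(xf) - 1L)
  w <- (at - xf[idx]) / (xf[idx + 1L] - xf[idx])
  list(left = idx - 1L, w = w)
}

#' Solve the backward Kolmogorov equation by Crank-Nicolson
#'
#' Computes \eqn{u(t, x) = E_x[f(X_t)]} for the Wright-Fisher diffusion with
#' scaled selection coefficient `gamma`, i.e. the solution of
#' \eqn{\partial_t u = \frac12 x(1-x)\partial_x^2 u + \gamma x(1-x)\partial_x u}
#' with \eqn{u(0,\cdot) = f}.  The endpoints are absorbing, so
#' \eqn{u(t,0)=f(0)} and \eqn{u(t,1)=f(1)} for all \eqn{t}.  All intermediate
#' time levels are retained.
#'
#' @param f Payoff function on \eqn{[0,1]} (vectorised).
#' @param gamma Scaled selection coefficient.
#' @param t Final time (> 0), in units of \eqn{N_e} generations.
#' @param grid A [frequency_grid()]; the time step used is
#'   `t / ceiling(t / grid$dt)` so that `t` is hit exactly.
#' @param n_euler Number of damped (backward Euler) start-up steps; leave at
#'   0 for smooth payoffs.
#' @param payoff_id Optional label stored with the solution.
#' @return An object of class `"backward_solution"`: list with `grid`,
#'   `gamma`, `times` (length `n_steps + 1`), `values`
#'   (`(n_steps+1) x (n_interior+2)` matrix, row 1 = payoff) and
#'   `payoff_id`.
#' @export
solve_backward <- function(f, gamma, t, grid, n_euler = 0L, payoff_id = NULL) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("`t` must be a positive number", call. = FALSE)
  }
  fx <- f(grid$x_full)
  if (!all(is.finite(fx))) stop("payoff `f` must be finite on [0,1]", call. = FALSE)
  n_steps <- max(1L, as.integer(ceiling(t / grid$dt - 1e-9)))
  dt_eff <- t / n_steps
  rows <- generator_rows(grid, gamma)
  # probe every full-grid node exactly
  J2 <- grid$n_interior + 2L
  res <- cn_evolve(rows$lo, rows$di, rows$up,
                   u0 = matrix(fx[2:(J2 - 1L)], ncol = 1),
                   bc_left = fx[1], bc_right = fx[J2],
                   dt = dt_eff, n_steps = n_steps, n_euler = as.integer(n_euler),
                   probe_left = 0:(J2 - 1L), probe_w = rep(0, J2))
  structure(
    list(grid = grid, gamma = gamma,
         times = seq(0, t, length.out = n_steps + 1L),
         values = res$probes,
         payoff_id = payoff_id %||% deparse(substitute(f))),
    class = "backward_solution"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# values of a backward_solution at time t (linear interpolation in t)
solution_at <- function(sol, t) {
  times <- sol$times
  if (t < times[1] - 1e-12 || t > times[length(times)] + 1e-9) {
    stop("time outside the solved range", call. = FALSE)
  }
  j <- findInterval(t, times, rightmost.closed = TRUE)
  j <- min(max(j, 1L), length(times) - 1L)
  w <- (t - times[j]) / (times[j + 1L] - times[j])
  (1 - w) * sol$values[j, ] + w * sol$values[j + 1L, ]
}

#' Expectation of a payoff under the transition density
#'
#' Computes \eqn{\int_0^1 \rho(x)\, u(t, x)\, dx} where
#' \eqn{u(t,x) = E_x[f(X_t)]} comes from [solve_backward()] and \eqn{\rho}
#' is an initial frequency density, possibly with an integrable \eqn{1/x}
#' singularity at 0 (handled by the log-substitution rule of
#' [freq_rule()]).
#'
#' @param f Payoff function.
#' @param initial_density Density of the initial frequency on \eqn{(0,1)};
#'   must be non-negative.
#' @param gamma Scaled selection coefficient.
#' @param t Elapsed time (> 0).
#' @param grid A [frequency_grid()].
#' @param rule Quadrature rule on \eqn{(0,1)}; defaults to [freq_rule()].
#' @return The scalar integral.
#' @export
transition_expectation <- function(f, initial_density, gamma, t, grid,
                                   rule = freq_rule()) {
  sol <- solve_backward(f, gamma, t, grid, payoff_id = "transition_expectation")
  ut <- sol$values[nrow(sol$values), ]
  st <- probe_stencil(grid, rule$nodes)
  uq <- (1 - st$w) * sol_full(ut, st$left) + st$w * sol_full(ut, st$left + 1L)
  dens <- initial_density(rule$nodes)
  if (any(!is.finite(dens))) stop("initial density not finite at a node", call. = FALSE)
  if (any(dens < 0)) {
    stop(sprintf("initial density negative at x = %.6g",
                 rule$nodes[which(dens < 0)[1]]), call. = FALSE)
  }
  sum(rule$weights * dens * uq)
}

# index into a full-grid vector by 0-based full index
sol_full <- function(u_full, idx0) u_full[idx0 + 1L]

#' Probability flux into the absorbing boundaries
#'
#' Tracks the probability mass absorbed at frequency 1 (fixation) and 0
#' (loss) over time, either for an initial frequency distribution or for the
#' steady influx of brand-new mutations at frequency \eqn{0^+} (the boundary
#' condition used for post-divergence mutations in the Poisson random field
#' model).
#'
#' With `initial = "influx"` the returned columns are the instantaneous
#' fixation/loss rates of a unit-rate influx of mutations entering at
#' vanishing frequency: `flux1` is \eqn{\partial_x P_x(\mathrm{fixed\ by\ }
#' t)|_{x=0}}, which for large `t` approaches the classical fixation-rate
#' constant \eqn{2\gamma/(1-e^{-2\gamma})}.  Otherwise `absorbed0` /
#' `absorbed1` are cumulative absorbed masses and `flux0` / `flux1` their
#' time derivatives.
#'
#' @param gamma Scaled selection coefficient.
#' @param times Increasing vector of report times (>= 0).
#' @param grid A [frequency_grid()].
#' @param initial Either the string `"influx"`, a single frequency in (0,1)
#'   (point initial condition), or a density function on (0,1).
#' @param rule Quadrature rule used when `initial` is a density.
#' @return A data frame with columns `time`, `absorbed0`, `absorbed1`,
#'   `flux0`, `flux1` (absorbed columns are `NA` in influx mode).
#' @export
absorption_flux <- function(gamma, times, grid, initial = "influx",
                            rule = freq_rule()) {
  stopifnot(inherits(grid, "frequency_grid"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  t_end <- max(times, grid$dt)
  # absorption probabilities solve the backward equation with an indicator
  # payoff concentrated on the boundary point
  ind1 <- function(x) as.numeric(x >= 1)
  ind0 <- function(x) as.numeric(x <= 0)
  sol1 <- solve_backward(ind1, gamma, t_end, grid, n_euler = 4L, payoff_id = "fix")
  sol0 <- solve_backward(ind0, gamma, t_end, grid, n_euler = 4L, payoff_id = "loss")

  eval_mass <- function(sol) {
    if (identical(initial, "influx")) {
      x1 <- grid$x[1]; x2 <- grid$x[2]
      vapply(times, function(tt) {
        u <- solution_at(sol, tt)
        u1 <- u[2]; u2 <- u[3]
        # quadratic extrapolation of u(x)/x to x = 0 (u(0) = 0)
        (x2^2 * u1 - x1^2 * u2) / (x1 * x2 * (x2 - x1))
      }, numeric(1))
    } else if (is.function(initial)) {
      st <- probe_stencil(grid, rule$nodes)
      dens <- initial(rule$nodes)
      vapply(times, function(tt) {
        u <- solution_at(sol, tt)
        uq <- (1 - st$w) * sol_full(u, st$left) + st$w * sol_full(u, st$left + 1L)
        sum(rule$weights * dens * uq)
      }, numeric(1))
    } else {
      x0 <- as.numeric(initial)
      stopifnot(length(x0) == 1L, x0 > 0, x0 < 1)
      st <- probe_stencil(grid, x0)
      vapply(times, function(tt) {
        u <- solution_at(sol, tt)
        (1 - st$w) * sol_full(u, st$left) + st$w * sol_full(u, st$left + 1L)
      }, numeric(1))
    }
  }

  m1 <- eval_mass(sol1)
  m0 <- eval_mass(sol0)
  if (identical(initial, "influx")) {
    # the influx-mode extrapolation already is a rate (per unit influx);
    # note ind0 has payoff 1 at x = 0 so u/x extrapolation is meaningless
    data.frame(time = times, absorbed0 = NA_real_, absorbed1 = NA_real_,
               flux0 = NA_real_, flux1 = m1)
  } else {
    grad <- function(m) {
      if (length(times) < 2) return(rep(NA_real_, length(times)))
      c(diff(m)[1] / diff(times)[1], diff(m) / diff(times))
    }
    data.frame(time = times, absorbed0 = m0, absorbed1 = m1,
               flux0 = grad(m0), flux1 = grad(m1))
  }
}
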