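#' Gauss-Legendre quadrature rule on an interval
#'
#' Builds the `order`-point Gauss-Legendre rule mapped affinely from
#' \eqn{[-1,1]} to `[lower, upper]`.  A rule of order \eqn{k} integrates
#' polynomials up to degree \eqn{2k-1} exactly.
#'
#' @param order Number of nodes (positive integer).
#' @param lower,upper Interval endpoints, `lower < upper`.
#' @return An object of class `"quadrature_rule"`: a list with elements
#'   `order`, `lower`, `upper`, `nodes` and `weights`.
#' @examples
#' r <- gauss_legendre_rule(2, 0, 1)
#' quad_integrate(function(x) x^3, r)  # exactly 1/4
#' @export
gauss_legendre_rule <- function(order, lower = -1, upper = 1) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order < 1 || order != round(order)) {
    stop("`order` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(lower) || !is.numeric(upper) || !is.finite(lower) ||
      !is.finite(upper) || lower >= upper) {
    stop("interval is degenerate: need finite `lower` < `upper`", call. = FALSE)
  }
  order <- as.integer(order)
  if (order == 1L) {
    # one-point rule: midpoint, weight = interval length
    nodes <- (lower + upper) / 2
    weights <- upper - lower
  } else {
    gl <- pracma::gaussLegendre(order, lower, upper)
    nodes <- gl$x
    weights <- gl$w
  }
  structure(
    list(order = order, lower = lower, upper = upper,
         nodes = nodes, weights = weights),
    class = "quadrature_rule"
  )
}

#' Integrate a function with a quadrature rule
#'
#' @param f Vectorised function of one variable, finite at all nodes.
#' @param rule A [gauss_legendre_rule()] object.
#' @return The weighted sum \eqn{\sum_i w_i f(x_i)}.
#' @export
quad_integrate <- function(f, rule) {
  stopifnot(inherits(rule, "quadrature_rule"))
  fx <- f(rule$nodes)
  if (length(fx) != length(rule$nodes)) {
    stop("`f` must be vectorised over the nodes", call. = FALSE)
  }
  bad <- !is.finite(fx)
  if (any(bad)) {
    stop(sprintf("`f` is not finite at node x = %.8g", rule$nodes[which(bad)[1]]),
         call. = FALSE)
  }
  sum(rule$weights * fx)
}

#' Quadrature rule for frequency-space integrals on (0, 1)
#'
#' Site-frequency spectra diverge like \eqn{1/x} at the origin, so a plain
#' rule on \eqn{(0,1)} converges poorly.  This rule is a composite of a
#' Gauss-Legendre panel on \eqn{[1/2, 1]} (where spectra are smooth) and
#' Gauss-Legendre panels in the variable \eqn{u = -\log x} on
#' \eqn{(\epsilon, 1/2)}, i.e. the substitution \eqn{x = e^{-u}} that turns
#' \eqn{dx/x} into \eqn{du}.  The frequency range below the truncation point
#' `eps` is dropped; its contribution to every integrand used here is
#' \eqn{O(\epsilon)}.
#'
#' @param order Nodes per panel.
#' @param eps Truncation frequency near 0.
#' @param log_panels Number of equal panels in \eqn{u} on
#'   \eqn{[\log 2, \log(1/\epsilon)]}.
#' @return A `"quadrature_rule"` whose nodes lie in \eqn{(\epsilon, 1)}; its
#'   weights include the substitution Jacobian so that
#'   [quad_integrate()] approximates \eqn{\int_\epsilon^1 f(x)\,dx} even when
#'   \eqn{f \sim c/x} near 0.
#' @export
freq_rule <- function(order = 24, eps = 1e-8, log_panels = 3) {
  stopifnot(order >= 2, eps > 0, eps < 0.5, log_panels >= 1)
  upper <- gauss_legendre_rule(order, 0.5, 1)
  nodes <- upper$nodes
  weights <- upper$weights
  u_lo <- log(2)
  u_hi <- log(1 / eps)
  breaks <- seq(u_lo, u_hi, length.out = log_panels + 1)
  for (p in seq_len(log_panels)) {
    r <- gauss_legendre_rule(order, breaks[p], breaks[p + 1])
    x <- exp(-r$nodes)
    nodes <- c(nodes, x)
    weights <- c(weights, r$weights * x)  # dx = -x du
  }
  ord <- order(nodes)
  structure(
    list(order = as.integer(order), lower = eps, upper = 1,
         nodes = nodes[ord], weights = weights[ord]),
    class = "quadrature_rule"
  )
}
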