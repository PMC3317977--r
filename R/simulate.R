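#' Design of a DOHRS simulation study
#'
#' Describes how one synthetic dataset is generated: fixed global
#' parameters (divergence time `t`, selection mean `mu_gamma` and variance
#' `sigma2`), and the distributions of the locus-specific parameters --
#' per-locus selection coefficients \eqn{\gamma_i \sim N(\mu_\gamma,
#' \sigma^2)}, mutation rates drawn from continuous uniform ranges, and
#' sample sizes from discrete uniform ranges.  The default ranges
#' (\eqn{\theta_s \in [1, 20]}, \eqn{\theta_r \in [0.5, 10]},
#' \eqn{m, n \in \{5, \dots, 15\}}) are plausible for Drosophila-scale
#' nuclear loci and are fully configurable.
#'
#' @param n_loci Number of loci per dataset (default 30).
#' @param t Scaled divergence time.
#' @param mu_gamma Mean of the across-locus selection distribution.
#' @param sigma2 Variance of the across-locus selection distribution (>= 0).
#' @param theta_s_range,theta_r_range Uniform ranges `c(low, high)` with
#'   `0 < low <= high`.
#' @param m_range,n_range Integer ranges `c(low, high)` with `low >= 1`.
#' @param seed Integer seed; every draw derived from this design is
#'   reproducible given the seed.
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_loci = 30, t = 1, mu_gamma = 1, sigma2 = 4,
                              theta_s_range = c(1, 20),
                              theta_r_range = c(0.5, 10),
                              m_range = c(5, 15), n_range = c(5, 15),
                              seed = 1) {
  if (!is.numeric(n_loci) || n_loci < 1 || n_loci != round(n_loci)) {
    stop("`n_loci` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(t) || t <= 0) stop("`t` must be positive", call. = FALSE)
  if (!is.numeric(sigma2) || sigma2 < 0) stop("`sigma2` must be >= 0", call. = FALSE)
  chk_range <- function(r, name, low_min) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < low_min) {
      stop(sprintf("`%s` must be c(low, high) with %g <= low <= high",
                   name, low_min), call. = FALSE)
    }
  }
  chk_range(theta_s_range, "theta_s_range", .Machine$double.xmin)
  chk_range(theta_r_range, "theta_r_range", .Machine$double.xmin)
  chk_range(m_range, "m_range", 1)
  chk_range(n_range, "n_range", 1)
  structure(
    list(n_loci = as.integer(n_loci), t = t, mu_gamma = mu_gamma,
         sigma2 = sigma2, theta_s_range = theta_s_range,
         theta_r_range = theta_r_range,
         m_range = as.integer(m_range), n_range = as.integer(n_range),
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# deterministic per-locus substream seeds from the design seed, so locus i
# is reproducible even if n_loci changes
locus_seeds <- function(design, n) {
  withr_seed <- design$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)
  sample.int(.Machine$integer.max, n)
}

#' Draw locus-specific parameters from a simulation design
#'
#' @param design A [simulation_design()].
#' @return A list of [locus_parameters()] of length `design$n_loci`, with
#'   attribute `"truth"`: a data frame of the drawn values.
#' @export
draw_locus_parameters <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  seeds <- locus_seeds(design, design$n_loci)
  params <- vector("list", design$n_loci)
  for (i in seq_len(design$n_loci)) {
    set.seed(seeds[i])
    gamma <- stats::rnorm(1, design$mu_gamma, sqrt(design$sigma2))
    theta_s <- stats::runif(1, design$theta_s_range[1], design$theta_s_range[2])
    theta_r <- stats::runif(1, design$theta_r_range[1], design$theta_r_range[2])
    # sample.int avoids the base-R sample() scalar pitfall for lo == hi
    m <- design$m_range[1] + sample.int(design$m_range[2] - design$m_range[1] + 1L, 1) - 1L
    n <- design$n_range[1] + sample.int(design$n_range[2] - design$n_range[1] + 1L, 1) - 1L
    params[[i]] <- locus_parameters(theta_s, theta_r, gamma, m, n,
                                    locus_id = sprintf("locus_%03d", i))
  }
  truth <- data.frame(
    locus_id = vapply(params, `[[`, "", "locus_id"),
    theta_s = vapply(params, `[[`, 0, "theta_s"),
    theta_r = vapply(params, `[[`, 0, "theta_r"),
    gamma = vapply(params, `[[`, 0, "gamma"),
    m = vapply(params, `[[`, 0L, "m"),
    n = vapply(params, `[[`, 0L, "n")
  )
  attr(params, "truth") <- truth
  params
}

#' Simulate a DOHRS dataset
#'
#' Draws locus parameters from the design, computes the six Poisson means
#' per locus with [expected_counts()] at the design's divergence time, and
#' samples the six counts from independent Poisson distributions.
#'
#' @param design A [simulation_design()].
#' @param ctx A [prf_context()] (defaults are used when `NULL`).
#' @return A [dohrs_dataset()] with attribute `"truth"`: the per-locus true
#'   parameters plus the global `t`, `mu_gamma`, `sigma2` (as attributes of
#'   the truth data frame).
#' @export
simulate_dohrs <- function(design, ctx = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(ctx)) ctx <- prf_context()
  params <- draw_locus_parameters(design)
  seeds <- locus_seeds(design, design$n_loci)
  rows <- vector("list", design$n_loci)
  for (i in seq_len(design$n_loci)) {
    p <- params[[i]]
    mu <- expected_counts(p, design$t, ctx)
    set.seed(seeds[i] %% .Machine$integer.max + 1L)  # distinct from the parameter stream
    counts <- stats::rpois(6, unclass(mu))
    if (min(p$m, p$n) == 1) counts[c(3, 6)] <- 0L
    rows[[i]] <- data.frame(
      locus_id = p$locus_id, m = p$m, n = p$n,
      fixed_s = counts[1], poly_one_s = counts[2], poly_both_s = counts[3],
      fixed_r = counts[4], poly_one_r = counts[5], poly_both_r = counts[6]
    )
  }
  ds <- dohrs_dataset(do.call(rbind, rows),
                      provenance = sprintf("simulated (seed %d)", design$seed))
  truth <- attr(params, "truth")
  attr(truth, "t") <- design$t
  attr(truth, "mu_gamma") <- design$mu_gamma
  attr(truth, "sigma2") <- design$sigma2
  attr(ds, "truth") <- truth
  ds
}

#' Write / read the truth sidecar of a simulated dataset
#'
#' The sidecar records the per-locus true parameters (same locus order as
#' the dataset) and the global `t`, `mu_gamma`, `sigma2` in `#`-comment
#' header lines, for downstream recovery scoring.
#'
#' @param truth The `"truth"` attribute of a simulated dataset.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t=%.10g mu_gamma=%.10g sigma2=%.10g",
                     attr(truth, "t"), attr(truth, "mu_gamma"),
                     attr(truth, "sigma2")), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  header <- readLines(path, n = 1)
  vals <- regmatches(header, gregexpr("[a-z_2]+=[-0-9.eE+]+", header))[[1]]
  kv <- strsplit(vals, "=")
  truth <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
  for (p in kv) attr(truth, p[1]) <- as.numeric(p[2])
  truth
}
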