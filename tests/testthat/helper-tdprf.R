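# Shared fixtures: solver contexts are expensive to warm up, so tests share
# one default-accuracy context and one reduced ("quick") context.

tdprf_test_env <- new.env()

default_ctx <- function() {
  if (is.null(tdprf_test_env$ctx_default)) {
    tdprf_test_env$ctx_default <- prf_context()
  }
  tdprf_test_env$ctx_default
}

quick_ctx <- function() {
  if (is.null(tdprf_test_env$ctx_quick)) {
    tdprf_test_env$ctx_quick <- prf_context(n_grid = 61, dt = 0.01, quad_order = 12,
                                            cache_max = 1500,
                                            gamma_quantum = 0.01)
  }
  tdprf_test_env$ctx_quick
}

watterson <- function(n) sum(1 / seq_len(n - 1))

# small deterministic DOHRS data frame for I/O and likelihood tests
toy_dohrs <- function(n_loci = 3) {
  set.seed(42)
  dohrs_dataset(data.frame(
    locus_id = sprintf("L%02d", seq_len(n_loci)),
    m = sample(5:12, n_loci, replace = TRUE),
    n = sample(5:12, n_loci, replace = TRUE),
    fixed_s = rpois(n_loci, 8), poly_one_s = rpois(n_loci, 12),
    poly_both_s = rpois(n_loci, 4), fixed_r = rpois(n_loci, 3),
    poly_one_r = rpois(n_loci, 5), poly_both_r = rpois(n_loci, 1)
  ))
}
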