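test_that("degenerate designs produce constant locus parameters", {
  des <- simulation_design(n_loci = 20, mu_gamma = 2.5, sigma2 = 0,
                           theta_s_range = c(3, 3), theta_r_range = c(1, 1),
                           m_range = c(7, 7), n_range = c(9, 9), seed = 5)
  ps <- draw_locus_parameters(des)
  expect_true(all(vapply(ps, `[[`, 0, "gamma") == 2.5))
  expect_true(all(vapply(ps, `[[`, 0, "theta_s") == 3))
  expect_true(all(vapply(ps, `[[`, 0L, "m") == 7L))
  expect_true(all(vapply(ps, `[[`, 0L, "n") == 9L))
})

test_that("selection coefficients are drawn from the across-locus normal", {
  des <- simulation_design(n_loci = 10000, mu_gamma = 1.5, sigma2 = 4, seed = 9)
  g <- attr(draw_locus_parameters(des), "truth")$gamma
  se <- 2 / sqrt(10000)
  expect_lt(abs(mean(g) - 1.5), 3 * se)
  expect_lt(abs(sd(g) - 2), 0.1)
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(n_loci = 0), "positive integer")
  expect_error(simulation_design(t = -1), "positive")
  expect_error(simulation_design(sigma2 = -2), ">= 0")
  expect_error(simulation_design(theta_s_range = c(5, 2)), "low <= high")
  expect_error(simulation_design(m_range = c(0, 5)), "low <= high")
})

test_that("simulated datasets are reproducible and valid", {
  ctx <- quick_ctx()
  des <- simulation_design(n_loci = 8, seed = 21)
  d1 <- simulate_dohrs(des, ctx)
  d2 <- simulate_dohrs(des, ctx)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_silent(validate_dohrs(d1))
  expect_equal(nrow(d1), 8)
  truth <- attr(d1, "truth")
  expect_equal(nrow(truth), 8)
  expect_equal(attr(truth, "t"), des$t)
})

test_that("a vanishing replacement rate leaves replacement classes empty", {
  ctx <- quick_ctx()
  des <- simulation_design(n_loci = 6, theta_r_range = c(1e-9, 1e-9), seed = 3)
  ds <- simulate_dohrs(des, ctx)
  expect_true(all(ds$fixed_r == 0 & ds$poly_one_r == 0 & ds$poly_both_r == 0))
})

test_that("counts have the Poisson means and equidispersion of the model", {
  # one parameter point replicated across many loci = replicate Poisson draws
  ctx <- quick_ctx()
  des <- simulation_design(n_loci = 1000, t = 0.8, mu_gamma = 2, sigma2 = 0,
                           theta_s_range = c(5, 5), theta_r_range = c(2, 2),
                           m_range = c(8, 8), n_range = c(11, 11), seed = 17)
  ds <- simulate_dohrs(des, ctx)
  lam <- expected_counts(locus_parameters(5, 2, 2, 8, 11), 0.8, ctx)
  cols <- c("fixed_s", "poly_one_s", "poly_both_s",
            "fixed_r", "poly_one_r", "poly_both_r")
  for (j in seq_along(cols)) {
    x <- ds[[cols[j]]]
    se_mean <- sqrt(lam[[j]] / 1000)
    expect_lt(abs(mean(x) - lam[[j]]), 3 * se_mean + 1e-9)
    # variance-to-mean ratio near 1 (Poisson equidispersion)
    if (lam[[j]] > 0.5) {
      expect_lt(abs(var(x) / mean(x) - 1), 3 * sqrt(2 / 999) + 3 / sqrt(lam[[j]] * 1000))
    }
  }
})

test_that("truth sidecars round-trip through their TSV format", {
  ctx <- quick_ctx()
  des <- simulation_design(n_loci = 4, seed = 2)
  ds <- simulate_dohrs(des, ctx)
  truth <- attr(ds, "truth")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$gamma, truth$gamma, tolerance = 1e-9)
  expect_equal(attr(back, "t"), attr(truth, "t"))
  expect_equal(attr(back, "sigma2"), attr(truth, "sigma2"))
})
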