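test_that("default discretization gives 76 components for any sigma0", {
  for (s0sq in c(1e-5, 0.25, 1, 7, 1e4))
    expect_identical(discretize_prior(s0_sq = s0sq)$B, 76L)
  # also invariant to the effective sample size carrying the scale
  expect_identical(discretize_prior(s0_sq = 1e-5, effective_n = 5e4)$B, 76L)
})

test_that("discretization respects its contracts", {
  pr <- discretize_prior(s0_sq = 0.5)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-12)
  expect_true(all(diff(pr$values) > 0))
  # a one-sigma span at unit step gives two bins
  pr2 <- discretize_prior(s0_sq = 1, step_fraction = 1,
                          tail_quantile = pnorm(-1))
  expect_identical(pr2$B, 2L)
  # degenerate prior collapses to a point mass, not an error
  pr0 <- discretize_prior(m0 = 0.3, s0_sq = 0)
  expect_identical(pr0$B, 1L)
  expect_equal(pr0$values, 0.3)
  expect_error(discretize_prior(s0_sq = 1, tail_quantile = 0.6),
               "tail_quantile")
})

test_that("tabulated_prior validates weights and ordering", {
  expect_error(tabulated_prior(c(1, 1), c(0.5, 0.5)), "increasing")
  expect_error(tabulated_prior(c(0, 1), c(-0.1, 1.1)), "nonnegative")
  expect_error(tabulated_prior(c(-1, 0), c(2, 2)), "renormalize")
  pr <- tabulated_prior(c(-1, 0), c(2, 2), renormalize = TRUE)
  expect_equal(pr$probs, c(0.5, 0.5))
  expect_error(tabulated_prior(c(-0.5, 0.5), c(0.5, 0.5),
                               scale = "delta_squared"), "nonnegative")
})

test_that("posterior weights follow Bayes' rule on the component grid", {
  # single component: posterior is certain whatever was observed
  one <- tabulated_prior(0.2, 1)
  expect_equal(posterior_weights(one, 5, zspec)$post_probs, 1)
  # equal-prior symmetric components at the density crossing point
  two <- tabulated_prior(c(0, 2), c(0.5, 0.5))
  w <- posterior_weights(two, 1, zspec)$post_probs
  expect_equal(w, c(0.5, 0.5), tolerance = 1e-12)
  # F family: weights proportional to central and noncentral densities;
  # frozen from an independent noncentral-F density evaluation
  fspec <- test_spec("f", n1 = 50, n2 = 50)   # N = 25
  prf <- tabulated_prior(c(0, 2.25 / 25), c(0.5, 0.5),
                         scale = "delta_squared")  # gammas 0 and 2.25
  wf <- posterior_weights(prf, 4, fspec)$post_probs
  expect_equal(wf, c(0.2396116, 0.7603884), tolerance = 1e-6)
  # invariance to rescaling all prior probabilities
  two_scaled <- tabulated_prior(c(0, 2), c(5, 5), renormalize = TRUE)
  expect_equal(posterior_weights(two_scaled, 1.7, zspec)$post_probs,
               posterior_weights(two, 1.7, zspec)$post_probs)
  # zero-prior components stay at zero posterior
  three <- tabulated_prior(c(-1, 0, 1), c(0.5, 0, 0.5))
  expect_equal(posterior_weights(three, 0.3, zspec)$post_probs[2], 0)
})

test_that("log-space normalization survives genome-wide tail observations", {
  pr <- discretize_prior(s0_sq = 1e-5, effective_n = 5e4)
  spec <- test_spec("normal", effective_n = 5e4)
  post <- posterior_weights(pr, p_to_stat(5e-9, spec), spec)
  expect_equal(sum(post$post_probs), 1, tolerance = 1e-10)
  expect_true(all(is.finite(post$post_probs)))
})

test_that("signed priors fold onto the delta^2 scale for chi-square/F", {
  pr <- tabulated_prior(c(-0.2, 0, 0.2), c(0.25, 0.5, 0.25))
  folded <- repint:::fold_prior(pr)
  expect_equal(folded$values, c(0, 0.04))
  expect_equal(folded$probs, c(0.5, 0.5))
  spec <- test_spec("chi_square", df1 = 1, effective_n = 100)
  post <- posterior_weights(pr, 3, spec)
  expect_equal(post$gammas, c(0, 4))   # N * delta^2
})

test_that("predictive CDF is a proper CDF for every family", {
  for (nm in names(all_specs)) {
    spec <- all_specs[[nm]]
    pr <- if (nm %in% c("normal", "student_t"))
      tabulated_prior(c(-0.3, 0, 0.25), c(0.2, 0.5, 0.3))
    else tabulated_prior(c(0, 0.05, 0.1), c(0.6, 0.3, 0.1),
                         scale = "delta_squared")
    post <- posterior_weights(pr, 1.5, spec)
    xs <- seq(if (nm %in% c("normal", "student_t")) -8 else 0, 30,
              length.out = 100)
    # far-tail noncentral t/F evaluations emit routine precision notes
    Fs <- suppressWarnings(predictive_cdf(post, xs))
    expect_true(all(diff(Fs) >= -1e-12), info = nm)
    expect_lt(suppressWarnings(
      predictive_cdf(post, if (nm %in% c("normal", "student_t"))
        -40 else 1e-12)), 1e-6)
    expect_gt(suppressWarnings(predictive_cdf(post, 1e4)), 1 - 1e-6)
  }
})

test_that("predictive CDF reduces to the central CDF for a null point mass", {
  post <- posterior_weights(tabulated_prior(0, 1), 0.4, zspec)
  xs <- c(-2, 0, 1, 2.5)
  expect_equal(predictive_cdf(post, xs), pnorm(xs), tolerance = 1e-12)
  # symmetry example: two components at gamma 0 and 2, equal weights, x = 1
  two <- tabulated_prior(c(0, 2), c(0.5, 0.5))
  expect_equal(predictive_cdf(posterior_weights(two, 1, zspec), 1), 0.5,
               tolerance = 1e-12)
})

test_that("predictive quantile inverts the CDF to 1e-10", {
  post <- posterior_weights(tabulated_prior(0, 1), 1, zspec)
  expect_equal(predictive_quantile(post, 0.9), 1.2815516, tolerance = 1e-6)
  for (nm in c("normal", "f")) {
    spec <- all_specs[[nm]]
    pr <- if (nm == "normal")
      discretize_prior(s0_sq = 0.5)
    else tabulated_prior(c(0, 0.04, 0.09), c(0.5, 0.3, 0.2),
                         scale = "delta_squared")
    post <- posterior_weights(pr, 2, spec)
    qs <- c(0.01, seq(0.05, 0.95, by = 0.15), 0.99)
    xs <- predictive_quantile(post, qs)
    expect_true(all(abs(predictive_cdf(post, xs) - qs) <= 1e-10), info = nm)
    expect_true(all(diff(xs) > 0), info = nm)
  }
  expect_error(predictive_quantile(post, 0), "strictly")
})

test_that("mixture interval matches the conjugate closed form at the default grid", {
  for (s0sq in c(0.25, 0.5, 1)) {
    for (z in c(-0.76, 0.5, 2.5)) {
      mi <- mixture_prediction_interval(stat = z,
                                        prior = discretize_prior(s0_sq = s0sq))
      ci <- conjugate_prediction_interval(stat = z,
                                          prior = conjugate_prior(sigma0_sq = s0sq))
      expect_lt(abs(mi$stat_lower - ci$stat_lower), 1e-3)
      expect_lt(abs(mi$stat_upper - ci$stat_upper), 1e-3)
    }
  }
})

test_that("mixture interval converges to the conjugate one as the grid refines", {
  z <- 1.3; s0sq <- 0.5
  ci <- conjugate_prediction_interval(stat = z,
                                      prior = conjugate_prior(sigma0_sq = s0sq))
  errs <- vapply(c(1 / 2, 1 / 4, 1 / 8, 1 / 16), function(sf) {
    mi <- mixture_prediction_interval(stat = z,
      prior = discretize_prior(s0_sq = s0sq, step_fraction = sf))
    max(abs(c(mi$stat_lower - ci$stat_lower, mi$stat_upper - ci$stat_upper)))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-12))   # monotone improvement
  expect_lt(errs[4], 5e-4)
})

test_that("mixture interval approaches the classical P-interval for huge priors", {
  # the grid step must keep resolving the unit-variance likelihood as the
  # prior spreads, so it is refined along with sigma0
  pr <- discretize_prior(s0_sq = 1e6, step_fraction = 0.25 / sqrt(1e6))
  mi <- mixture_prediction_interval(0.01, prior = pr)
  cl <- classical_p_interval(0.01)
  expect_lt(abs(mi$p_lower - cl$p_lower), 1e-2)
  expect_lt(abs(mi$p_upper - cl$p_upper), 1e-2)
})

test_that("point-mass null prior gives the central 80% band", {
  mi <- mixture_prediction_interval(stat = 0.7, prior = tabulated_prior(0, 1))
  expect_equal(mi$stat_lower, -1.2815516, tolerance = 1e-6)
  expect_equal(mi$stat_upper, 1.2815516, tolerance = 1e-6)
})

test_that("prior table files round-trip in both dialects", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "delta\tprob",
               "-0.1\t0.2", "0\t0.6", "0.1\t0.2"), tf)
  pr <- read_prior_table(tf)
  expect_s3_class(pr, "tabulated_prior")
  expect_equal(pr$values, c(-0.1, 0, 0.1))
  writeLines(c("# M=1000", "or\tcount", "1.2\t8", "1.5\t2"), tf)
  ot <- read_prior_table(tf)
  expect_s3_class(ot, "or_table")
  expect_equal(ot$M, 1000)
  # off-unit-mass probabilities renormalize with a warning
  writeLines(c("delta\tprob", "-0.1\t0.2", "0.1\t0.3"), tf)
  expect_warning(pr2 <- read_prior_table(tf), "renormalized")
  expect_equal(sum(pr2$probs), 1)
  writeLines(c("foo\tbar", "1\t2"), tf)
  expect_error(read_prior_table(tf), "unrecognized")
})
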