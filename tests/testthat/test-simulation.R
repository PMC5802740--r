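test_that("selection_rule validates and sets mode-specific defaults", {
  expect_equal(selection_rule("window", 0.045, 0.055)$sided, "two_sided")
  expect_equal(selection_rule("min_of_L", L = 10)$sided, "one_sided")
  expect_error(selection_rule("window", 0.5, 0.1), "p_low < p_high")
  expect_error(selection_rule("min_of_L", L = 0), "positive integer")
})

test_that("unselected draws have the marginal convolution variance", {
  set.seed(31)
  d <- draw_pairs(1e5, 0.7)
  expect_lt(abs(var(d$z_obt) - 1.7), 3 * 1.7 * sqrt(2 / 1e5))
  expect_lt(abs(mean(d$z_obt)), 3 * sqrt(1.7 / 1e5))
  # z_rep has the same marginal but is conditionally independent given gamma
  expect_lt(abs(var(d$z_rep) - 1.7), 3 * 1.7 * sqrt(2 / 1e5))
})

test_that("threshold selection honours its P-value contract", {
  set.seed(32)
  d1 <- draw_pairs(2000, 0.25,
                   selection_rule("threshold", p_high = 0.05,
                                  sided = "one_sided"))
  expect_true(all(1 - pnorm(d1$z_obt) < 0.05))
  d2 <- draw_pairs(2000, 0.25,
                   selection_rule("threshold", p_high = 0.05))
  expect_true(all(2 * (1 - pnorm(abs(d2$z_obt))) < 0.05))
  d3 <- draw_pairs(2000, 0.25,
                   selection_rule("window", p_low = 0.045, p_high = 0.055))
  p2 <- 2 * (1 - pnorm(abs(d3$z_obt)))
  expect_true(all(p2 >= 0.045 & p2 <= 0.055))
})

test_that("the exact conditional sampler equals rejection sampling in law", {
  set.seed(33)
  sel <- selection_rule("window", p_low = 0.02, p_high = 0.1)
  a <- draw_pairs(1e5, 0.5, sel)
  b <- repint:::rejection_draw_pairs(1e5, 0.5, sel)
  ks_obt <- suppressWarnings(ks.test(a$z_obt, b$z_obt))
  ks_rep <- suppressWarnings(ks.test(a$z_rep, b$z_rep))
  expect_gt(ks_obt$p.value, 1e-3)
  expect_gt(ks_rep$p.value, 1e-3)
})

test_that("min_of_L with L = 1 is distributionally plain sampling", {
  set.seed(34)
  a <- draw_pairs(5e4, 0.5, selection_rule("min_of_L", L = 1))
  b <- draw_pairs(5e4, 0.5)
  expect_gt(suppressWarnings(ks.test(a$z_obt, b$z_obt))$p.value, 1e-3)
})

test_that("window selection around P = 0.05 inflates the observed statistic", {
  set.seed(35)
  none <- draw_pairs(2e4, 0.25)
  win <- draw_pairs(2e4, 0.25,
                    selection_rule("window", p_low = 0.045, p_high = 0.055))
  expect_gt(mean(abs(win$z_obt)), mean(abs(none$z_obt)))
})

test_that("coverage is seed-deterministic and nominal without selection", {
  cfg <- sim_config(0.25, method = "p_interval", reps = 20000, seed = 77)
  est1 <- simulate_coverage(cfg)
  est2 <- simulate_coverage(cfg)
  expect_identical(est1$hits, est2$hits)
  expect_lt(abs(est1$proportion - 0.8), 3 * est1$mc_se)
  expect_equal(est1$mc_se,
               sqrt(est1$proportion * (1 - est1$proportion) / est1$reps))
})

test_that("matched-prior Bayesian coverage is level-invariant under selection", {
  rules <- list(selection_rule("none"),
                selection_rule("threshold", p_high = 0.05),
                selection_rule("window", p_low = 0.045, p_high = 0.055),
                selection_rule("min_of_L", L = 10))
  for (i in seq_along(rules)) {
    est <- simulate_coverage(sim_config(0.5, method = "conjugate",
                                        reps = 20000, seed = 100 + i,
                                        selection = rules[[i]]))
    expect_lt(abs(est$proportion - 0.8), 3 * est$mc_se)
  }
})

test_that("P-interval coverage degrades as the threshold tightens", {
  props <- vapply(c(0.05, 0.01, 0.001), function(th) {
    simulate_coverage(sim_config(0.25, method = "p_interval", reps = 20000,
                                 seed = round(1000 * th),
                                 selection = selection_rule("threshold",
                                                            p_high = th))
    )$proportion
  }, numeric(1))
  expect_true(all(diff(props) < 0))
  expect_lt(props[3], 0.25)
})

test_that("mis-specified analysis variance shifts coverage in the safe direction", {
  sel <- selection_rule("min_of_L", L = 10)
  under <- simulate_coverage(sim_config(0.25, analysis_sigma0_sq = 0.125,
                                        method = "conjugate", reps = 20000,
                                        seed = 41, selection = sel))
  over <- simulate_coverage(sim_config(0.25, analysis_sigma0_sq = 0.5,
                                       method = "conjugate", reps = 20000,
                                       seed = 42, selection = sel))
  expect_lt(under$proportion, 0.8)
  expect_gt(over$proportion, under$proportion)
})

test_that("Bonferroni-adjusted P-interval levels restore long-run coverage", {
  L <- 10
  est <- simulate_coverage(sim_config(0.25, method = "p_interval",
                                      level = 1 - 0.2 / L, reps = 20000,
                                      seed = 43,
                                      selection = selection_rule("min_of_L",
                                                                 L = L)))
  # the union bound guarantees at least the unadjusted nominal level
  expect_gt(est$proportion, 0.8 - 3 * est$mc_se)
})

test_that("replication-pair tables are self-consistent", {
  cfg <- sim_config(1, method = "p_interval", level = 0.8, reps = 100,
                    seed = 52)
  tab <- simulate_replication_pairs(cfg, 1000)
  expect_identical(nrow(tab), 1000L)
  expect_equal(tab$covered,
               tab$z_rep >= tab$stat_lower & tab$z_rep <= tab$stat_upper)
  # hit frequency near the nominal level
  expect_lt(abs(mean(tab$covered) - 0.8), 4 * sqrt(0.8 * 0.2 / 1000))
  # coverage agrees with simulate_coverage under the same conditions
  est <- simulate_coverage(sim_config(1, method = "p_interval", level = 0.8,
                                      reps = 20000, seed = 53))
  expect_lt(abs(mean(tab$covered) - est$proportion),
            4 * sqrt(0.8 * 0.2 / 1000))
  # the mixture route produces the same flags through its predictive CDF
  cfgm <- sim_config(0.5, method = "mixture", reps = 500, seed = 54)
  tabm <- simulate_replication_pairs(cfgm, 100)
  covm <- repint:::interval_covers("mixture", tabm$z_obt, tabm$z_rep,
                                   0.8, 0.5)
  expect_equal(tabm$covered, covm)
})

test_that("simulation configs round-trip through YAML", {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sigma0_sq = 0.25, method = "p_interval",
                        level = 0.8, reps = 500, seed = 9,
                        selection = list(mode = "window", p_low = 0.045,
                                         p_high = 0.055)), tf)
  cfg <- read_sim_config(tf)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$selection$mode, "window")
  expect_equal(cfg$analysis_sigma0_sq, 0.25)
  cfg2 <- read_sim_config(tf, reps = 100, seed = 1)
  expect_identical(cfg2$reps, 100L)
  expect_identical(cfg2$seed, 1)
})
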