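test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(31)
  g0 <- draw_genotypes(10, 10, 0)
  expect_true(all(g0$calls == 0))

  n <- 1e5
  g <- draw_genotypes(n, n, 0.2)
  fem <- g$sex == "female"
  het <- mean(g$calls[fem] == 1)
  p_het <- 2 * 0.2 * 0.8
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / n))
  expect_lt(abs(mean(g$calls[!fem]) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_true(all(g$calls[!fem] <= 1))
})

test_that("skewing draws live on [-1/2, 1/2] with the right moments", {
  set.seed(32)
  n <- 1e5
  u1 <- draw_skewness("raised_cosine", n)
  v1 <- 0.25 * (1 / 3 - 2 / pi^2)
  expect_true(all(abs(u1) <= 0.5))
  expect_lt(abs(mean(u1)), 3 * sqrt(v1 / n))
  expect_lt(abs(var(u1) - v1), 4 * v1 / sqrt(n))

  # Beta(2,2) scenario: support [0, 1], mean 1/2, variance 1/20
  u2 <- draw_skewness("beta22", n)
  expect_true(all(u2 >= 0 & u2 <= 1))
  expect_lt(abs(mean(u2) - 0.5), 3 * sqrt(0.05 / n))
  expect_lt(abs(var(u2) - 0.05), 4 * 0.05 / sqrt(n))

  u3 <- draw_skewness("truncated_normal", n)
  expect_true(all(abs(u3) <= 0.5))
  expect_lt(abs(mean(u3)), 3 * 0.18 / sqrt(n))
  expect_lt(sd(u3), 0.18)          # truncation shrinks the spread
  # against the truncated-normal second moment by quadrature
  v3 <- integrate(function(x) x^2 * skew_dist("truncated_normal")$dfun(x),
                  -0.5, 0.5, rel.tol = 1e-10)$value
  expect_lt(abs(var(u3) - v3), 4 * v3 / sqrt(n))

  expect_error(draw_skewness("cauchy", 5))
})

test_that("event times are exponential with the additive rate", {
  set.seed(33)
  n <- 1e5
  cfg <- scenario_config(p_A = 0.2, beta = -2.5)
  sex_m <- factor(rep("male", n), levels = c("female", "male"))
  sex_f <- factor(rep("female", n), levels = c("female", "male"))
  t_m <- draw_event_times(rep(0, n), sex_m, rep(0, n), cfg)
  expect_lt(abs(mean(t_m) - 1 / 5), 3 * (1 / 5) / sqrt(n))
  t_f <- draw_event_times(rep(0, n), sex_f, rep(0, n), cfg)
  expect_lt(abs(mean(t_f) - 1 / 6), 3 * (1 / 6) / sqrt(n))
  t_mz <- draw_event_times(rep(1, n), sex_m, rep(0, n), cfg)
  expect_lt(abs(mean(t_mz) - 1 / 2.5), 3 * (1 / 2.5) / sqrt(n))

  bad <- scenario_config(p_A = 0.2, beta = -2.5, lambda0 = 5)
  bad$beta <- -5.5   # bypass the constructor check on purpose
  expect_error(draw_event_times(1, sex_m[1], 0, bad), "non-positive")
  expect_error(scenario_config(p_A = 0.2, beta = -5.5), "non-positive")
})

test_that("administrative censoring is calibrated to its target", {
  cfg0 <- scenario_config(censor_frac = 0)
  expect_identical(calibrate_censor_time(cfg0), Inf)

  # beta = 0: genotype drops out, the mixture is sex-only
  cfg <- scenario_config(p_A = 0.2, beta = 0, censor_frac = 0.2)
  cc <- calibrate_censor_time(cfg)
  expect_equal(0.5 * exp(-5 * cc) + 0.5 * exp(-6 * cc), 0.2,
               tolerance = 1e-9)
  expect_equal(cc, 0.295, tolerance = 0.01)

  # realized censoring matches the target under the full model
  set.seed(34)
  cfg2 <- scenario_config(p_A = 0.3, beta = -2.5, censor_frac = 0.4)
  ct <- calibrate_censor_time(cfg2)
  cens <- replicate(50, {
    g <- draw_genotypes(cfg2$n_female, cfg2$n_male, cfg2$p_A)
    z <- code_genotype(g$calls, g$sex, "XCI")
    u <- draw_skewness(cfg2$skew, length(z))
    tt <- draw_event_times(z, g$sex, u, cfg2)
    mean(tt > ct)
  })
  n_tot <- 50 * 400
  expect_lt(abs(mean(cens) - 0.4), 3 * sqrt(0.4 * 0.6 / n_tot))
})

test_that("replications are deterministic given the seed", {
  cfg <- scenario_config(p_A = 0.2, beta = -2, censor_frac = 0.2,
                         n_reps = 5, seed = 99)
  ct <- calibrate_censor_time(cfg)
  set.seed(123); p1 <- run_replication(cfg, ct)
  set.seed(123); p2 <- run_replication(cfg, ct)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  r1 <- estimate_rejection_rates(cfg)
  r2 <- estimate_rejection_rates(cfg)
  expect_identical(r1, r2)
})

test_that("rejection-rate boundary cases behave", {
  cfg <- scenario_config(p_A = 0.2, beta = -2.5, alpha = 1,
                         n_reps = 10, seed = 3)
  rr <- estimate_rejection_rates(cfg)
  expect_true(all(rr$rejection_rate == 1))
  expect_equal(rr$mc_se, rep(0, 6))
})

test_that("null p-values are approximately uniform", {
  # sanity check, not a calibration gate: 300 null replicates
  cfg <- scenario_config(p_A = 0.2, beta = 0, n_reps = 300, seed = 41)
  ct <- calibrate_censor_time(cfg)
  seeds <- xcisurv:::replication_seeds(cfg$seed, cfg$n_reps)
  p <- vapply(seq_len(cfg$n_reps), function(r) {
    set.seed(seeds[r])
    run_replication(cfg, ct)[["score_like_strat"]]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("grid reproduction is seed-stable and correctly laid out", {
  cells <- data.frame(p_A = 0.2, beta = c(0, -2.5), censor_frac = 0)
  g1 <- reproduce_tables(tables = 1, n_reps = 30, seed = 17,
                         cells = cells)
  g2 <- reproduce_tables(tables = 1, n_reps = 30, seed = 17,
                         cells = cells)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 2 * 6)   # two cells x three tests x two modes
  expect_true(all(g1$skew_dist == "raised_cosine"))
  expect_true(all(g1$rejection_rate >= 0 & g1$rejection_rate <= 100))
  # TSV output round-trips
  f <- withr::local_tempfile(fileext = ".tsv")
  reproduce_tables(tables = 1, n_reps = 30, seed = 17, cells = cells,
                   file = f)
  back <- read.delim(f)
  expect_equal(back$rejection_rate, g1$rejection_rate)
})
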