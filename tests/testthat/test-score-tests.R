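toy_data <- function() {
  d <- survival_dataset(1:4, rep(1, 4), c("F", "F", "M", "M"))
  list(data = d, z = code_genotype(c(2, 0, 1, 0), d$sex, "XCI"))
}

test_that("event table reports risk-set means per event time", {
  toy <- toy_data()
  et <- event_table(toy$data, toy$z)
  expect_equal(et$time, 1:4)
  expect_equal(et$n_risk, 4:1)
  expect_equal(et$zbar, c(0.5, 1 / 3, 0.5, 0))

  # all censored: empty table
  dc <- survival_dataset(1:3, rep(0, 3), c("F", "M", "M"))
  expect_equal(nrow(event_table(dc, c(0, 1, 0))), 0)

  # single subject
  d1 <- survival_dataset(5, 1, "F")
  et1 <- event_table(d1, 0.5)
  expect_equal(et1$n_risk, 1L)
  expect_equal(et1$zbar, 0.5)

  # tied event and censoring: censored subject stays in the risk set
  dt <- survival_dataset(c(1, 1, 2), c(1, 0, 1), c("F", "M", "M"))
  ett <- event_table(dt, c(1, 0, 0))
  expect_equal(ett$n_risk, c(3L, 1L))
})

test_that("score-like and Cox statistics match the hand-worked example", {
  toy <- toy_data()
  ts <- score_like_test(toy$data, toy$z)
  expect_equal(ts$U, 2 / 3)
  expect_equal(ts$variance, 1 / 4 + 1 / 9 + 1 / 4)
  expect_equal(ts$statistic, (2 / 3)^2 / (1 / 4 + 1 / 9 + 1 / 4))
  expect_equal(ts$p.value,
               pchisq(ts$statistic, 1, lower.tail = FALSE))
  expect_equal(ts$flag, "ok")

  tc <- cox_score_test(toy$data, toy$z)
  expect_equal(tc$U, ts$U)                       # same numerator
  expect_equal(tc$variance, 1 / 4 + 2 / 9 + 1 / 4 + 0)
  expect_equal(tc$statistic, (2 / 3)^2 / (1 / 4 + 2 / 9 + 1 / 4))
  # the two variance estimators order the statistics on this instance
  expect_lt(tc$statistic, ts$statistic)
})

test_that("degenerate inputs are flagged, not silently scored", {
  d <- survival_dataset(1:3, c(1, 1, 0), c("F", "M", "M"))
  r <- score_like_test(d, c(0.5, 0.5, 0.5))
  expect_equal(r$flag, "degenerate_no_variation")
  expect_true(is.na(r$p.value) && is.na(r$statistic))
  expect_equal(r$U, 0)

  dn <- survival_dataset(1:3, c(0, 0, 0), c("F", "M", "M"))
  rn <- score_like_test(dn, c(0, 0.5, 1))
  expect_equal(rn$flag, "no_events")
  expect_true(is.na(rn$p.value))

  expect_equal(cox_score_test(d, c(1, 1, 1))$flag,
               "degenerate_no_variation")

  # missing genotypes are dropped and counted
  r2 <- score_like_test(d, c(NA, 0, 1))
  expect_equal(r2$n_dropped, 1L)
  expect_equal(r2$n, 2L)
  expect_error(score_like_test(d, c(NA, NA, NA)), "no subjects")
})

test_that("U and B match brute-force risk-set enumeration (n <= 8)", {
  set.seed(7)
  for (i in 1:1000) {
    ds <- random_small_dataset(sample(1:8, 1))
    bf <- brute_force_score(ds$data$time, ds$data$event, ds$z)
    ts <- score_like_test(ds$data, ds$z)
    tc <- cox_score_test(ds$data, ds$z)
    expect_equal(ts$U, bf$U)
    expect_equal(ts$variance, bf$B)
    expect_equal(tc$variance, bf$I)
  }
})

test_that("Cox score statistic agrees with an established fitter", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    ds <- random_small_dataset(n)
    tc <- cox_score_test(ds$data, ds$z)
    if (tc$flag != "ok") next
    fit <- survival::coxph(
      survival::Surv(ds$data$time, ds$data$event) ~ as.numeric(ds$z),
      ties = "breslow", init = 0,
      control = survival::coxph.control(iter.max = 0))
    expect_equal(tc$statistic, unname(fit$score), tolerance = 1e-8)
  }
})

test_that("statistics are rank-invariant and allele-swap symmetric", {
  set.seed(5)
  for (i in 1:50) {
    ds <- random_small_dataset(sample(5:25, 1))
    t0 <- score_like_test(ds$data, ds$z)
    # strictly increasing time transform changes nothing
    d2 <- survival_dataset(exp(ds$data$time / 2), ds$data$event,
                           ds$data$sex)
    t2 <- score_like_test(d2, ds$z)
    expect_equal(t2$U, t0$U)
    expect_equal(t2$variance, t0$variance)
    # allele swap: z -> 1 - z negates U, keeps S
    t3 <- score_like_test(ds$data, 1 - as.numeric(ds$z))
    expect_equal(t3$U, -t0$U)
    expect_equal(t3$variance, t0$variance)
    # numerator equality across the two tests
    expect_equal(cox_score_test(ds$data, ds$z)$U, t0$U)
  }
})

test_that("stratified tests sum the per-stratum score and variance", {
  toy <- toy_data()
  # one stratum: identical to the unstratified test
  t1 <- stratified_test(toy$data, toy$z, rep("all", 4), "score_like")
  t0 <- score_like_test(toy$data, toy$z)
  expect_equal(t1$U, t0$U)
  expect_equal(t1$statistic, t0$statistic)

  # two copies of the toy as two strata: U and B double, S doubles
  d2 <- survival_dataset(rep(1:4, 2), rep(1, 8),
                         rep(c("F", "F", "M", "M"), 2))
  z2 <- rep(as.numeric(toy$z), 2)
  t2 <- stratified_test(d2, z2, rep(1:2, each = 4), "score_like")
  expect_equal(t2$U, 2 * t0$U)
  expect_equal(t2$variance, 2 * t0$variance)
  expect_equal(t2$statistic, 2 * t0$statistic)

  # cox kind dispatches to the information variance
  t2c <- stratified_test(d2, z2, rep(1:2, each = 4), "cox")
  expect_equal(t2c$variance, 2 * cox_score_test(toy$data, toy$z)$variance)

  # a stratum with no events contributes nothing
  d3 <- survival_dataset(c(1:4, 9, 10), c(rep(1, 4), 0, 0),
                         c("F", "F", "M", "M", "F", "M"))
  t3 <- stratified_test(d3, c(as.numeric(toy$z), 1, 0),
                        c(rep("a", 4), "b", "b"), "score_like")
  expect_equal(t3$statistic, t0$statistic)

  # all strata degenerate
  t4 <- stratified_test(toy$data, rep(0.5, 4), rep(1:2, 2), "score_like")
  expect_equal(t4$flag, "degenerate_no_variation")

  expect_error(stratified_test(toy$data, toy$z, c(1, 2, NA, 1),
                               "score_like"), "stratum")
})
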