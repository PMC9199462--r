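test_that("conditional survival follows the additive-hazard form", {
  sp <- hazard_spec(beta = -2.5, lambda0 = 5)
  expect_equal(conditional_survival(0, 1, 0, sp), 1)
  # direct substitution: exp(-(5*0.2 - 2.5*0.2)) = exp(-0.5)
  expect_equal(conditional_survival(0.2, 1, 0, sp), exp(-0.5))
  # beta = 0: genotype and skewing drop out
  sp0 <- hazard_spec(0, 5)
  for (z in c(0, 0.5, 1))
    expect_equal(conditional_survival(0.3, z, 0.2, sp0), exp(-5 * 0.3))
  # u only acts on heterozygotes
  expect_equal(conditional_survival(0.2, 1, 0.4, sp),
               conditional_survival(0.2, 1, -0.4, sp))
  expect_error(conditional_survival(0.2, 1, 0.7, sp), "1/2")
  expect_error(hazard_spec(beta = -6, lambda0 = 5), "negative")
})

test_that("marginal survival equals the quadrature marginalization", {
  # closed form (raised cosine) on a (beta, t) grid
  for (beta in c(-2.5, -2, -1, 0.8)) {
    sp <- hazard_spec(beta, 5)
    t <- c(1e-9, 0.05, 0.1, 0.3, 0.6, 1)
    expect_equal(marginal_survival(t, 0.5, sp),
                 quadrature_marginal_survival(t, sp),
                 tolerance = 1e-8)
    # homozygotes: marginal = conditional
    expect_equal(marginal_survival(t, 1, sp),
                 conditional_survival(t, 1, 0, sp))
    expect_equal(marginal_survival(t, 0, sp), exp(-5 * t))
  }
  # continuity at t = 0
  sp <- hazard_spec(-2, 5)
  expect_equal(marginal_survival(0, 0.5, sp), 1)
  # MGF identity: S(t | 1/2) = exp(-lambda0 t - beta t / 2) M_U(-beta t)
  t <- 0.3
  expect_equal(marginal_survival(t, 0.5, sp),
               exp(-5 * t + 2 * t / 2) * xcisurv:::rcosine_mgf(2 * t))
})

test_that("non-raised-cosine skewing laws are marginalized numerically", {
  for (nm in c("beta22", "truncated_normal")) {
    sp <- hazard_spec(-2, 5, skew = skew_dist(nm))
    t <- c(0.05, 0.2, 0.5)
    expect_equal(marginal_survival(t, 0.5, sp),
                 quadrature_marginal_survival(t, sp),
                 tolerance = 1e-7)
  }
})

test_that("marginal hazard is the derivative of -log marginal survival", {
  for (beta in c(-2.5, -1, 1.5)) {
    sp <- hazard_spec(beta, 5)
    for (t in c(0.02, 0.1, 0.4, 1)) {
      eps <- 1e-6
      num <- -(log(marginal_survival(t + eps, 0.5, sp)) -
                 log(marginal_survival(t - eps, 0.5, sp))) / (2 * eps)
      expect_equal(marginal_hazard(t, 0.5, sp), num, tolerance = 1e-6)
    }
  }
  # t -> 0+ limit is lambda0 + beta/2 (E[U] = 0); exact at t = 0
  sp <- hazard_spec(-2, 5)
  expect_equal(marginal_hazard(0, 0.5, sp), 4)
  expect_equal(marginal_hazard(1e-12, 0.5, sp), 4, tolerance = 1e-9)
  # beta = 0 and homozygotes reduce to the baseline forms
  expect_equal(marginal_hazard(c(0.1, 2), 0.5, hazard_spec(0, 5)),
               c(5, 5))
  expect_equal(marginal_hazard(0.3, 0, sp), 5)
  expect_equal(marginal_hazard(0.3, 1, sp), 3)
  # quadrature path for a non-closed-form skewing law
  spb <- hazard_spec(-2, 5, skew = skew_dist("beta22"))
  eps <- 1e-6
  num <- -(log(marginal_survival(0.3 + eps, 0.5, spb)) -
             log(marginal_survival(0.3 - eps, 0.5, spb))) / (2 * eps)
  expect_equal(marginal_hazard(0.3, 0.5, spb), num, tolerance = 1e-6)
})

test_that("marginal hazard integrates back to -log marginal survival", {
  sp <- hazard_spec(-2.2, 5)
  grid <- seq(0, 0.8, length.out = 4001)   # t = 0 uses the analytic limit
  h <- marginal_hazard(grid, 0.5, sp)
  cum <- cumsum((h[-1] + h[-length(h)]) / 2 * diff(grid))
  target <- -log(marginal_survival(grid[-1], 0.5, sp))
  expect_lt(max(abs(cum / target - 1)), 1e-4)
})

test_that("baseline cumulative-hazard estimator reduces to Nelson-Aalen", {
  # hand value: four events, risk sets 4, 3, 2, 1
  d <- survival_dataset(1:4, rep(1, 4), c("F", "F", "M", "M"))
  z <- code_genotype(c(2, 0, 1, 0), d$sex, "XCI")
  ch <- estimate_baseline_cumhaz(d, z, beta = 0)
  expect_equal(ch$fn(4), 1 / 4 + 1 / 3 + 1 / 2 + 1)
  expect_equal(ch$fn(0), 0)
  expect_equal(ch$fn(2.5), 1 / 4 + 1 / 3)   # constant between events

  # no events: identically zero
  d0 <- survival_dataset(c(1, 2), c(0, 0), c("F", "M"))
  ch0 <- estimate_baseline_cumhaz(d0, c(0, 1), beta = 0)
  expect_equal(ch0$fn(c(0, 1.5, 10)), c(0, 0, 0))

  # equality with Nelson-Aalen on random censored datasets
  set.seed(2024)
  for (i in 1:100) {
    ds <- random_small_dataset(sample(3:12, 1))
    ch <- estimate_baseline_cumhaz(ds$data, ds$z, beta = 0)
    tt <- ds$data$time
    na_hand <- vapply(ch$knots, function(v)
      sum(vapply(unique(tt[ds$data$event == 1 & tt <= v]), function(s)
        sum(tt == s & ds$data$event == 1) / sum(tt >= s), numeric(1))),
      numeric(1))
    expect_equal(ch$cumhaz, na_hand)
  }
})

test_that("baseline estimator applies the beta correction term", {
  # no heterozygous subjects: correction is -beta * integral of zbar
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 0), c("F", "M", "F"))
  z <- code_genotype(c(2, 0, 0), d$sex, "XCI")   # z = 1, 0, 0
  beta <- -0.4
  ch <- estimate_baseline_cumhaz(d, z, beta = beta)
  # zbar is 1/3 on (0,1], 0 afterwards; jumps 1/3 at t=1, 1/2 at t=2
  expect_equal(ch$fn(1), 1 / 3 - beta * (1 / 3) * 1)
  expect_equal(ch$fn(3), 1 / 3 + 1 / 2 - beta * (1 / 3) * 1)

  # with heterozygotes, the correction integrates the marginalization
  # bracket; term-by-term oracle via numeric integration
  d2 <- survival_dataset(c(0.5, 1.2, 2), c(1, 1, 1), c("F", "F", "M"))
  z2 <- code_genotype(c(1, 2, 0), d2$sex, "XCI")  # 0.5, 1, 0
  beta <- -1.1
  ch2 <- estimate_baseline_cumhaz(d2, z2, beta = beta)
  sp <- hazard_spec(beta, 5)
  bracket <- function(s) marginal_hazard(s, 0.5, sp) - 5 - beta / 2
  oracle <- function(tt) {
    jumps <- sum(1 / c(3, 2, 1)[which(c(0.5, 1.2, 2) <= tt)])
    zbar_f <- function(s) mean(c(0.5, 1, 0)[c(0.5, 1.2, 2) >= s])
    hbar_f <- function(s) mean(c(1, 0, 0)[c(0.5, 1.2, 2) >= s])
    corr <- integrate(function(s)
      vapply(s, function(ss) beta * zbar_f(ss) +
               hbar_f(ss) * bracket(ss), numeric(1)),
      0, tt, rel.tol = 1e-10, subdivisions = 400L)$value
    jumps - corr
  }
  for (tt in c(0.3, 0.5, 1, 1.2, 1.7, 2))
    expect_equal(ch2$fn(tt), oracle(tt), tolerance = 1e-7)
})
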