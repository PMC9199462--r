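#' Simulation scenario configuration
#'
#' Describes one cell of the size/power study: genotypes are drawn under
#' Hardy-Weinberg proportions at a pseudo minor-allele frequency `p_A`
#' (two independent Bernoulli draws per female, one per male), the
#' skewing variable of heterozygous females follows `skew`, and event
#' times are exponential with the additive rate
#' `lambda0 * (eta if female) + beta * (z + u * 1(z = 1/2))`.
#' Administrative (type I) censoring cuts all follow-up at a fixed time
#' calibrated so the expected censored fraction equals `censor_frac`.
#'
#' The defaults mirror the study design used for the package's
#' reference tables: 400 subjects (200 females, 200 males), baseline
#' rate 5 with a female multiplier of 1.2, nominal level 0.05, 1000
#' replications.
#'
#' @param p_A pseudo minor-allele frequency in (0, 1).
#' @param beta genetic effect (0 for size; the power grid uses
#'   -1.5 ... -2.5).
#' @param censor_frac target censored fraction in `[0, 1)`; 0 disables
#'   censoring.
#' @param skew skewing distribution: a name accepted by [skew_dist()]
#'   or a `skew_dist` object.
#' @param n_female,n_male sample sizes.
#' @param lambda0 male baseline hazard rate.
#' @param eta female baseline multiplier.
#' @param alpha nominal test level.
#' @param n_reps Monte-Carlo replications.
#' @param seed master seed; each replication runs on its own derived
#'   substream so cells are reproducible and parallelizable.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(p_A = 0.2, beta = 0, censor_frac = 0,
                            skew = "raised_cosine",
                            n_female = 200L, n_male = 200L,
                            lambda0 = 5, eta = 1.2, alpha = 0.05,
                            n_reps = 1000L, seed = 1L) {
  if (p_A <= 0 || p_A >= 1) stop("'p_A' must lie in (0, 1)")
  if (censor_frac < 0 || censor_frac >= 1)
    stop("'censor_frac' must lie in [0, 1)")
  if (!inherits(skew, "skew_dist")) skew <- skew_dist(skew)
  # minimal individual rate over genotypes and the skewing support:
  # homozygotes/males span w in [0, 1]; heterozygous females span
  # w = 1/2 + u over the support of U (baseline lambda0 * eta)
  w_max_het <- 0.5 + skew$support[2]
  min_rate <- min(lambda0 + min(0, beta),
                  lambda0 * eta + min(0, beta * w_max_het))
  if (min_rate <= 0)
    stop("non-positive hazard rate: baseline + beta * w <= 0 for some ",
         "admissible coding value w")
  structure(list(p_A = p_A, beta = beta, censor_frac = censor_frac,
                 skew = skew, n_female = as.integer(n_female),
                 n_male = as.integer(n_male), lambda0 = lambda0,
                 eta = eta, alpha = alpha, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Draw Hardy-Weinberg genotypes for an X-linked locus
#'
#' Female alternative-allele counts are the sum of two independent
#' Bernoulli(`p_A`) draws; male counts a single Bernoulli(`p_A`).
#' Uses the current RNG state.
#'
#' @param n_female,n_male sample sizes.
#' @param p_A alternative-allele frequency in (0, 1).
#' @return A list with `calls` (counts) and `sex` (factor), females
#'   first.
#' @export
draw_genotypes <- function(n_female, n_male, p_A) {
  if (p_A < 0 || p_A > 1) stop("'p_A' must lie in [0, 1]")
  calls <- c(rbinom(n_female, 2L, p_A), rbinom(n_male, 1L, p_A))
  sex <- factor(rep(c("female", "male"), c(n_female, n_male)),
                levels = c("female", "male"))
  list(calls = calls, sex = sex)
}

#' Draw skewing values
#'
#' @param dist a [skew_dist()] object or name.
#' @param n number of draws.
#' @return Numeric vector in `[-1/2, 1/2]`.
#' @export
draw_skewness <- function(dist, n) {
  if (!inherits(dist, "skew_dist")) dist <- skew_dist(dist)
  dist$rfun(n)
}

#' Draw additive-hazard event times
#'
#' Constant hazards make the conditional event times exponential with
#' rate `lambda0 * (eta if female) + beta * (z + u * 1(z = 1/2))`.
#'
#' @param z XCI-coded genotype values.
#' @param sex sex factor.
#' @param u skewing values (used only where `z = 1/2`).
#' @param config a [scenario_config()].
#' @return Event times.
#' @export
draw_event_times <- function(z, sex, u, config) {
  base <- ifelse(sex == "female", config$lambda0 * config$eta,
                 config$lambda0)
  rate <- base + config$beta * (z + u * (z == 0.5))
  if (any(rate <= 0)) stop("non-positive individual hazard rate")
  rexp(length(rate), rate)
}

# Population marginal survival at time t under a scenario: mixture over
# sex (1:1 unless sizes differ), HWE genotype frequencies, and the
# skewing law (via its MGF) for heterozygous females.
population_survival <- function(t, config) {
  p <- config$p_A; b <- config$beta
  lf <- config$lambda0 * config$eta; lm <- config$lambda0
  wf <- config$n_female / (config$n_female + config$n_male)
  sm <- (1 - p) * exp(-lm * t) + p * exp(-(lm + b) * t)
  sf <- (1 - p)^2 * exp(-lf * t) + p^2 * exp(-(lf + b) * t) +
    2 * p * (1 - p) * exp(-(lf + b / 2) * t) * config$skew$mgf(-b * t)
  wf * sf + (1 - wf) * sm
}

#' Calibrate the administrative censoring time
#'
#' Solves for the fixed cut-off `c` at which the population marginal
#' survival equals the target censored fraction, so that censoring all
#' follow-up at `c` yields the desired expected proportion of censored
#' subjects. Returns `Inf` when `censor_frac = 0`.
#'
#' @param config a [scenario_config()].
#' @return The censoring time (possibly `Inf`).
#' @export
calibrate_censor_time <- function(config) {
  f <- config$censor_frac
  if (f == 0) return(Inf)
  upper <- 1
  while (population_survival(upper, config) > f) upper <- upper * 2
  uniroot(function(t) population_survival(t, config) - f,
          lower = 0, upper = upper, tol = 1e-12)$root
}

# One simulated dataset under a scenario (current RNG state);
# censor_time precomputed by the caller.
simulate_scenario_data <- function(config, censor_time = Inf) {
  g <- draw_genotypes(config$n_female, config$n_male, config$p_A)
  z <- code_genotype(g$calls, g$sex, "XCI")
  u <- numeric(length(z))
  het <- z == 0.5
  u[het] <- draw_skewness(config$skew, sum(het))
  tt <- draw_event_times(z, g$sex, u, config)
  time <- pmin(tt, censor_time)
  event <- as.integer(tt <= censor_time)
  list(data = survival_dataset(time, event, g$sex),
       calls = g$calls, z_xci = z,
       z_xce = code_genotype(g$calls, g$sex, "XCE"))
}

#' Run one simulation replication
#'
#' Simulates a single dataset under `config` (using the current RNG
#' state) and applies all three tests, each sex-stratified and
#' unstratified.
#'
#' @param config a [scenario_config()].
#' @param censor_time administrative censoring time; defaults to the
#'   calibrated value (precompute it when running many replications).
#' @return A named numeric vector of six p-values
#'   (`score_like`, `cox_xci`, `cox_xce` crossed with `_strat` /
#'   `_unstrat`); degenerate tests give `NA`.
#' @export
run_replication <- function(config,
                            censor_time = calibrate_censor_time(config)) {
  sim <- simulate_scenario_data(config, censor_time)
  d <- sim$data
  s <- d$sex
  c(score_like_strat   = score_like_test(d, sim$z_xci, strata = s)$p.value,
    score_like_unstrat = score_like_test(d, sim$z_xci)$p.value,
    cox_xci_strat      = cox_score_test(d, sim$z_xci, strata = s)$p.value,
    cox_xci_unstrat    = cox_score_test(d, sim$z_xci)$p.value,
    cox_xce_strat      = cox_score_test(d, sim$z_xce, strata = s)$p.value,
    cox_xce_unstrat    = cox_score_test(d, sim$z_xce)$p.value)
}

# Independent substream seeds for the replications of one cell,
# derived reproducibly from the master seed.
replication_seeds <- function(seed, n_reps) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n_reps)
}

#' Empirical size or power of the tests in one scenario
#'
#' Runs `config$n_reps` replications and tabulates, for each test and
#' stratification mode, the proportion of replicates with p-value below
#' `config$alpha`. Degenerate replicates (no events, or no genotype
#' variation inside the event risk sets) are counted as non-rejections
#' and reported.
#'
#' @param config a [scenario_config()].
#' @return A data frame (one row per test x stratification) with
#'   columns `test`, `stratified`, `rejection_rate`, `mc_se`
#'   (binomial Monte-Carlo standard error), `n_degenerate`, `n_reps`.
#' @export
estimate_rejection_rates <- function(config) {
  ct <- calibrate_censor_time(config)
  seeds <- replication_seeds(config$seed, config$n_reps)
  pm <- matrix(NA_real_, nrow = config$n_reps, ncol = 6L)
  for (r in seq_len(config$n_reps)) {
    set.seed(seeds[r])
    pm[r, ] <- run_replication(config, censor_time = ct)
  }
  nm <- c("score_like_strat", "score_like_unstrat", "cox_xci_strat",
          "cox_xci_unstrat", "cox_xce_strat", "cox_xce_unstrat")
  colnames(pm) <- nm
  # degenerate (NA) replicates count as non-rejections
  rej <- colSums(!is.na(pm) & pm < config$alpha) / config$n_reps
  data.frame(test = rep(c("score_like", "cox_xci", "cox_xce"), each = 2L),
             stratified = rep(c(TRUE, FALSE), 3L),
             rejection_rate = unname(rej),
             mc_se = sqrt(unname(rej) * (1 - unname(rej)) / config$n_reps),
             n_degenerate = colSums(is.na(pm)),
             n_reps = config$n_reps,
             row.names = NULL)
}

#' Reproduce the size/power grids
#'
#' Runs the full Monte-Carlo grid for one or more skewing
#' distributions: pseudo-MAF 0.10/0.20/0.30, effects 0 to -2.5,
#' censoring 0/20/40%. Grid 1 uses the raised-cosine skewing law,
#' grid 2 the mean-1/2 Beta(2,2), grid 3 the truncated normal. Each cell
#' runs on its own reproducible substream derived from `seed`. A full
#' three-grid run at 1000 replications is a matter of minutes; restrict
#' `cells` for spot checks.
#'
#' @param tables subset of `1:3` (which skewing distributions).
#' @param n_reps replications per cell.
#' @param alpha nominal level.
#' @param seed master seed.
#' @param cells optional data frame with columns `p_A`, `beta`,
#'   `censor_frac` restricting the grid.
#' @param file optional path; when given, the result is written as TSV
#'   with rates scaled to percent.
#' @return A data frame with columns `table`, `skew_dist`, `censoring`,
#'   `p_A`, `beta`, `test`, `stratified`, `rejection_rate` (percent),
#'   `mc_se` (percent), `n_degenerate`.
#' @export
reproduce_tables <- function(tables = 1:3, n_reps = 1000L, alpha = 0.05,
                             seed = 1L, cells = NULL, file = NULL) {
  skews <- c("raised_cosine", "beta22", "truncated_normal")
  grid <- expand.grid(table = 1:3, censor_frac = c(0, 0.2, 0.4),
                      p_A = c(0.1, 0.2, 0.3),
                      beta = c(0, -1.5, -1.75, -2, -2.25, -2.5),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$table, grid$censor_frac, grid$p_A, grid$beta), ]
  grid$cell_seed <- replication_seeds(seed, nrow(grid))
  grid <- grid[grid$table %in% tables, ]
  if (!is.null(cells)) {
    key <- function(g) paste(g$p_A, g$beta, g$censor_frac)
    grid <- grid[key(grid) %in% key(cells), ]
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- scenario_config(p_A = g$p_A, beta = g$beta,
                           censor_frac = g$censor_frac,
                           skew = skews[g$table], alpha = alpha,
                           n_reps = n_reps, seed = g$cell_seed)
    rr <- estimate_rejection_rates(cfg)
    rr$rejection_rate <- 100 * rr$rejection_rate
    rr$mc_se <- 100 * rr$mc_se
    out[[i]] <- cbind(data.frame(table = g$table, skew_dist = skews[g$table],
                                 censoring = g$censor_frac, p_A = g$p_A,
                                 beta = g$beta), rr[setdiff(names(rr),
                                                            "n_reps")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(file))
    write.table(res, file, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
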