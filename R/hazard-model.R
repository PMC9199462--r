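#' Skewing-variable distributions
#'
#' Constructor for the distribution of the latent X-inactivation
#' skewing variable `U` of heterozygous females:
#' \describe{
#'   \item{`raised_cosine`}{raised cosine with `mu = 0`, `gamma = 1/2`
#'     on `[-1/2, 1/2]`, mean 0 (the working model; admits closed-form
#'     marginal survival).}
#'   \item{`beta22`}{Beta(2, 2) on `[0, 1]`, mean 1/2: a robustness
#'     scenario in which inactivation is skewed towards the
#'     alternative allele on average, so the heterozygote effect
#'     `beta (1/2 + U)` averages a full homozygote effect.}
#'   \item{`truncated_normal`}{Normal(0, `sd`) truncated to
#'     `[-1/2, 1/2]`, mean 0; default `sd = 0.18`.}
#' }
#'
#' @param name distribution name.
#' @param sd standard deviation of the untruncated normal (only for
#'   `"truncated_normal"`).
#' @return An object of class `"skew_dist"` with elements `name`,
#'   `support` (a length-2 range), `rfun(n)` (random draws using the
#'   current RNG state), `dfun(x)` (density) and `mgf(s)` (moment
#'   generating function `E exp(sU)`, closed form for the raised
#'   cosine, numeric quadrature otherwise).
#' @examples
#' sk <- skew_dist("raised_cosine")
#' sk$mgf(0)  # 1
#' @export
skew_dist <- function(name = c("raised_cosine", "beta22",
                               "truncated_normal"), sd = 0.18) {
  name <- match.arg(name)
  obj <- switch(name,
    raised_cosine = list(
      support = c(-0.5, 0.5),
      rfun = function(n) rrcosine(n, 0, 0.5),
      dfun = function(x) drcosine(x, 0, 0.5),
      mgf  = function(s) rcosine_mgf(s, 0, 0.5)),
    beta22 = list(
      support = c(0, 1),
      rfun = function(n) rbeta(n, 2, 2),
      dfun = function(x) stats::dbeta(x, 2, 2)),
    truncated_normal = {
      lo <- pnorm(-0.5, sd = sd); hi <- pnorm(0.5, sd = sd)
      den <- hi - lo
      list(
        support = c(-0.5, 0.5),
        rfun = function(n) qnorm(lo + runif(n) * den, sd = sd),
        dfun = function(x) ifelse(abs(x) > 0.5, 0,
                                  stats::dnorm(x, sd = sd) / den))
    })
  if (is.null(obj$mgf)) {
    dfun <- obj$dfun
    sup <- obj$support
    obj$mgf <- function(s)
      vapply(s, function(ss)
        integrate(function(u) exp(ss * u) * dfun(u), sup[1], sup[2],
                  rel.tol = 1e-10)$value, numeric(1))
  }
  obj$name <- name
  class(obj) <- "skew_dist"
  obj
}

#' Additive-hazard model specification
#'
#' Fixes the ingredients of the semi-parametric additive hazard model
#' for an X-linked locus: the conditional hazard of a subject with
#' coded genotype `z` and (for heterozygous females, `z = 1/2`)
#' skewing value `u` is
#' \deqn{\lambda(t \mid z, u) = \lambda_0(t) + \beta z +
#'       \beta u \, 1(z = 1/2).}
#'
#' @param beta genetic effect on the hazard scale (negative =
#'   protective alternative allele).
#' @param lambda0 constant baseline hazard rate (scalar, the fast path
#'   used throughout the simulations) or a function `Lambda0(t)`
#'   returning the cumulative baseline hazard.
#' @param skew a [skew_dist()] object (default raised cosine).
#' @return An object of class `"hazard_spec"`. For a constant baseline
#'   the construction checks that the conditional hazard is
#'   non-negative over the whole coding range `w` in `[0, 1]`.
#' @export
hazard_spec <- function(beta, lambda0 = 5,
                        skew = skew_dist("raised_cosine")) {
  if (!inherits(skew, "skew_dist")) skew <- skew_dist(skew)
  constant <- is.numeric(lambda0)
  if (constant) {
    if (length(lambda0) != 1L || lambda0 <= 0)
      stop("'lambda0' must be a positive rate or a cumulative function")
    if (lambda0 + min(0, beta) < 0)
      stop("conditional hazard goes negative: lambda0 + beta * w < 0 ",
           "for some coding value w in [0, 1]")
    Lambda0 <- function(t) lambda0 * t
    lam0 <- function(t) rep(lambda0, length(t))
  } else {
    Lambda0 <- lambda0
    lam0 <- NULL   # general baseline: rate available only via Lambda0
  }
  structure(list(beta = beta, constant_baseline = constant,
                 lambda0 = if (constant) lambda0 else NA_real_,
                 Lambda0 = Lambda0, lam0 = lam0, skew = skew),
            class = "hazard_spec")
}

#' Conditional survival given genotype and skewing value
#'
#' `S(t | z, u) = exp(-(Lambda0(t) + beta z t + beta u t 1(z = 1/2)))`
#' for a constant-baseline specification (and the analogous expression
#' with a general cumulative baseline). Errors if the conditional
#' hazard is negative anywhere on `[0, t]` (constant baseline).
#'
#' @param t non-negative time(s).
#' @param z coded genotype value (0, 1/2 or 1).
#' @param u skewing value in `[-1/2, 1/2]` (ignored unless `z = 1/2`).
#' @param spec a [hazard_spec()].
#' @return Survival probabilities in `[0, 1]`.
#' @export
conditional_survival <- function(t, z, u, spec) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(abs(u) > 0.5)) stop("'u' must lie in [-1/2, 1/2]")
  eff <- z + u * (z == 0.5)
  if (spec$constant_baseline && any(spec$lambda0 + spec$beta * eff < 0))
    stop("negative conditional hazard for this (z, u)")
  exp(-(spec$Lambda0(t) + spec$beta * eff * t))
}

#' Marginal survival over the skewing distribution
#'
#' Survival given the genotype coding only, with the latent skewing
#' variable of heterozygous females integrated out. For `z` in `{0, 1}`
#' this coincides with [conditional_survival()]. For `z = 1/2` with the
#' raised-cosine skewing law the marginalization has the closed form
#' \deqn{S(t \mid z = 1/2) = e^{-\Lambda_0(t) - \beta t / 2}
#'       \, M_U(-\beta t)}
#' where \eqn{M_U} is the raised-cosine moment generating function
#' \eqn{\pi^2 \sinh(s/2) / ((s/2)(\pi^2 + s^2/4))}; any other skewing
#' law is integrated numerically against its density.
#'
#' @inheritParams conditional_survival
#' @return Survival probabilities; `S(0) = 1`.
#' @export
marginal_survival <- function(t, z, spec) {
  if (any(t < 0)) stop("'t' must be non-negative")
  base <- exp(-(spec$Lambda0(t) + spec$beta * z * t))
  if (!isTRUE(all.equal(z, 0.5))) return(base)
  base * spec$skew$mgf(-spec$beta * t)
}

#' Marginal hazard over the skewing distribution
#'
#' The hazard implied by [marginal_survival()]:
#' `lambda(t | z) = lambda0(t) + beta z` for `z` in `{0, 1}`, and for
#' `z = 1/2`
#' \deqn{\lambda(t \mid 1/2) = \lambda_0(t) + \beta/2 +
#'   \left[-\frac{\beta}{2}\coth\frac{\beta t}{2} + \frac1t +
#'   \frac{\beta^2 t / 2}{\pi^2 + \beta^2 t^2/4}\right]}
#' under the raised-cosine law (general laws use the quadrature ratio
#' `beta E[U e^{-beta t U}] / E[e^{-beta t U}]`). The apparent `1/t`
#' singularity is removable: the bracket vanishes as `t -> 0+`, so the
#' limit value `lambda0(0) + beta/2` is returned at `t = 0`. Requires
#' a constant-baseline specification (the baseline rate must be
#' available pointwise).
#'
#' @inheritParams conditional_survival
#' @return Hazard rates (non-negative for admissible specifications).
#' @export
marginal_hazard <- function(t, z, spec) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (!spec$constant_baseline)
    stop("marginal_hazard() needs a constant-baseline hazard_spec")
  base <- spec$lambda0 + spec$beta * z
  if (!isTRUE(all.equal(z, 0.5))) return(rep(base, length(t)))
  beta <- spec$beta
  if (beta == 0) return(rep(spec$lambda0, length(t)))
  if (spec$skew$name == "raised_cosine") {
    # -d/dt log M(-beta t) with M the raised-cosine MGF
    bracket <- beta * rcosine_dlogmgf(-beta * t, gamma = 0.5)
  } else {
    dfun <- spec$skew$dfun
    mgf <- spec$skew$mgf
    sup <- spec$skew$support
    num <- vapply(t, function(tt)
      integrate(function(u) u * exp(-beta * tt * u) * dfun(u),
                sup[1], sup[2], rel.tol = 1e-10)$value, numeric(1))
    bracket <- beta * num / mgf(-beta * t)
  }
  base + bracket
}

#' Semi-parametric cumulative baseline-hazard estimator
#'
#' Estimates the cumulative baseline hazard `Lambda0(t)` of the
#' additive-hazard model at a given effect size `beta`, from censored
#' data and the XCI-coded genotype. The estimator accumulates the
#' Nelson-Aalen event jumps `d_j / n_j` and subtracts, continuously in
#' time, the risk-set average of the non-baseline part of the marginal
#' hazard: `beta * zbar(s)` plus, weighted by the at-risk fraction of
#' heterozygotes, the raised-cosine marginalization bracket. At
#' `beta = 0` the correction vanishes and the estimator reduces exactly
#' to Nelson-Aalen. Accumulation stops when the risk set empties (the
#' estimate is constant beyond the largest observed time, flagged).
#'
#' @param data a [survival_dataset()].
#' @param z coded genotype (`"XCI"` scheme), no missing values.
#' @param beta effect size at which to evaluate the estimator.
#' @param skew a [skew_dist()] for the heterozygote correction term
#'   (default raised cosine).
#' @return An object of class `"cumhaz_estimate"`: a list with `knots`
#'   (the distinct observed times), `cumhaz` (the estimate at each knot,
#'   event jumps included), and `fn`, a vectorized function evaluating
#'   the estimate at arbitrary times.
#' @export
estimate_baseline_cumhaz <- function(data, z, beta,
                                     skew = skew_dist("raised_cosine")) {
  cc <- complete_cases(data, z)
  if (cc$n_dropped > 0)
    stop("estimate_baseline_cumhaz() requires complete coded genotypes")
  if (!inherits(skew, "skew_dist")) skew <- skew_dist(skew)
  time <- cc$data$time; status <- cc$data$event; zz <- cc$z
  n <- length(time)
  knots <- sort.int(unique(time))
  # risk set on the interval (knots[k-1], knots[k]] is {X >= knots[k]}
  o <- order(time)
  ot <- time[o]; oz <- zz[o]; oh <- as.numeric(zz[o] == 0.5)
  k <- findInterval(knots, ot, left.open = TRUE) + 1L
  nrisk <- n - k + 1L
  zbar <- rev(cumsum(rev(oz)))[k] / nrisk
  hbar <- rev(cumsum(rev(oh)))[k] / nrisk
  # event jumps d_j / n_j at each knot (0 where the knot is censoring-only)
  dej <- vapply(knots, function(tt) sum(time == tt & status == 1L),
                numeric(1)) / nrisk
  # integral of the het bracket over (a, b]: log M(-beta a) - log M(-beta b)
  logM <- function(t) log(skew$mgf(-beta * t))
  a <- c(0, knots[-length(knots)])
  drift <- beta * zbar * (knots - a) + hbar * (logM(a) - logM(knots))
  cumhaz <- cumsum(dej - drift)
  fn <- function(t) {
    vapply(t, function(tt) {
      if (tt < 0) stop("'t' must be non-negative")
      j <- findInterval(tt, knots)   # knots[j] <= tt
      base <- if (j == 0L) 0 else cumhaz[j]
      if (j >= length(knots)) return(base)  # risk set empty beyond last knot
      a0 <- if (j == 0L) 0 else knots[j]
      if (tt == a0) return(base)
      # partial drift over (a0, tt]; the next event jump is not reached
      base - (beta * zbar[j + 1L] * (tt - a0) +
                hbar[j + 1L] * (logM(a0) - logM(tt)))
    }, numeric(1))
  }
  structure(list(knots = knots, cumhaz = cumhaz, beta = beta, fn = fn,
                 truncated_at = max(knots)),
            class = "cumhaz_estimate")
}
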