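# Risk-set summaries shared by the score-like and Cox score statistics.
#
# All statistics are sums over observed events of centred coded genotypes,
# with centring at the risk-set mean Zbar(t) = sum_i Y_i(t) Z_i / sum_i Y_i(t)
# and the at-risk convention Y_i(t) = 1(t <= X_i): a subject observed at t
# is still in the risk set at t; ties between events and censorings keep the
# censored subject at risk; tied events share the common risk set (Breslow).
#
# Returns, for complete data (no NA):
#   U  score numerator                 sum_events (Z_i - Zbar(t_i))
#   B  martingale variance estimate    sum_events (Z_i - Zbar(t_i))^2
#   I  Cox observed information        sum_events (Z2bar(t_i) - Zbar(t_i)^2)
risk_kernel <- function(time, status, z) {
  ev <- status == 1L
  nev <- sum(ev)
  if (nev == 0L)
    return(list(U = 0, B = 0, I = 0, n_events = 0L))
  o <- order(time)
  ot <- time[o]
  oz <- z[o]
  sz  <- rev(cumsum(rev(oz)))        # suffix sums: sum of z over {X >= ot[k]}
  sz2 <- rev(cumsum(rev(oz * oz)))
  te <- time[ev]
  ze <- z[ev]
  dt <- sort.int(unique(te))
  k <- findInterval(dt, ot, left.open = TRUE) + 1L   # first index with ot >= dt
  nrisk <- length(ot) - k + 1L
  zbar <- sz[k] / nrisk
  z2bar <- sz2[k] / nrisk
  g <- findInterval(te, dt)          # group events by distinct event time
  d <- tabulate(g, length(dt))
  s1 <- as.vector(rowsum(ze, g))
  s2 <- as.vector(rowsum(ze * ze, g))
  list(U = sum(s1 - d * zbar),
       B = max(0, sum(s2 - 2 * zbar * s1 + d * zbar^2)),
       I = max(0, sum(d * (z2bar - zbar^2))),
       n_events = nev)
}

# Complete-case alignment of a dataset and a coded-genotype vector.
complete_cases <- function(data, z) {
  if (!inherits(data, "survival_dataset"))
    stop("'data' must be a survival_dataset")
  if (length(z) != nrow(data))
    stop("coded genotype length does not match the dataset")
  keep <- !is.na(z)
  list(data = data[keep, , drop = FALSE], z = as.numeric(z)[keep],
       n_dropped = sum(!keep))
}

make_test_result <- function(U, V, n_events, n, n_dropped, method,
                             stratified, variance_label) {
  tol <- 1e-12
  if (n_events == 0L) {
    flag <- "no_events"; S <- NA_real_; p <- NA_real_
  } else if (V <= tol) {
    flag <- "degenerate_no_variation"; S <- NA_real_; p <- NA_real_
  } else {
    flag <- "ok"
    S <- U^2 / V
    p <- pchisq(S, df = 1, lower.tail = FALSE)
  }
  structure(list(U = U, variance = V, statistic = S, p.value = p,
                 n = n, n_events = as.integer(n_events),
                 n_dropped = as.integer(n_dropped), flag = flag,
                 method = method, stratified = stratified,
                 variance_label = variance_label),
            class = "xci_test")
}

#' @export
print.xci_test <- function(x, ...) {
  cat("\n\t", x$method, if (x$stratified) " (stratified)", "\n\n", sep = "")
  cat("n =", x$n, " events =", x$n_events)
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped: missing genotype)",
                           sep = "")
  cat("\n")
  if (x$flag != "ok") {
    cat("flag:", x$flag, "- statistic and p-value undefined\n")
  } else {
    cat(sprintf("U = %.6g, %s = %.6g, chi-square(1) = %.6g, p = %.4g\n",
                x$U, x$variance_label, x$variance, x$statistic, x$p.value))
  }
  invisible(x)
}

#' Per-event-time risk-set summaries
#'
#' Tabulates, at each distinct observed event time, the number of events,
#' the risk-set size and the risk-set means of the coded genotype and of
#' its square. These are the building blocks of all score statistics in
#' the package.
#'
#' @param data a [survival_dataset()].
#' @param z coded genotype vector from [code_genotype()] (no missing
#'   values; apply complete-case filtering first).
#' @return A data frame with columns `time`, `n_events`, `n_risk`,
#'   `zbar`, `z2bar`; zero rows if no events.
#' @export
event_table <- function(data, z) {
  cc <- complete_cases(data, z)
  if (cc$n_dropped > 0)
    stop("event_table() requires complete coded genotypes")
  time <- cc$data$time; status <- cc$data$event; z <- cc$z
  ev <- status == 1L
  if (!any(ev))
    return(data.frame(time = numeric(0), n_events = integer(0),
                      n_risk = integer(0), zbar = numeric(0),
                      z2bar = numeric(0)))
  o <- order(time)
  ot <- time[o]; oz <- z[o]
  sz <- rev(cumsum(rev(oz)))
  sz2 <- rev(cumsum(rev(oz * oz)))
  dt <- sort.int(unique(time[ev]))
  k <- findInterval(dt, ot, left.open = TRUE) + 1L
  nrisk <- length(ot) - k + 1L
  d <- tabulate(findInterval(time[ev], dt), length(dt))
  data.frame(time = dt, n_events = d, n_risk = nrisk,
             zbar = sz[k] / nrisk, z2bar = sz2[k] / nrisk)
}

test_engine <- function(data, z, strata, variance_of, method,
                        variance_label) {
  if (!inherits(data, "survival_dataset"))
    stop("'data' must be a survival_dataset")
  zz <- as.numeric(z)
  if (length(zz) != nrow(data))
    stop("coded genotype length does not match the dataset")
  keep <- !is.na(zz)
  n_dropped <- sum(!keep)
  time <- data$time[keep]
  status <- data$event[keep]
  zz <- zz[keep]
  if (!length(time))
    stop("no subjects left after removing missing genotypes")
  if (is.null(strata)) {
    sl <- list(seq_along(time))
  } else {
    if (length(strata) != length(keep))
      stop("'strata' must have the same length as the dataset")
    strata <- strata[keep]
    if (anyNA(strata))
      stop("every subject must be assigned a stratum")
    sl <- split(seq_along(time), strata)
  }
  U <- 0; V <- 0; nev <- 0L
  for (idx in sl) {
    k <- risk_kernel(time[idx], status[idx], zz[idx])
    U <- U + k$U
    V <- V + variance_of(k)
    nev <- nev + k$n_events
  }
  make_test_result(U, V, nev, length(time), n_dropped, method,
                   stratified = !is.null(strata),
                   variance_label = variance_label)
}

#' Score-like additive-hazards test for X-linked loci
#'
#' Tests the null hypothesis of no genetic effect (`beta = 0`) on the
#' hazard of an X-linked locus under a semi-parametric additive hazard
#' model that allows a skewed X-inactivation pattern in heterozygous
#' females. The statistic is a counting-process score evaluated at the
#' null,
#' \deqn{U = \sum_i \int (Z_i - \bar Z(t)) \, dN_i(t), \qquad
#'       B = \sum_i \int (Z_i - \bar Z(t))^2 \, dN_i(t),}
#' and \eqn{S = U^2/B} is referred to a chi-square distribution with one
#' degree of freedom. Only the fixed XCI coding `Z` enters: the latent
#' skewness variable of heterozygous females drops out of the score at
#' the null, so the test requires no assumption on (or estimate of) the
#' skewing distribution.
#'
#' Subjects with missing coded genotype are dropped (complete-case per
#' locus) and the dropped count is reported. With no events, or no
#' variation of `Z` inside the event-time risk sets, the result carries
#' a diagnostic flag and an `NA` p-value rather than a spurious 0 or 1.
#'
#' @param data a [survival_dataset()].
#' @param z coded genotype from [code_genotype()] (scheme `"XCI"` for the
#'   test's motivating model).
#' @param strata optional stratum labels; when supplied, the score and
#'   its variance are computed within each stratum and summed.
#' @return An object of class `"xci_test"` with elements `U`, `variance`,
#'   `statistic`, `p.value`, `n`, `n_events`, `n_dropped`, `flag`.
#' @seealso [cox_score_test()] for the proportional-hazards comparator,
#'   [stratified_test()] for a uniform stratified interface.
#' @examples
#' d <- survival_dataset(1:4, rep(1, 4), c("F", "F", "M", "M"))
#' score_like_test(d, code_genotype(c(2, 0, 1, 0), d$sex, "XCI"))
#' @export
score_like_test <- function(data, z, strata = NULL) {
  test_engine(data, z, strata, variance_of = function(k) k$B,
              method = "Additive-hazards score-like test (XCI-S)",
              variance_label = "B")
}

#' Cox partial-likelihood score test
#'
#' The standard Cox score test of `beta = 0` for a single coded
#' genotype, computed from risk-set sums with Breslow handling of tied
#' event times. The score numerator is identical to that of
#' [score_like_test()]; the variance is the observed partial-likelihood
#' information \eqn{I = \sum_{events} (\overline{Z^2}(t) - \bar Z(t)^2)}.
#' Combined with the XCI coding this is the "Cox-XCI" comparator; with
#' the XCE coding, "Cox-XCE".
#'
#' @inheritParams score_like_test
#' @return An object of class `"xci_test"`.
#' @export
cox_score_test <- function(data, z, strata = NULL) {
  scheme <- attr(z, "scheme")
  test_engine(data, z, strata, variance_of = function(k) k$I,
              method = paste0("Cox partial-likelihood score test",
                              if (!is.null(scheme)) paste0(" (", scheme, ")")),
              variance_label = "I")
}

#' Stratified association test
#'
#' Computes the score numerator and its variance separately within each
#' stratum and sums both before forming the chi-square statistic. Strata
#' without events contribute zero to both terms. With a single stratum
#' the result equals the unstratified test exactly.
#'
#' @inheritParams score_like_test
#' @param strata stratum labels, one per subject.
#' @param kind `"score_like"` or `"cox"`.
#' @return An object of class `"xci_test"`.
#' @export
stratified_test <- function(data, z, strata, kind = c("score_like", "cox")) {
  kind <- match.arg(kind)
  if (kind == "score_like") score_like_test(data, z, strata = strata)
  else cox_score_test(data, z, strata = strata)
}
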