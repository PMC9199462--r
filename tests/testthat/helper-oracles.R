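# Independent brute-force oracles used across the test files.
# These deliberately share no code with the package internals: risk sets
# are materialized explicitly, selections scan all thresholds, and the
# Hardy-Weinberg conditional law is enumerated from binomial
# coefficients.

# Score-like / Cox quantities by explicit risk-set enumeration: loop
# over every observed event and rebuild its risk set from scratch.
brute_force_score <- function(time, event, z) {
  U <- 0; B <- 0; I <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    rs <- which(time >= time[i])          # Y(t) = 1(t <= X)
    zbar <- mean(z[rs])
    U <- U + (z[i] - zbar)
    B <- B + (z[i] - zbar)^2
    I <- I + mean(z[rs]^2) - zbar^2
  }
  list(U = U, B = B, I = I)
}

# A random small survival dataset with XCI-style coded genotypes.
random_small_dataset <- function(n) {
  sex <- sample(c("female", "male"), n, replace = TRUE)
  calls <- ifelse(sex == "female", sample(0:2, n, replace = TRUE),
                  sample(0:1, n, replace = TRUE))
  # discrete times so that ties actually occur
  time <- sample(1:4, n, replace = TRUE) + 0
  event <- sample(0:1, n, replace = TRUE)
  list(data = survival_dataset(time, event, sex),
       z = code_genotype(calls, sex, "XCI"), sex = sex)
}

# Benjamini-Hochberg by scanning every candidate threshold.
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0) return(integer(0))
  sort(o[seq_len(kmax)])
}

# Hardy-Weinberg exact p-value by direct enumeration of the conditional
# heterozygote distribution from binomial coefficients:
# P(h) = choose(n, h) choose(n - h, (r - h)/2) 2^h / choose(2n, r)
# restricted to h with the parity of the rare count r.
enumerate_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  r <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n == 0 || r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  pr <- vapply(hs, function(h)
    exp(lchoose(n, h) + lchoose(n - h, (r - h) / 2) + h * log(2) -
          lchoose(2 * n, r)), numeric(1))
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Gauss-style quadrature of the conditional survival against a skewing
# density (independent of the closed forms under test).
quadrature_marginal_survival <- function(t, spec) {
  sup <- spec$skew$support
  vapply(t, function(tt)
    integrate(function(u)
      exp(-(spec$Lambda0(tt) + spec$beta * (0.5 + u) * tt)) *
        spec$skew$dfun(u),
      sup[1], sup[2], rel.tol = 1e-11, abs.tol = 1e-13)$value,
    numeric(1))
}
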