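#' Synthetic X-chromosome cohort configuration
#'
#' Describes a synthetic cohort emulating the shape of a real-world
#' biotherapy-immunogenicity study: a few hundred subjects, roughly
#' two-thirds female, a dense panel of X-chromosome SNPs with minor
#' allele frequencies above 5%, an event (anti-drug-antibody
#' detection) in about 27.5% of subjects before a common administrative
#' horizon, and optionally a handful of planted protective loci acting
#' through the additive-hazard model with skewed-inactivation effects
#' in heterozygous females.
#'
#' Null SNPs carry no effect. Planted SNPs drive the event times: each
#' subject's hazard is `lambda0 * (eta if female)` plus the sum of the
#' planted `beta * (z + u * 1(z = 1/2))` terms. The default planted
#' effect (`beta = -4.9` at MAF 0.20 under raised-cosine skewing)
#' leaves hemizygous carrier males with a near-zero hazard, emulating
#' the strong carrier-protection pattern such scans are designed to
#' detect. The administrative horizon is calibrated exactly (through
#' the genotype-and-skewness marginal survival, planted effects
#' included) so the expected event fraction equals `event_target`.
#'
#' @param n_subjects total cohort size.
#' @param frac_female fraction of females.
#' @param n_snps number of SNPs on the panel.
#' @param maf_range range the per-SNP allele frequencies are drawn
#'   from, uniformly.
#' @param planted data frame with columns `maf`, `beta`, `skew`
#'   (a [skew_dist()] name), one row per planted SNP; `NULL` for a
#'   pure-null panel.
#' @param event_target expected fraction of subjects with an observed
#'   event.
#' @param lambda0,eta baseline hazard rate (males) and female
#'   multiplier.
#' @param missing_rate genotype missingness rate.
#' @return An object of class `"fixture_config"`.
#' @export
fixture_config <- function(n_subjects = 456L, frac_female = 309 / 456,
                           n_snps = 12976L, maf_range = c(0.05, 0.5),
                           planted = data.frame(maf = 0.2, beta = -4.9,
                                                skew = "raised_cosine"),
                           event_target = 0.275, lambda0 = 5, eta = 1.2,
                           missing_rate = 0.01) {
  if (!is.null(planted)) {
    if (!all(c("maf", "beta", "skew") %in% names(planted)))
      stop("'planted' needs columns maf, beta, skew")
    if (any(lambda0 + pmin(0, planted$beta) < 0))
      stop("planted effect drives the male hazard negative")
    if (nrow(planted) > n_snps) stop("more planted SNPs than SNPs")
  }
  if (event_target <= 0 || event_target >= 1)
    stop("'event_target' must lie in (0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 frac_female = frac_female, n_snps = as.integer(n_snps),
                 maf_range = maf_range, planted = planted,
                 event_target = event_target, lambda0 = lambda0,
                 eta = eta, missing_rate = missing_rate),
            class = "fixture_config")
}

# Expected population survival at the horizon, planted effects
# included: genotypes at distinct SNPs are independent, so the
# per-SNP marginal factors multiply within each sex.
fixture_population_survival <- function(t, config) {
  pl <- config$planted
  per_sex <- function(lam) {
    s <- exp(-lam * t)
    if (!is.null(pl)) for (i in seq_len(nrow(pl))) {
      p <- pl$maf[i]; b <- pl$beta[i]
      mgf <- skew_dist(pl$skew[i])$mgf
      if (lam == config$lambda0) {      # male factor
        s <- s * ((1 - p) + p * exp(-b * t))
      } else {                          # female factor
        s <- s * ((1 - p)^2 + p^2 * exp(-b * t) +
                    2 * p * (1 - p) * exp(-b * t / 2) * mgf(-b * t))
      }
    }
    s
  }
  wf <- config$frac_female
  wf * per_sex(config$lambda0 * config$eta) +
    (1 - wf) * per_sex(config$lambda0)
}

#' Generate a synthetic X-chromosome scan fixture
#'
#' Draws a full synthetic cohort under a [fixture_config()]: genotypes
#' in Hardy-Weinberg proportions per SNP (two Bernoulli draws per
#' female, one per male), event times from the additive-hazard model
#' driven by the planted SNPs, administrative censoring at the
#' calibrated horizon, and uniform genotype missingness. Optionally
#' writes a PLINK trio, a phenotype TSV (`IID time event sex`) and a
#' truth TSV recording the planted effects.
#'
#' @param config a [fixture_config()].
#' @param seed integer seed (full outputs are reproducible given the
#'   seed).
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.bed/.bim/.fam`, `<prefix>.pheno.tsv` and
#'   `<prefix>.truth.tsv`.
#' @return A list with `gm` (a `"genotype_matrix"`), `pheno` (a
#'   [survival_dataset()]), `truth` (data frame of planted SNPs:
#'   `id`, `pos`, `maf`, `beta`, `skew`) and `horizon` (the
#'   administrative censoring time).
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1L,
                             out_prefix = NULL) {
  set.seed(seed)
  n <- config$n_subjects
  n_f <- round(n * config$frac_female)
  n_m <- n - n_f
  sex <- factor(rep(c("female", "male"), c(n_f, n_m)),
                levels = c("female", "male"))
  iid <- sprintf("SUBJ%04d", seq_len(n))
  n_snp <- config$n_snps
  pos <- sort(sample.int(154000000L, n_snp))
  id <- sprintf("snpX_%06d", seq_len(n_snp))
  pl <- config$planted
  n_pl <- if (is.null(pl)) 0L else nrow(pl)
  planted_idx <- if (n_pl) sort(sample.int(n_snp, n_pl)) else integer(0)
  maf <- runif(n_snp, config$maf_range[1], config$maf_range[2])
  if (n_pl) maf[planted_idx] <- pl$maf
  geno <- matrix(NA_integer_, n_snp, n)
  fem <- sex == "female"
  for (j in seq_len(n_snp)) {
    g <- draw_genotypes(n_f, n_m, maf[j])
    geno[j, ] <- g$calls
  }
  # event times: baseline plus the planted additive effects
  rate <- ifelse(fem, config$lambda0 * config$eta, config$lambda0)
  if (n_pl) for (i in seq_len(n_pl)) {
    z <- code_genotype(geno[planted_idx[i], ], sex, "XCI")
    u <- numeric(n)
    het <- z == 0.5
    u[het] <- draw_skewness(pl$skew[i], sum(het))
    rate <- rate + pl$beta[i] * (z + u * (z == 0.5))
  }
  if (any(rate <= 0)) stop("non-positive hazard rate in fixture")
  tt <- rexp(n, rate)
  upper <- 1
  while (fixture_population_survival(upper, config) >
           1 - config$event_target) upper <- upper * 2
  horizon <- uniroot(function(t)
    fixture_population_survival(t, config) - (1 - config$event_target),
    lower = 0, upper = upper, tol = 1e-12)$root
  time <- pmin(tt, horizon)
  event <- as.integer(tt <= horizon)
  # missingness after the outcome draw, so truth is unaffected
  if (config$missing_rate > 0) {
    miss <- runif(n_snp * n) < config$missing_rate
    geno[miss] <- NA_integer_
  }
  gm <- structure(list(genotypes = geno,
                       snp = data.frame(chr = "X", id = id, pos = pos,
                                        a1 = "A", a2 = "C",
                                        flipped = FALSE,
                                        stringsAsFactors = FALSE),
                       subject = data.frame(fid = "FAM", iid = iid,
                                            sex = sex,
                                            stringsAsFactors = FALSE)),
                  class = "genotype_matrix")
  pheno <- survival_dataset(time, event, sex, subject_id = iid)
  truth <- if (n_pl)
    data.frame(id = id[planted_idx], pos = pos[planted_idx],
               maf = pl$maf, beta = pl$beta, skew = pl$skew,
               stringsAsFactors = FALSE)
  else
    data.frame(id = character(0), pos = integer(0), maf = numeric(0),
               beta = numeric(0), skew = character(0))
  if (!is.null(out_prefix)) {
    write_plink(gm, out_prefix)
    ptab <- data.frame(IID = iid, time = time, event = event,
                       sex = ifelse(fem, "F", "M"))
    write.table(ptab, paste0(out_prefix, ".pheno.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(gm = gm, pheno = pheno, truth = truth, horizon = horizon)
}
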