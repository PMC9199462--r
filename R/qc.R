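#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic SNP: given the observed
#' allele counts, the p-value is the probability, under the
#' Hardy-Weinberg conditional distribution of the heterozygote count,
#' of any table as or less probable than the observed one. Used here on
#' female genotype counts during SNP quality control. The plain (not
#' mid-p) exact test is used, the field standard for QC at extreme
#' thresholds.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return The exact p-value (1 for monomorphic or empty tables).
#' @examples
#' hwe_exact_test(200, 0, 200)  # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  n_A <- 2L * n_AA + n_Aa
  if (n == 0L || n_A == 0L || n_A == 2L * n) return(1)
  rare <- min(n_A, 2L * n - n_A)
  # heterozygote counts share the parity of the rare-allele count
  het <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | n, n_A), up to a common constant:
  # n! 2^h / (n_AA! h! n_aa!) with n_AA = (n_A - h)/2 on the A side
  hom_rare <- (rare - het) %/% 2L
  hom_common <- n - het - hom_rare
  logp <- het * log(2) - lgamma(hom_rare + 1) - lgamma(het + 1) -
    lgamma(hom_common + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- match(n_Aa, het)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-7)]))
}

#' Per-SNP quality control
#'
#' Applies the scan's SNP filters to a genotype matrix: overall call
#' rate, exact Hardy-Weinberg test in females, and minor allele
#' frequency in each sex separately (a SNP fails if its MAF is below
#' the threshold in either sex). Filters are computed independently
#' from the raw matrix, so statuses do not depend on the order of
#' application. The Hardy-Weinberg filter removes `p < hwe_p_min`
#' strictly; a SNP at exactly the threshold is retained.
#'
#' @param gm a `"genotype_matrix"` from [read_plink()] or
#'   [generate_fixture()].
#' @param call_rate_min minimum fraction of non-missing calls.
#' @param hwe_p_min female Hardy-Weinberg exclusion threshold.
#' @param maf_min per-sex minor-allele-frequency threshold.
#' @return A data frame, one row per SNP: `id`, `call_rate`,
#'   `maf_female`, `maf_male`, `hwe_p_female`, `status` (`"pass"` or a
#'   comma-separated list of failed filters among `call_rate`,
#'   `hwe_female`, `maf_female`, `maf_male`).
#' @export
snp_qc <- function(gm, call_rate_min = 0.95, hwe_p_min = 1e-5,
                   maf_min = 0.05) {
  g <- gm$genotypes
  n_snp <- nrow(g)
  fem <- gm$subject$sex == "female"
  call_rate <- rowMeans(!is.na(g))
  gf <- g[, fem, drop = FALSE]
  gmm <- g[, !fem, drop = FALSE]
  n_AA <- rowSums(gf == 2L, na.rm = TRUE)
  n_Aa <- rowSums(gf == 1L, na.rm = TRUE)
  n_aa <- rowSums(gf == 0L, na.rm = TRUE)
  af_f <- (2 * n_AA + n_Aa) / (2 * (n_AA + n_Aa + n_aa))
  nm_ok <- rowSums(!is.na(gmm))
  af_m <- rowSums(gmm, na.rm = TRUE) / nm_ok
  maf_f <- pmin(af_f, 1 - af_f)
  maf_m <- pmin(af_m, 1 - af_m)
  hwe_p <- vapply(seq_len(n_snp), function(j)
    hwe_exact_test(n_AA[j], n_Aa[j], n_aa[j]), numeric(1))
  reasons <- vapply(seq_len(n_snp), function(j) {
    r <- character(0)
    if (call_rate[j] < call_rate_min) r <- c(r, "call_rate")
    if (hwe_p[j] < hwe_p_min) r <- c(r, "hwe_female")
    if (is.na(maf_f[j]) || maf_f[j] < maf_min) r <- c(r, "maf_female")
    if (is.na(maf_m[j]) || maf_m[j] < maf_min) r <- c(r, "maf_male")
    if (length(r)) paste(r, collapse = ",") else "pass"
  }, character(1))
  data.frame(id = gm$snp$id, call_rate = call_rate, maf_female = maf_f,
             maf_male = maf_m, hwe_p_female = hwe_p, status = reasons,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg selection
#'
#' Step-up false-discovery-rate selection: with ordered p-values
#' `p_(1) <= ... <= p_(m)`, select all p-values up to the largest `k`
#' with `p_(k) <= k q / m`. Missing p-values must be excluded by the
#' caller (the FDR universe is the set of valid tests).
#'
#' @param pvals p-values in `[0, 1]`, no `NA`.
#' @param q nominal FDR level.
#' @return Integer indices (into `pvals`) of the selected hypotheses;
#'   empty if none.
#' @export
bh_select <- function(pvals, q = 0.05) {
  if (anyNA(pvals)) stop("remove missing p-values before selection")
  if (!length(pvals)) return(integer(0))
  which(p.adjust(pvals, method = "BH") <= q)
}
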