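#' Assemble and validate a right-censored phenotype dataset
#'
#' Bundles follow-up times, event indicators, sex and an optional stratum
#' label into a validated dataset used by all tests in the package. The
#' at-risk convention is fixed throughout: a subject with follow-up time
#' `X` is at risk at time `t` whenever `t <= X` (closed at the observed
#' time), and the counting process jumps at `X` when the event indicator
#' is 1.
#'
#' @param time numeric vector of non-negative follow-up times (the minimum
#'   of the event and censoring times, in any consistent unit).
#' @param event binary vector (0/1 or logical); 1 means the event was
#'   observed at `time`, 0 means the subject was censored.
#' @param sex vector of sex labels; accepted encodings are
#'   `"female"`/`"male"`, `"F"`/`"M"` or PLINK-style `2`/`1`.
#' @param stratum optional vector of stratum labels (any atomic type);
#'   used by the sex- or covariate-stratified tests.
#' @param subject_id optional character vector of subject identifiers;
#'   defaults to `"S1"`, `"S2"`, ...
#'
#' @return An object of class `"survival_dataset"`: a data frame with
#'   columns `subject_id`, `time`, `event`, `sex` (factor with levels
#'   `female`, `male`) and optionally `stratum`.
#'
#' @examples
#' d <- survival_dataset(time = c(1, 2), event = c(1, 0), sex = c("F", "M"))
#' sum(d$event)
#' @export
survival_dataset <- function(time, event, sex, stratum = NULL,
                             subject_id = NULL) {
  n <- length(time)
  if (n < 1L)
    stop("at least one subject is required")
  if (length(event) != n || length(sex) != n)
    stop("'time', 'event' and 'sex' must have equal length")
  if (!is.null(stratum) && length(stratum) != n)
    stop("'stratum' must have the same length as 'time'")
  if (!is.numeric(time) || anyNA(time))
    stop("'time' must be numeric with no missing values")
  if (any(time < 0))
    stop("negative follow-up time")
  event <- as.integer(event)
  if (anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("'event' must be 0/1")
  sex <- normalize_sex(sex)
  if (is.null(subject_id))
    subject_id <- paste0("S", seq_len(n))
  out <- data.frame(subject_id = as.character(subject_id),
                    time = as.numeric(time), event = event, sex = sex,
                    stringsAsFactors = FALSE)
  if (!is.null(stratum))
    out$stratum <- stratum
  class(out) <- c("survival_dataset", "data.frame")
  out
}

normalize_sex <- function(sex) {
  s <- as.character(sex)
  map <- c("female" = "female", "male" = "male",
           "F" = "female", "M" = "male",
           "f" = "female", "m" = "male",
           "2" = "female", "1" = "male")
  out <- map[s]
  if (anyNA(out[!is.na(s)]))
    stop("unknown sex label: ",
         paste(unique(s[is.na(out) & !is.na(s)]), collapse = ", "))
  factor(out, levels = c("female", "male"))
}

#' Read a phenotype table
#'
#' Reads a tab-delimited phenotype file with header columns
#' `IID time event sex stratum` (`stratum` optional; sex coded
#' `F`/`M` or `2`/`1`).
#'
#' @param path path to the TSV file.
#' @return A [survival_dataset()].
#' @export
read_pheno <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = NA)
  need <- c("IID", "time", "event", "sex")
  if (!all(need %in% names(tab)))
    stop("phenotype table must have columns: ", paste(need, collapse = " "))
  survival_dataset(time = tab$time, event = tab$event, sex = tab$sex,
                   stratum = if ("stratum" %in% names(tab)) tab$stratum,
                   subject_id = tab$IID)
}

#' Code X-chromosome genotypes under the XCI or XCE scheme
#'
#' Converts per-subject alternative-allele counts into the coded value
#' `Z` consumed by the association tests. Females carry counts 0/1/2,
#' hemizygous males 0/1. Under the X-inactivation (XCI) scheme both
#' sexes are coded on 0, 1/2, 1 (male hemizygotes count as a full
#' homozygote: 0 or 1). Under the escape (XCE) scheme females are coded
#' the same but male carriers count as half a female homozygote
#' (0 or 1/2). Missing calls propagate to missing coded values.
#'
#' Only the fixed coding `Z` enters the test statistics; the latent
#' skewing variable that perturbs heterozygous females plays no part in
#' the statistic evaluated under the null hypothesis (its contribution
#' vanishes at `beta = 0`).
#'
#' The XCE convention used here (male carriers = 1/2) is proportional to
#' the 0/1/2 females, 0/1 males convention used by some software; score
#' tests are invariant to a common rescaling of the coding, so the two
#' give identical p-values.
#'
#' @param calls integer vector of alternative-allele counts
#'   (females 0/1/2, males 0/1, `NA` allowed).
#' @param sex sex labels as in [survival_dataset()].
#' @param scheme `"XCI"` or `"XCE"`.
#' @return A numeric vector of coded values with attribute `"scheme"`.
#' @examples
#' code_genotype(c(1, 1), c("F", "M"), "XCI")  # 0.5, 1
#' code_genotype(c(1, 1), c("F", "M"), "XCE")  # 0.5, 0.5
#' @export
code_genotype <- function(calls, sex, scheme = c("XCI", "XCE")) {
  scheme <- match.arg(scheme)
  sex <- normalize_sex(sex)
  if (length(calls) != length(sex))
    stop("'calls' and 'sex' must have equal length")
  calls <- as.numeric(calls)
  fem <- sex == "female"
  ok <- !is.na(calls)
  if (any(ok & fem & !(calls %in% c(0, 1, 2))))
    stop("female calls must be 0, 1, 2 or NA")
  if (any(ok & !fem & calls == 2))
    stop("male genotype call of 2: inconsistent with hemizygosity")
  if (any(ok & !fem & !(calls %in% c(0, 1))))
    stop("male calls must be 0, 1 or NA")
  z <- numeric(length(calls))
  z[fem] <- calls[fem] / 2
  z[!fem] <- if (scheme == "XCI") calls[!fem] else calls[!fem] / 2
  z[!ok] <- NA_real_
  structure(z, scheme = scheme)
}

#' Alternative-allele frequency by sex
#'
#' Computes the frequency of the counted (alternative) allele among
#' females, males, and pooled with X-chromosome dosage weighting
#' (two alleles per female, one per male). Returns `NA` for a sex with
#' no non-missing calls.
#'
#' @param calls alternative-allele counts (females 0/1/2, males 0/1).
#' @param sex sex labels.
#' @return Named numeric vector `c(female, male, pooled)`.
#' @examples
#' # females AA, Aa, Aa, aa; males A, a, a, a
#' allele_frequency(c(2, 1, 1, 0, 1, 0, 0, 0),
#'                  c("F", "F", "F", "F", "M", "M", "M", "M"))
#' @export
allele_frequency <- function(calls, sex) {
  sex <- normalize_sex(sex)
  calls <- as.numeric(calls)
  fem <- sex == "female" & !is.na(calls)
  mal <- sex == "male" & !is.na(calls)
  nf <- sum(fem); nm <- sum(mal)
  af <- if (nf > 0) sum(calls[fem]) / (2 * nf) else NA_real_
  am <- if (nm > 0) sum(calls[mal]) / nm else NA_real_
  den <- 2 * nf + nm
  ap <- if (den > 0) (sum(calls[fem]) + sum(calls[mal])) / den else NA_real_
  c(female = af, male = am, pooled = ap)
}
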