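#' X-chromosome association scan
#'
#' Runs the end-to-end scan: joins the genotype matrix with the
#' phenotype table on subject id, drops subjects whose X-SNP call rate
#' is below `sample_call_rate_min`, applies per-SNP quality control
#' ([snp_qc()]), and tests every passing SNP with the score-like
#' additive-hazards test under the XCI coding — sex-stratified (the
#' default ranking) and unstratified, both always reported. SNPs whose
#' test is degenerate (no genotype variation in the event risk sets)
#' are flagged and excluded from the FDR step; Benjamini-Hochberg
#' selection at level `q` is applied to the remaining stratified
#' p-values (unstratified if `stratify_by_sex = FALSE`).
#'
#' @param gm a `"genotype_matrix"`.
#' @param pheno a [survival_dataset()] whose `subject_id` matches the
#'   genotype `iid`s (inner join; mismatches are counted).
#' @param q FDR level for selection.
#' @param stratify_by_sex rank and select on the sex-stratified test?
#' @param call_rate_min,hwe_p_min,maf_min SNP QC thresholds, see
#'   [snp_qc()].
#' @param sample_call_rate_min minimum per-subject X-SNP call rate.
#' @return An object of class `"xci_scan"`: a list with `table` (one
#'   row per SNP: position, QC metrics, `n_used`, `U`, `B`,
#'   `statistic`, `p`, `p_unstratified`, `qc_status`, `flag`,
#'   `bh_selected`), `n_subjects_used`, `n_subjects_dropped_qc`,
#'   `n_unmatched_geno`, `n_unmatched_pheno`, `qc_counts`, `q`.
#' @export
xchr_scan <- function(gm, pheno, q = 0.05, stratify_by_sex = TRUE,
                      call_rate_min = 0.95, hwe_p_min = 1e-5,
                      maf_min = 0.05, sample_call_rate_min = 0.95) {
  idx_g <- match(pheno$subject_id, gm$subject$iid)
  keep_p <- !is.na(idx_g)
  if (!any(keep_p)) stop("no overlapping subject ids between genotypes ",
                         "and phenotypes")
  n_unmatched_pheno <- sum(!keep_p)
  n_unmatched_geno <- nrow(gm$subject) - sum(keep_p)
  ph <- pheno[keep_p, , drop = FALSE]
  g <- gm$genotypes[, idx_g[keep_p], drop = FALSE]
  sex <- gm$subject$sex[idx_g[keep_p]]
  if (any(as.character(sex) != as.character(ph$sex), na.rm = TRUE))
    warning("sex differs between .fam and phenotype table for some ",
            "subjects; using the phenotype table")
  sex <- ph$sex
  # per-sample X call-rate filter
  scr <- colMeans(!is.na(g))
  ok_s <- scr >= sample_call_rate_min
  n_dropped_qc <- sum(!ok_s)
  ph <- ph[ok_s, , drop = FALSE]
  g <- g[, ok_s, drop = FALSE]
  sex <- sex[ok_s]
  sub_gm <- structure(list(genotypes = g, snp = gm$snp,
                           subject = data.frame(fid = "0",
                                                iid = ph$subject_id,
                                                sex = sex)),
                      class = "genotype_matrix")
  qc <- snp_qc(sub_gm, call_rate_min = call_rate_min,
               hwe_p_min = hwe_p_min, maf_min = maf_min)
  n_snp <- nrow(gm$snp)
  res <- data.frame(id = gm$snp$id, chr = gm$snp$chr, pos = gm$snp$pos,
                    call_rate = qc$call_rate,
                    maf_female = qc$maf_female, maf_male = qc$maf_male,
                    hwe_p_female = qc$hwe_p_female,
                    qc_status = qc$status,
                    n_used = NA_integer_, U = NA_real_, B = NA_real_,
                    statistic = NA_real_, p = NA_real_,
                    p_unstratified = NA_real_,
                    flag = NA_character_, bh_selected = FALSE,
                    stringsAsFactors = FALSE)
  pass <- which(qc$status == "pass")
  fem <- sex == "female"
  for (j in pass) {
    # XCI coding, without re-validating sex labels per SNP
    z <- ifelse(fem, g[j, ] / 2, g[j, ])
    ts <- score_like_test(ph, z, strata = sex)
    tu <- score_like_test(ph, z)
    res$n_used[j] <- ts$n
    res$U[j] <- ts$U
    res$B[j] <- ts$variance
    res$statistic[j] <- ts$statistic
    res$p[j] <- ts$p.value
    res$p_unstratified[j] <- tu$p.value
    res$flag[j] <- ts$flag
  }
  rank_p <- if (stratify_by_sex) res$p else res$p_unstratified
  valid <- which(!is.na(rank_p))
  if (length(valid)) {
    sel <- bh_select(rank_p[valid], q = q)
    res$bh_selected[valid[sel]] <- TRUE
  }
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  fail_reasons <- c("call_rate", "hwe_female", "maf_female", "maf_male")
  qc_counts <- vapply(fail_reasons, function(r)
    sum(grepl(r, qc$status, fixed = TRUE)), integer(1))
  structure(list(table = res, n_subjects_used = nrow(ph),
                 n_subjects_dropped_qc = n_dropped_qc,
                 n_unmatched_geno = n_unmatched_geno,
                 n_unmatched_pheno = n_unmatched_pheno,
                 qc_counts = c(qc_counts,
                               n_snps = n_snp,
                               n_pass = sum(qc$status == "pass"),
                               n_tested = length(valid)),
                 stratified = stratify_by_sex, q = q),
            class = "xci_scan")
}

#' @export
print.xci_scan <- function(x, ...) {
  cat("X-chromosome scan:", x$qc_counts[["n_snps"]], "SNPs,",
      x$n_subjects_used, "subjects\n")
  cat("QC pass:", x$qc_counts[["n_pass"]],
      "| tested (non-degenerate):", x$qc_counts[["n_tested"]],
      "| BH-selected at q =", x$q, ":", sum(x$table$bh_selected), "\n")
  invisible(x)
}

#' Write scan output files
#'
#' Writes `<prefix>.scan.tsv` (the full per-SNP table, position
#' sorted), `<prefix>.hits.tsv` (the BH-selected rows) and
#' `<prefix>.qc.log` (subject and per-filter SNP removal counts).
#' Missing values are written as `.`. Outputs are deterministic for
#' identical inputs.
#'
#' @param scan an `"xci_scan"` object.
#' @param prefix output path prefix.
#' @return The paths written, invisibly.
#' @export
write_scan_outputs <- function(scan, prefix) {
  paths <- paste0(prefix, c(".scan.tsv", ".hits.tsv", ".qc.log"))
  write.table(scan$table, paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  write.table(scan$table[scan$table$bh_selected, , drop = FALSE],
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  qc <- scan$qc_counts
  lines <- c(
    sprintf("subjects used: %d", scan$n_subjects_used),
    sprintf("subjects dropped (X call rate): %d",
            scan$n_subjects_dropped_qc),
    sprintf("subjects unmatched (genotypes only): %d",
            scan$n_unmatched_geno),
    sprintf("subjects unmatched (phenotypes only): %d",
            scan$n_unmatched_pheno),
    sprintf("SNPs total: %d", qc[["n_snps"]]),
    sprintf("SNPs failing call rate: %d", qc[["call_rate"]]),
    sprintf("SNPs failing female HWE: %d", qc[["hwe_female"]]),
    sprintf("SNPs failing female MAF: %d", qc[["maf_female"]]),
    sprintf("SNPs failing male MAF: %d", qc[["maf_male"]]),
    sprintf("SNPs passing QC: %d", qc[["n_pass"]]),
    sprintf("SNPs tested (non-degenerate): %d", qc[["n_tested"]]),
    sprintf("SNPs BH-selected at q = %g: %d", scan$q,
            sum(scan$table$bh_selected)))
  writeLines(lines, paths[3])
  invisible(paths)
}
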