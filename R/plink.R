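# PLINK 1 binary genotype I/O (.bed/.bim/.fam), SNP-major layout.
#
# .bed: magic bytes 0x6C 0x1B, mode byte 0x01 (SNP-major), then
# ceiling(n_subjects / 4) bytes per SNP, two bits per subject packed
# little-endian within each byte: 00 = homozygous A1, 01 = missing,
# 10 = heterozygous, 11 = homozygous A2. Counts below are of the A1
# allele of the .bim line, then re-oriented per SNP to the minor allele
# (score tests are allele-swap invariant; orientation is recorded in
# the `flipped` column so signs of U stay interpretable).

# 256 x 4 lookup: byte value -> A1 counts of its four packed subjects.
plink_decode_table <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  b <- 0:255
  cbind(codes[bitwAnd(b, 3L) + 1L],
        codes[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        codes[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        codes[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes `prefix.bed` / `prefix.bim` / `prefix.fam` (SNP-major only)
#' into an in-memory genotype matrix of alternative-allele counts.
#' Counts are first taken relative to the A1 allele of the `.bim` line
#' and then re-oriented SNP-wise to the minor allele (pooled,
#' X-dosage-weighted frequency); re-oriented SNPs are marked in the
#' `flipped` metadata column. Male X genotypes are stored by PLINK as
#' homozygous calls and are mapped to 0/1; heterozygous male calls are
#' set to missing with a warning.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @return An object of class `"genotype_matrix"`: a list with
#'   `genotypes` (SNPs x subjects integer matrix, `NA` = missing),
#'   `snp` (data frame: `chr`, `id`, `pos`, `a1`, `a2`, `flipped`),
#'   `subject` (data frame: `fid`, `iid`, `sex`).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam_df) < 5L) stop("malformed .fam file: ", fam)
  sex_code <- as.character(fam_df[[5L]])
  sex <- factor(ifelse(sex_code == "2", "female",
                       ifelse(sex_code == "1", "male", NA)),
                levels = c("female", "male"))
  subject <- data.frame(fid = as.character(fam_df[[1L]]),
                        iid = as.character(fam_df[[2L]]),
                        sex = sex, stringsAsFactors = FALSE)
  if (anyDuplicated(subject$iid))
    stop("duplicate subject ids in ", fam)
  bim_info <- file.info(bim)
  if (is.na(bim_info$size) || bim_info$size == 0L) {
    snp <- data.frame(chr = character(0), id = character(0),
                      pos = integer(0), a1 = character(0),
                      a2 = character(0), flipped = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "numeric", "integer",
                                        "character", "character"))
    snp <- data.frame(chr = bim_df[[1L]], id = bim_df[[2L]],
                      pos = bim_df[[4L]], a1 = bim_df[[5L]],
                      a2 = bim_df[[6L]], flipped = FALSE,
                      stringsAsFactors = FALSE)
    if (anyDuplicated(snp$id)) stop("duplicate SNP ids in ", bim)
    if (any(snp$pos < 0)) stop("negative base-pair position in ", bim)
  }
  n_sub <- nrow(subject)
  n_snp <- nrow(snp)
  bpl <- (n_sub + 3L) %/% 4L     # bytes per SNP record
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("bad magic bytes in ", bed, " (offset 0-1): not a PLINK .bed file")
  if (raw[3L] != as.raw(0x01))
    stop("unsupported .bed mode byte at offset 2 (only SNP-major 0x01)")
  want <- 3L + n_snp * bpl
  if (length(raw) < want)
    stop("truncated .bed record in ", bed, ": expected ", want,
         " bytes, found ", length(raw), " (failure at byte offset ",
         length(raw), ")")
  geno <- matrix(NA_integer_, nrow = n_snp, ncol = n_sub)
  if (n_snp > 0L && n_sub > 0L) {
    lut <- plink_decode_table()
    body <- as.integer(raw[-(1:3)][seq_len(n_snp * bpl)])
    dim(body) <- c(bpl, n_snp)
    for (j in seq_len(n_snp)) {
      counts <- as.vector(t(lut[body[, j] + 1L, , drop = FALSE]))
      geno[j, ] <- counts[seq_len(n_sub)]
    }
  }
  male <- which(subject$sex == "male")
  if (length(male)) {
    gm_male <- geno[, male, drop = FALSE]
    het_male <- !is.na(gm_male) & gm_male == 1L
    if (any(het_male)) {
      warning(sum(het_male), " heterozygous male call(s) set to missing")
      gm_male[het_male] <- NA_integer_
    }
    gm_male[!is.na(gm_male)] <- gm_male[!is.na(gm_male)] %/% 2L
    geno[, male] <- gm_male
  }
  gm <- structure(list(genotypes = geno, snp = snp, subject = subject),
                  class = "genotype_matrix")
  orient_to_minor(gm)
}

# Flip SNPs whose counted allele has pooled frequency > 1/2 so that the
# counted allele is the minor one; swaps a1/a2 and sets `flipped`.
orient_to_minor <- function(gm) {
  if (nrow(gm$snp) == 0L) return(gm)
  fem <- gm$subject$sex == "female"
  for (j in seq_len(nrow(gm$snp))) {
    f <- allele_frequency(gm$genotypes[j, ], gm$subject$sex)["pooled"]
    if (!is.na(f) && f > 0.5) {
      row <- gm$genotypes[j, ]
      row[fem] <- 2L - row[fem]
      row[!fem] <- 1L - row[!fem]
      gm$genotypes[j, ] <- row
      gm$snp[j, c("a1", "a2")] <- gm$snp[j, c("a2", "a1")]
      gm$snp$flipped[j] <- TRUE
    }
  }
  gm
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()] (SNP-major, mode byte 0x01). Male 0/1
#' calls are stored as homozygous genotypes, following the PLINK
#' convention for hemizygous loci.
#'
#' @param gm a `"genotype_matrix"`.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  n_sub <- nrow(gm$subject)
  n_snp <- nrow(gm$snp)
  fam <- data.frame(gm$subject$fid, gm$subject$iid, 0L, 0L,
                    ifelse(gm$subject$sex == "female", 2L, 1L), -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$snp$chr, gm$snp$id, 0L, gm$snp$pos,
                    gm$snp$a1, gm$snp$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # two-bit codes per A1 count: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- function(cnt) {
    out <- integer(length(cnt))
    out[is.na(cnt)] <- 1L
    out[!is.na(cnt) & cnt == 2L] <- 0L
    out[!is.na(cnt) & cnt == 1L] <- 2L
    out[!is.na(cnt) & cnt == 0L] <- 3L
    out
  }
  bpl <- (n_sub + 3L) %/% 4L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  male <- gm$subject$sex == "male"
  for (j in seq_len(n_snp)) {
    cnt <- gm$genotypes[j, ]
    cnt[male & !is.na(cnt)] <- 2L * cnt[male & !is.na(cnt)]
    codes <- code_of(cnt)
    length(codes) <- 4L * bpl          # pads with NA
    codes[is.na(codes)] <- 0L          # pad bits are zero, as PLINK writes
    dim(codes) <- c(4L, bpl)
    bytes <- codes[1L, ] + bitwShiftL(codes[2L, ], 2L) +
      bitwShiftL(codes[3L, ], 4L) + bitwShiftL(codes[4L, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
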