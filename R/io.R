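# File formats: PLINK bed/bim/fam (SNP-major 2-bit encoding), GCTA-style
# GRM text, summary-statistics TSV and phenotype TSV. Coordinates are
# 1-based; A1 is the counted/effect allele; phenotype status is coded
# {0 = control, 1 = case} internally and translated to fam's {1, 2} at the
# boundary.

# 2-bit genotype codes, SNP-major: 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het, 11 = hom A2 (dosage 0); individuals packed 4 per byte starting
# at the lowest-order bits.
.bed_decode_table <- local({
  tab <- matrix(NA_real_, 256, 4)
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (b in 0:255)
    for (k in 0:3)
      tab[b + 1, k + 1] <- map[[bitwAnd(bitwShiftR(b, 2 * k), 3L) + 1L]]
  tab
})

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes the SNP-major 2-bit bed encoding into A1 dosages. The magic
#' bytes 0x6C 0x1B and the SNP-major mode byte 0x01 are enforced;
#' individual-major files raise an explicit error.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return a [GenotypeData-class]; case/control status from the fam
#'   phenotype column (1/2 coding), where present, is attached to the
#'   sample table as `status`.
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "A1", "A2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "integer"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file: expected magic bytes 0x6C 0x1B")
  if (raw[3] == as.raw(0x00))
    stop("individual-major bed files are not supported")
  if (raw[3] != as.raw(0x01))
    stop("unknown bed mode byte; expected 0x01 (SNP-major)")
  bps <- ceiling(n / 4)                    # bytes per SNP
  if (length(raw) - 3 != bps * m) stop("truncated bed file")
  body <- as.integer(raw[-(1:3)])
  # decode all bytes to 4 genotypes, then trim the per-SNP padding
  geno <- matrix(t(.bed_decode_table[body + 1, , drop = FALSE]), nrow = 4 * bps)
  d <- geno[seq_len(n), , drop = FALSE]
  samples <- data.frame(sample_id = fam$iid, stringsAsFactors = FALSE)
  if (any(fam$pheno %in% 1:2))
    samples$status <- ifelse(fam$pheno == 2, "case",
                             ifelse(fam$pheno == 1, "control", NA))
  GenotypeData(d, bim[, c("id", "chr", "pos", "A1", "A2")], samples)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' @param genotypes a [GenotypeData-class] with hard-call dosages
#'   (0/1/2/NA).
#' @param prefix output path prefix.
#' @param phenotypes optional phenotype table; its `status` is written to
#'   the fam phenotype column as {1 = control, 2 = case}.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(genotypes, prefix, phenotypes = NULL) {
  d <- dosages(genotypes)
  if (any(!is.na(d) & d != round(d)))
    stop("bed files require hard-call dosages (0/1/2)")
  snps <- snpInfo(genotypes)
  n <- nrow(d); m <- ncol(d)
  # dosage -> 2-bit code
  code <- matrix(3L, n, m)                 # hom A2
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 2] <- 0L
  bps <- ceiling(n / 4)
  pad <- bps * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i4 <- seq(1, nrow(code), by = 4)
  bytes <- code[i4, , drop = FALSE] +
    code[i4 + 1, , drop = FALSE] * 4L +
    code[i4 + 2, , drop = FALSE] * 16L +
    code[i4 + 3, , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  utils::write.table(
    data.frame(snps$chr, snps$id, 0, snps$pos, snps$A1, snps$A2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ph <- rep(-9L, n)
  if (!is.null(phenotypes)) {
    st <- phenotypes$status[match(sampleIds(genotypes),
                                  phenotypes$sample_id)]
    ph <- ifelse(is.na(st), -9L, ifelse(st == "case", 2L, 1L))
  }
  ids <- sampleIds(genotypes)
  utils::write.table(data.frame(ids, ids, 0, 0, 0, ph),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write a GRM in GCTA-compatible text form
#'
#' Writes the lower triangle as tab-separated lines
#' `i j n_snps value` (1-based indices, full precision) to
#' `<prefix>.grm.gz`-style plain text `<prefix>.grm` plus the id file
#' `<prefix>.grm.id`.
#'
#' @param grm a [GRM-class].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writeGrmText <- function(grm, prefix) {
  A <- grmValues(grm)
  cnt <- grmSnpCounts(grm)
  n <- nrow(A)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  lines <- sprintf("%d\t%d\t%d\t%.17g", lt[, 1], lt[, 2],
                   cnt[lt], A[lt])
  writeLines(lines, paste0(prefix, ".grm"))
  ids <- sampleIds(grm)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM written by [writeGrmText()]
#'
#' @param prefix path prefix.
#' @return a [GRM-class].
#' @export
readGrmText <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, ".grm"), header = FALSE,
                           col.names = c("i", "j", "n_snps", "value"))
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  A <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  idx <- cbind(tab$i, tab$j)
  A[idx] <- tab$value; A[idx[, 2:1]] <- tab$value
  cnt[idx] <- tab$n_snps; cnt[idx[, 2:1]] <- tab$n_snps
  new("GRM", values = A, nSnpsUsed = cnt, sampleIds = ids)
}

#' Write / read a phenotype table
#'
#' Tab-separated with header `sample_id status subtype site`.
#' @param phenotypes phenotype data.frame.
#' @param path file path.
#' @return `writePhenotypes`: the path, invisibly; `readPhenotypes`: the
#'   data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
  cols <- intersect(c("sample_id", "status", "subtype", "site"),
                    names(phenotypes))
  utils::write.table(phenotypes[, cols], path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Write / read summary statistics
#'
#' Tab-separated with the conventional header (SNP, CHR, BP, A1, A2, FRQ,
#' BETA, SE, P, N and, when present, INFO, Q, HET_P, DIRECTION).
#' Floating values are written at full precision.
#'
#' @param stats a `SummaryStats` or `MetaResult` data.frame.
#' @param path file path.
#' @return `writeSummaryStats`: the path, invisibly; `readSummaryStats`:
#'   the data.frame in internal column naming.
#' @export
writeSummaryStats <- function(stats, path) {
  out <- data.frame(SNP = stats$id, CHR = stats$chr, BP = stats$pos,
                    A1 = stats$effect_allele, A2 = stats$other_allele,
                    FRQ = if (!is.null(stats$effect_allele_freq))
                      stats$effect_allele_freq else NA,
                    BETA = stats$beta, SE = stats$se, P = stats$p_value,
                    N = if (!is.null(stats$n)) stats$n else NA)
  if (!is.null(stats$info_score)) out$INFO <- stats$info_score
  if (!is.null(stats$cochran_Q)) {
    out$Q <- stats$cochran_Q
    out$HET_P <- stats$p_heterogeneity
    out$DIRECTION <- stats$direction
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(id = as.character(raw$SNP), chr = raw$CHR,
                    pos = raw$BP, effect_allele = raw$A1,
                    other_allele = raw$A2, effect_allele_freq = raw$FRQ,
                    beta = raw$BETA, se = raw$SE, p_value = raw$P,
                    n = raw$N, stringsAsFactors = FALSE)
  if (!is.null(raw$INFO)) out$info_score <- raw$INFO
  if (!is.null(raw$Q)) {
    out$cochran_Q <- raw$Q
    out$p_heterogeneity <- raw$HET_P
    out$direction <- raw$DIRECTION
  }
  out
}
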