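#' Read genotypes from PLINK binary or VCF
#'
#' PLINK 1.x binary trios (.bed SNP-major with .bim/.fam) and biallelic VCF
#' are supported. VCF genotypes are mapped to counts of the ALT allele, which
#' becomes the B allele of the container; non-biallelic records are skipped
#' with a message reporting how many.
#'
#' @param path path to the `.bed` file (its `.bim`/`.fam` siblings must sit
#'   next to it) or to a `.vcf` file.
#' @param format `"plink"`, `"vcf"`, or `"auto"` (default; decided from the
#'   file extension).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path)) "plink"
              else if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else stop("cannot infer format from extension of ", path)
  }
  if (format == "plink") read_plink(path) else read_vcf_genotypes(path)
}

#' Write genotypes to PLINK binary or VCF
#'
#' Round-trips exactly: `read_genotypes(write_genotypes(gm, ...))` preserves
#' genotypes, individual IDs, and SNP metadata.
#'
#' @param gm a [geno_matrix()].
#' @param path output path; for PLINK the `.bed` path (siblings written
#'   alongside), for VCF the `.vcf` path.
#' @param format `"plink"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") write_plink(gm, path) else write_vcf_genotypes(gm, path)
  invisible(path)
}

## ---- PLINK 1.x binary ----------------------------------------------------
## .bed byte layout (SNP-major): magic 0x6c 0x1b 0x01, then per SNP
## ceil(n/4) bytes, two bits per individual, LSB first:
## 00 hom A1, 01 missing, 10 het, 11 hom A2.  A2 is stored as the B allele.

read_plink <- function(bed_path) {
  stem <- sub("\\.bed$", "", bed_path)
  bim <- utils::read.table(paste0(stem, ".bim"), header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(stem, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed_path, what = "raw", n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed_path)
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  # expand each byte to 4 two-bit codes, LSB first
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 8, by = 2), , drop = FALSE] +
           2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.integer(codes), nrow = 4 * bytes_per_snp)[seq_len(n), ,
                                                               drop = FALSE]
  # 00->0 (hom A1), 10->1 het, 11->2 hom A2, 01->NA
  lookup <- c(`0` = 0L, `2` = 1L, `3` = 2L)
  G <- matrix(NA_integer_, n, m)
  for (v in c(0L, 2L, 3L)) G[codes == v] <- lookup[[as.character(v)]]
  snps <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                     allele_A = bim$a1, allele_B = bim$a2,
                     stringsAsFactors = FALSE)
  geno_matrix(G, fam[[2]], snps)
}

write_plink <- function(gm, bed_path) {
  stem <- sub("\\.bed$", "", bed_path)
  n <- nrow(gm$data); m <- ncol(gm$data)
  snps <- gm$snps
  utils::write.table(
    data.frame(snps$chrom, snps$id, 0, snps$pos, snps$allele_A, snps$allele_B),
    paste0(stem, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gm$ids, gm$ids, 0, 0, 0, -9),
    paste0(stem, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  # dosage -> two-bit code
  code_of <- function(g) {
    out <- rep(1L, length(g))          # 01 missing
    out[!is.na(g) & g == 0L] <- 0L
    out[!is.na(g) & g == 1L] <- 2L
    out[!is.na(g) & g == 2L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    codes <- c(code_of(gm$data[, j]), rep(0L, pad))
    b <- codes[seq(1, length(codes), by = 4)] +
         4L * codes[seq(2, length(codes), by = 4)] +
         16L * codes[seq(3, length(codes), by = 4)] +
         64L * codes[seq(4, length(codes), by = 4)]
    writeBin(as.raw(b), con)
  }
  invisible(bed_path)
}

## ---- VCF -----------------------------------------------------------------

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  if (any(multi))
    message(sum(multi), " non-biallelic VCF record(s) skipped")
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # count ALT alleles, phase-agnostic
  count_alt <- function(s) {
    out <- rep(NA_integer_, length(s))
    s <- gsub("\\|", "/", s)
    out[s %in% c("0/0", "0")] <- 0L
    out[s %in% c("0/1", "1/0")] <- 1L
    out[s %in% c("1/1", "1")] <- 2L
    out
  }
  G <- t(apply(gt, 1, count_alt))
  ids <- colnames(gt)
  fix <- fix[keep, , drop = FALSE]
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  snps <- data.frame(id = snp_id, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     allele_A = fix[, "REF"], allele_B = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  geno_matrix(t(G), ids, snps)
}

write_vcf_genotypes <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tropigwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$ids), collapse = "\t"), con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(gm$data))) {
    g <- gm$data[, j]
    calls <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    s <- gm$snps[j, ]
    writeLines(paste(c(s$chrom, s$pos, s$id, s$allele_A, s$allele_B,
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}
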