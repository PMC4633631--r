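#' Write a PLINK binary fileset
#'
#' Emits SNP-major BED (magic bytes `0x6C 0x1B 0x01`), BIM and FAM files.
#' Per the PLINK 1 specification each genotype occupies 2 bits, individuals
#' packed four to a byte starting at the low bits; the 2-bit codes are
#' 0 = homozygous A1 (dosage 2), 1 = missing, 2 = heterozygous, 3 =
#' homozygous A2 (dosage 0). A1 (BIM column 5) is the counted allele.
#' Padding bits in the last byte of each SNP block are zero.
#'
#' @param geno A [genotype_data()] object.
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return Invisibly, a list with the three file paths.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_data"))
  paths <- list(bed = paste0(prefix, ".bed"),
                bim = paste0(prefix, ".bim"),
                fam = paste0(prefix, ".fam"))
  n <- nrow(geno$dosage); m <- ncol(geno$dosage)
  npad <- 4L * as.integer(ceiling(n / 4))

  # 2-bit code per genotype: dosage 2 -> 0, 1 -> 2, 0 -> 3, NA -> 1
  body <- raw(0)
  if (m > 0) {
    code_of <- c(3L, 2L, 0L)
    dos <- geno$dosage
    codes <- matrix(0L, npad, m)
    v <- code_of[dos + 1L]
    v[is.na(dos)] <- 1L
    codes[seq_len(n), ] <- v
    # bits, LSB first within each byte
    low <- codes %% 2L
    high <- codes %/% 2L
    bits <- matrix(0L, 2L * npad, m)
    bits[seq(1L, 2L * npad, by = 2L), ] <- low
    bits[seq(2L, 2L * npad, by = 2L), ] <- high
    body <- packBits(as.logical(bits), type = "raw")
  }

  con <- file(paths$bed, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) writeBin(body, con)

  bim <- data.frame(chr = geno$snp_map$chr, id = geno$snp_map$id,
                    cm = rep(0, m), bp = geno$snp_map$bp,
                    a1 = geno$snp_map$a1, a2 = geno$snp_map$a2)
  utils::write.table(bim, paths$bim, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  st <- geno$sample_table
  fam <- data.frame(fid = st$id, iid = st$id, pat = 0, mat = 0,
                    sex = ifelse(is.na(st$sex), 0L, st$sex),
                    phe = ifelse(is.na(st$phenotype), -9L, st$phenotype))
  utils::write.table(fam, paths$fam, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a PLINK binary fileset
#'
#' Reads SNP-major BED/BIM/FAM files into a [genotype_data()] object.
#' Dosage is the count of allele A1 (BIM column 5). Missing genotypes are
#' preserved as `NA`; 1-based BIM positions are retained. The MHC/X region
#' tag is reconstructed from chromosome and position (extended MHC =
#' chr6:26,500,000-34,000,000 inclusive; chromosome 23 = X).
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @return A [genotype_data()] object.
#' @export
read_plink <- function(prefix) {
  paths <- list(bed = paste0(prefix, ".bed"),
                bim = paste0(prefix, ".bim"),
                fam = paste0(prefix, ".fam"))
  for (p in paths) if (!file.exists(p))
    stop("missing file: ", p, call. = FALSE)

  bim <- utils::read.table(paths$bim, header = FALSE,
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths$fam, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "phe"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- as.integer(ceiling(n / 4))

  raw <- readBin(paths$bed, "raw", n = file.size(paths$bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad BED magic bytes in ", paths$bed, call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported (third magic byte 0x01)",
         call. = FALSE)
  if (length(raw) != 3L + bytes_per_snp * m)
    stop(sprintf("BED file %s is truncated: expected %d bytes, found %d",
                 paths$bed, 3L + bytes_per_snp * m, length(raw)),
         call. = FALSE)

  body <- raw[-(1:3)]
  bits <- as.integer(rawToBits(body))           # LSB first
  bits <- matrix(bits, nrow = 8L * bytes_per_snp, ncol = m)
  low <- bits[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  high <- bits[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  v <- low + 2L * high
  dos_of <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(dos_of[v + 1L], n, m)

  region <- ifelse(bim$chr == 23L, "X",
                   ifelse(bim$chr == 6L & bim$bp >= 26500000L &
                            bim$bp <= 34000000L, "MHC", "autosome"))
  snp_map <- data.frame(id = bim$id, chr = bim$chr, bp = bim$bp,
                        a1 = bim$a1, a2 = bim$a2, region = region,
                        stringsAsFactors = FALSE)
  sample_table <- data.frame(
    id = as.character(fam$iid),
    sex = ifelse(fam$sex %in% c(1L, 2L), fam$sex, NA_integer_),
    phenotype = ifelse(fam$phe %in% c(1L, 2L), fam$phe, NA_integer_),
    stringsAsFactors = FALSE)
  genotype_data(dos, snp_map, sample_table)
}

#' Intersect the SNP universes of two genotype sets
#'
#' Mirrors the practice of analysing only SNPs directly genotyped on all
#' platforms: returns the SNP ids present in both maps, in the order of the
#' first.
#'
#' @param geno1,geno2 [genotype_data()] objects.
#' @return Character vector of shared SNP ids.
#' @export
intersect_snps <- function(geno1, geno2) {
  intersect(geno1$snp_map$id, geno2$snp_map$id)
}
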