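## PLINK 1 binary genotypes (.bed / .bim / .fam) and a tab-separated toy
## format. The .bed decoder follows the SNP-major layout: 3 magic bytes
## (0x6c 0x1b 0x01), then ceiling(n/4) bytes per variant, two bits per
## subject packed from the low bits up. Two-bit codes map to effect-allele
## (A1) dosage: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.

.bed_magic <- as.raw(c(0x6c, 0x1b))

## 256 x 4 lookup: byte value -> dosages of the 4 subjects it packs.
.bed_lookup <- local({
  codes <- c(2, NA, 1, 0)  # two-bit values 00, 01, 10, 11
  m <- matrix(NA_real_, 256L, 4L)
  for (b in 0:255)
    m[b + 1L, ] <- codes[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  m
})

#' Read genotypes from PLINK 1 binary or tab-separated text
#'
#' @param path for `format = "plink1"`, the file-set prefix (with or without
#'   a trailing `.bed`); for `format = "tsv"`, a tab-separated file whose
#'   header row holds variant ids and whose first column holds subject ids.
#' @param format `"plink1"` or `"tsv"`.
#' @return A [genotype_matrix()]. PLINK allele 1 (A1) becomes the effect
#'   allele and dosages count A1 alleles; missing genotypes are `NA`.
#'   For tsv input, variant positions default to 1, 2, ... on chromosome "1"
#'   unless the ids encode nothing better — tsv is a toy-fixture format.
#' @export
read_genotypes <- function(path, format = c("plink1", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_genotypes_tsv(path))
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f))
      gem_stop(paste0("missing PLINK file: ", f), "gemeval_format_error")
  famdf <- read.table(fam, header = FALSE, colClasses = "character")
  ids <- famdf[[2L]]
  bimdf <- read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bimdf) < 6)
    gem_stop(paste0("malformed .bim (need 6 columns): ", bim),
             "gemeval_format_error")
  variants <- data.frame(chrom = bimdf[[1L]],
                         pos_bp = as.integer(bimdf[[4L]]),
                         id = bimdf[[2L]],
                         effect_allele = bimdf[[5L]],
                         other_allele = bimdf[[6L]],
                         stringsAsFactors = FALSE)
  n <- length(ids)
  p <- nrow(variants)
  bpv <- ceiling(n / 4)  # bytes per variant
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], .bed_magic))
    gem_stop(paste0("bad magic bytes in ", bed), "gemeval_format_error")
  if (raw[3L] != as.raw(1L))
    gem_stop(paste0("only SNP-major .bed is supported: ", bed),
             "gemeval_format_error")
  body <- raw[-(1:3)]
  if (length(body) != bpv * p)
    gem_stop(sprintf("%s: expected %d data bytes for %d subjects x %d variants, found %d",
                     bed, bpv * p, n, p, length(body)),
             "gemeval_format_error")
  dos <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    bytes <- as.integer(body[((j - 1L) * bpv + 1L):(j * bpv)])
    vals <- t(.bed_lookup[bytes + 1L, , drop = FALSE])  # 4 x bpv, subject-major
    dos[, j] <- as.vector(vals)[seq_len(n)]
  }
  genotype_matrix(dos, variants, ids)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path))
    gem_stop(paste0("no such file: ", path), "gemeval_format_error")
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  ids <- tab[[1L]]
  vid <- names(tab)[-1L]
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "double")
  variants <- data.frame(chrom = "1", pos_bp = seq_along(vid), id = vid,
                         effect_allele = "A", other_allele = "B",
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, ids)
}

#' Write genotypes to PLINK 1 binary or tab-separated text
#'
#' The PLINK 1 writer is the exact inverse of [read_genotypes()]; dosages
#' must be in \{0, 1, 2, NA\} (the format has no fractional dosages).
#'
#' @param g a [genotype_matrix()].
#' @param path file-set prefix (plink1) or file path (tsv).
#' @param format `"plink1"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("plink1", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format == "tsv") {
    tab <- data.frame(subject_id = subject_ids(g), g$dosages,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  d <- g$dosages
  ok <- is.na(d) | d %in% c(0, 1, 2)
  if (!all(ok))
    gem_stop("PLINK 1 can only encode dosages in {0, 1, 2, NA}",
             "gemeval_validation_error")
  prefix <- sub("\\.bed$", "", path)
  v <- g$variants
  write.table(data.frame(v$chrom, v$id, 0L, v$pos_bp,
                         v$effect_allele, v$other_allele),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- subject_ids(g)
  write.table(data.frame(ids, ids, 0L, 0L, 0L, -9L),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(d)
  bpv <- ceiling(n / 4)
  # dosage -> two-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, ncol(d))
  code[d == 1] <- 2L
  code[d == 2] <- 0L
  code[is.na(d)] <- 1L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, as.raw(1L)), con)
  shift <- c(0L, 2L, 4L, 6L)
  for (j in seq_len(ncol(d))) {
    padded <- c(code[, j], integer(bpv * 4L - n))
    quads <- matrix(padded, nrow = 4L)
    bytes <- colSums(quads * 2L^shift)
    writeBin(as.raw(bytes), con)
  }
  invisible(path)
}
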