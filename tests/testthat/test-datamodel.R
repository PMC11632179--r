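test_that("genotype container validates dosage range, ids and ordering", {
  g <- make_toy_genotypes(n = 3, p = 2)
  expect_s3_class(g, "genotype_matrix")
  expect_identical(dim(g), c(3L, 2L))

  expect_error(make_toy_genotypes(n = 3, p = 2,
                                  dosages = matrix(c(0, 1, 2, 3, 0, 1), 3, 2)),
               class = "gemeval_validation_error")
  v <- data.frame(chrom = "1", pos_bp = c(10L, 20L), id = c("a", "a"),
                  effect_allele = "A", other_allele = "G")
  expect_error(genotype_matrix(matrix(0, 2, 2), v, c("s1", "s2")),
               class = "gemeval_validation_error")

  # variants are stored sorted by (chrom, pos) regardless of input order
  g2 <- make_toy_genotypes(n = 4, p = 3, pos = c(300L, 100L, 200L))
  expect_equal(g2$variants$pos_bp, c(100L, 200L, 300L))
  expect_identical(colnames(g2$dosages), g2$variants$id)
})

test_that("tsv genotypes round-trip through write and read", {
  g <- make_toy_genotypes(n = 3, p = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f, format = "tsv")
  g2 <- read_genotypes(f, format = "tsv")
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_identical(subject_ids(g2), subject_ids(g))

  # out-of-range entry in a hand-written file is rejected
  writeLines(c("subject_id\tv1\tv2", "s1\t0\t3", "s2\t1\t2"),
             f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_genotypes(f2, format = "tsv"),
               class = "gemeval_validation_error")
})

test_that("plink1 triple round-trips dosages (incl. missing) bit-exactly", {
  set.seed(9)
  dos <- matrix(sample(c(0, 1, 2, NA), 7 * 11, replace = TRUE), 7, 11)
  g <- make_toy_genotypes(n = 7, p = 11, dosages = dos)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_genotypes(g, prefix, format = "plink1")
  g2 <- read_genotypes(prefix, format = "plink1")
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$variants, g$variants)

  # fractional dosages cannot be encoded
  gf <- make_toy_genotypes(n = 3, p = 2,
                           dosages = matrix(c(0.5, 1, 2, 0, 1, 2), 3, 2))
  expect_error(write_genotypes(gf, prefix, format = "plink1"),
               class = "gemeval_validation_error")
  # corrupted magic bytes are reported as a format error
  writeBin(as.raw(c(0xde, 0xad, 0x01)), paste0(prefix, ".bed"))
  expect_error(read_genotypes(prefix, format = "plink1"),
               class = "gemeval_format_error")
})

test_that("align_cohort intersects, canonicalizes order, and is idempotent", {
  g <- make_toy_genotypes(n = 3, p = 2)        # subjects S001..S003
  tab <- data.frame(subject_id = c("S003", "S001", "S002"), x = 1:3)
  b <- align_cohort(g, pheno = tab, role = "discovery")
  expect_identical(subject_ids(b$genotypes), b$tables$pheno$subject_id)
  expect_identical(subject_ids(b$genotypes), sort(subject_ids(g)))

  # intersection semantics and drop accounting
  tab2 <- data.frame(subject_id = c("S002", "S003", "S999"), x = 1:3)
  b2 <- align_cohort(g, pheno = tab2)
  expect_identical(subject_ids(b2$genotypes), c("S002", "S003"))
  expect_equal(unname(b2$dropped), c(1L, 1L))

  # aligning an aligned bundle changes nothing
  b3 <- align_cohort(b2$genotypes, pheno = b2$tables$pheno)
  expect_identical(b3$tables$pheno, b2$tables$pheno)
  expect_identical(b3$genotypes$dosages, b2$genotypes$dosages)

  disj <- data.frame(subject_id = c("T1", "T2"), x = 1:2)
  expect_error(align_cohort(g, pheno = disj),
               class = "gemeval_validation_error")
})

test_that("mean imputation fills missing dosages and flags degenerate variants", {
  dos <- matrix(c(0, 2, NA,
                  1, 1, 1,
                  NA, NA, NA), 3, 3)
  g <- make_toy_genotypes(n = 3, p = 3, dosages = dos)
  gi <- impute_missing_dosages(g)
  expect_equal(unname(gi$dosages[, 1]), c(0, 2, 1))       # mean of {0,2}
  expect_equal(unname(gi$dosages[, 3]), c(0, 0, 0))       # all-missing -> 0
  expect_setequal(attr(gi, "excluded"), g$variants$id[2:3])

  # per-variant mean over originally observed entries is preserved
  obs_mean <- colMeans(g$dosages, na.rm = TRUE)[1]
  expect_equal(unname(mean(gi$dosages[, 1])), unname(obs_mean))

  # no missing values: identity
  g2 <- make_toy_genotypes(n = 5, p = 4, seed = 3)
  expect_identical(impute_missing_dosages(g2)$dosages, g2$dosages)
})
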