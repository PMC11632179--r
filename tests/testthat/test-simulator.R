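test_that("genotype simulation is deterministic with calibrated frequencies", {
  g1 <- simulate_genotypes(500, 50, seed = 3)
  g2 <- simulate_genotypes(500, 50, seed = 3)
  expect_identical(g1$dosages, g2$dosages)

  # MAF pinned at 0.5: per-variant mean dosage near 1 within 3 SE
  gm <- simulate_genotypes(4000, 30, maf_range = c(0.5, 0.5), seed = 4)
  se <- sqrt(2 * 0.5 * 0.5 / 4000)
  expect_true(all(abs(colMeans(gm$dosages) - 1) < 3 * se + 1e-12))

  # variants sit far apart: the default clump window finds no pairs
  expect_equal(nrow(pairwise_r2(g1, window_kb = 250)), 0L)
})

test_that("infinitesimal model realizes the configured heritability", {
  g <- simulate_genotypes(4000, 120, seed = 10)
  pcs <- simulate_pcs(g, m_pcs = 2, h2 = 0.2, n_causal = 50, seed = 10)
  expect_equal(length(pcs$causal), 2L)
  expect_length(intersect(pcs$causal[[1]], pcs$causal[[2]]), 0)
  # var(G beta)/var(Z) concentrates near h2 (MC spread at this n_k ~ 0.04)
  expect_true(all(abs(pcs$realized_h2 - 0.2) < 0.1))

  # h2 = 0 degenerates to pure noise
  pcs0 <- simulate_pcs(g, m_pcs = 1, h2 = 0, n_causal = 10, seed = 2)
  expect_equal(pcs0$realized_h2, 0, tolerance = 1e-12)
  expect_equal(sd(pcs0$Z[, 1]), 1, tolerance = 0.1)
})

test_that("liability variance shares match their configured fractions", {
  set.seed(20)
  n <- 20000
  Z <- matrix(rnorm(2 * n), n, 2)
  age <- runif(n, 40, 69)
  sex <- rbinom(n, 1, 0.5)
  y <- simulate_liability(Z, age, sex, f_pc = 0.1, f_age = 0.1, f_sex = 0.1,
                          seed = 21)
  # each component explains ~10%; 2 MC standard errors at n = 20000
  for (v in list(Z[, 1], Z[, 2], age, sex))
    expect_equal(cor(y, v)^2, 0.10, tolerance = 0.25)
  expect_equal(var(y) * (1 - 4 * 0.1), var(y) - sum(
    sapply(list(Z[, 1], Z[, 2], age, sex), function(v) cor(y, v)^2 * var(y))),
    tolerance = 0.05)

  # all fractions zero: liability is the unit-variance residual alone
  y0 <- simulate_liability(Z, age, sex, f_pc = 0, f_age = 0, f_sex = 0,
                           seed = 22)
  expect_equal(sd(y0), 1, tolerance = 0.05)
  expect_lt(abs(cor(y0, Z[, 1])), 0.03)

  expect_error(simulate_liability(Z, age, sex, f_pc = 0.4, f_age = 0.2,
                                  f_sex = 0.0),
               class = "gemeval_validation_error")
})

test_that("scenarios permute exactly what they claim to", {
  cfg <- sim_config(n_discovery = 600, n_evaluation = 600, n_variants = 200,
                    m_pcs = 2, h2 = 0.4, n_causal = 10, seed = 5)
  base <- simulate_dataset(cfg)
  expect_identical(apply_scenario(base, "high_high")$discovery,
                   base$discovery)

  hl <- apply_scenario(base, "high_low", seed = 6)
  dt <- base$discovery$tables$pheno
  ht <- hl$discovery$tables$pheno
  expect_identical(ht$PC1, dt$PC1)                  # components untouched
  expect_identical(sort(ht$Y), sort(dt$Y))          # Y permuted, not redrawn
  expect_lt(abs(cor(ht$Y, ht$PC1)), 3 / sqrt(600))

  ll <- apply_scenario(base, "low_low", seed = 6)
  lt <- ll$discovery$tables$pheno
  expect_identical(sort(lt$PC1), sort(dt$PC1))
  expect_false(identical(lt$PC1, dt$PC1))
  # permuted components are no longer heritable: null-calibrated GWAS
  st <- run_gwas(lt$PC1, ll$discovery$genotypes)
  expect_lt(mean(st$z^2), 1.3)
})

test_that("dataset generation is seed-reproducible with disjoint cohorts", {
  cfg <- sim_config(n_discovery = 300, n_evaluation = 300, n_variants = 100,
                    m_pcs = 2, seed = 8)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$discovery$tables$pheno, d2$discovery$tables$pheno)
  expect_identical(d1$evaluation$genotypes$dosages,
                   d2$evaluation$genotypes$dosages)
  expect_length(intersect(subject_ids(d1$discovery$genotypes),
                          subject_ids(d1$evaluation$genotypes)), 0)
  expect_true(all(unlist(d1$truth$causal) %in%
                    d1$discovery$genotypes$variants$id))
})

test_that("a written dataset round-trips through the plink reader", {
  cfg <- sim_config(n_discovery = 50, n_evaluation = 50, n_variants = 30,
                    m_pcs = 2, n_causal = 5, seed = 12)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(ds, dir)
  g <- read_genotypes(file.path(dir, "discovery"), format = "plink1")
  expect_identical(g$dosages, ds$discovery$genotypes$dosages)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$scenario, "high_high")
})
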