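mk_stats <- function(ids, p, chrom = "1", pos = 1000L * seq_along(ids),
                     T_stat = NULL) {
  out <- data.frame(id = ids, chrom = chrom, pos_bp = pos, p = p,
                    stringsAsFactors = FALSE)
  if (!is.null(T_stat)) out$T_stat <- T_stat
  class(out) <- c("mv_stats", "data.frame")
  attr(out, "m") <- 2L
  out
}

test_that("combined statistic is the chi-square sum of squared Walds", {
  g <- make_toy_genotypes(n = 30, p = 6, seed = 4)
  set.seed(4)
  per_pc <- batch_gwas(cbind(rnorm(30), rnorm(30)), g)
  mv <- combine_stats(per_pc)
  expect_equal(mv$T_stat, per_pc[[1]]$z^2 + per_pc[[2]]$z^2,
               tolerance = 1e-10)
  expect_equal(mv$p, pchisq(mv$T_stat, 2, lower.tail = FALSE))
  expect_true(all(diff(mv$p[order(mv$T_stat)]) <= 0))

  # one component: combined p equals the two-sided normal p of z
  mv1 <- combine_stats(per_pc[1])
  expect_equal(mv1$p, per_pc[[1]]$p, tolerance = 1e-12)
  # frozen chi-square(1) upper tail at T = 9 (z = 3)
  expect_equal(pchisq(9, 1, lower.tail = FALSE), 0.002699796,
               tolerance = 1e-6)

  # zero Walds sit at the null point
  z0 <- per_pc
  z0[[1]]$z <- z0[[2]]$z <- 0
  mv0 <- combine_stats(z0)
  expect_equal(mv0$T_stat, rep(0, 6))
  expect_equal(mv0$p, rep(1, 6))

  # mismatched variant sets name the symmetric difference
  bad <- per_pc
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(combine_stats(bad), class = "gemeval_validation_error")
})

test_that("pairwise r2 respects the window and detects duplicated variants", {
  set.seed(6)
  base <- rbinom(50, 2, 0.4)
  dos <- cbind(base, base, rbinom(50, 2, 0.4))
  # v1/v2 adjacent (within window), v3 five Mb away
  g <- make_toy_genotypes(n = 50, p = 3, pos = c(1000L, 2000L, 5e6L),
                          dosages = dos)
  r2 <- pairwise_r2(g, window_kb = 250)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$r2, 1, tolerance = 1e-12)

  # independent variants at large n: mean off-diagonal r2 is about 1/n
  n <- 10000
  gi <- simulate_genotypes(n, 40, seed = 8)
  gi$variants$pos_bp <- 1000L * seq_len(40)   # force all pairs in-window
  gi <- genotype_matrix(gi$dosages, gi$variants, subject_ids(gi))
  r2i <- pairwise_r2(gi, window_kb = 250)
  expect_equal(nrow(r2i), choose(40, 2))
  expect_equal(mean(r2i$r2), 1 / n, tolerance = 0.35)
})

test_that("greedy clumping matches the hand-worked example", {
  stats <- mk_stats(c("v1", "v2", "v3"), p = c(1e-10, 1e-9, 1e-8))
  r2m <- data.frame(id1 = c("v1", "v1", "v2"), id2 = c("v2", "v3", "v3"),
                    r2 = c(0.8, 0.0, 0.0))
  cl <- clump(stats, r2m, p1 = 5e-8, r2_threshold = 0.1, window_kb = 250)
  expect_identical(cl$index_variants, c("v1", "v3"))
  expect_identical(unname(cl$assignments["v2"]), "v1")

  # single significant variant indexes itself
  s1 <- mk_stats("v1", p = 1e-9)
  cl1 <- clump(s1, r2m[0, ], p1 = 5e-8)
  expect_identical(cl1$index_variants, "v1")

  # no LD at all: every significant variant is an index
  s3 <- mk_stats(c("a", "b", "c"), p = c(1e-9, 1e-9, 0.5))
  cl3 <- clump(s3, r2m[0, ], p1 = 5e-8)
  expect_identical(sort(cl3$index_variants), c("a", "b"))
})

test_that("clumping equals an exhaustive oracle and is threshold-monotone", {
  for (case_seed in 1:5) {
    set.seed(case_seed)
    p_var <- 50 + 30 * case_seed  # up to 200 variants
    ids <- sprintf("v%03d", seq_len(p_var))
    stats <- mk_stats(ids, p = 10^-runif(p_var, 0, 12),
                      pos = sort(sample.int(3e6, p_var)))
    pairs <- t(combn(sample(ids, 25), 2))
    r2m <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                      r2 = runif(nrow(pairs)))
    counts <- c()
    for (thr in c(0.1, 0.5, 0.9)) {
      cl <- clump(stats, r2m, p1 = 1e-4, r2_threshold = thr, window_kb = 500)
      or <- oracle_clump(stats, r2m, p1 = 1e-4, r2_threshold = thr,
                         window_kb = 500)
      expect_identical(cl$index_variants, or$index_variants)
      expect_identical(cl$assignments[sort(names(cl$assignments))],
                       or$assignments[sort(names(or$assignments))])
      counts <- c(counts, length(cl$index_variants))

      # post-hoc invariants: no high-r2 in-window index pair; every pruned
      # variant is linked to and weaker than its index
      pos <- setNames(stats$pos_bp, stats$id)
      pv <- setNames(stats$p, stats$id)
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      r2l <- setNames(r2m$r2, key(r2m$id1, r2m$id2))
      idx <- cl$index_variants
      if (length(idx) > 1) {
        ij <- t(combn(idx, 2))
        close_by <- abs(pos[ij[, 1]] - pos[ij[, 2]]) <= 500 * 1000
        r2ij <- r2l[key(ij[, 1], ij[, 2])]
        expect_equal(sum(close_by & !is.na(r2ij) & r2ij > thr, na.rm = TRUE),
                     0)
      }
      if (length(cl$assignments)) {
        w <- names(cl$assignments)
        v <- unname(cl$assignments)
        expect_true(all(pv[w] >= pv[v]))
        expect_true(all(r2l[key(w, v)] > thr))
      }
    }
    expect_true(all(diff(counts) >= 0))  # raising threshold prunes less
  }
})

test_that("heritability metrics summarize clumped GWS index variants", {
  stats <- mk_stats(c("v1", "v2", "v3", "v4"),
                    p = c(1e-9, 1e-10, 1e-12, 0.2),
                    T_stat = c(30, 50, 100, 2))
  cl <- clump(stats, data.frame(id1 = character(), id2 = character(),
                                r2 = numeric()), p1 = 5e-8)
  h <- heritability_metrics(stats, cl)
  expect_equal(h$n_gws_hits, 3L)
  expect_equal(h$mean_chi2, 60)
  expect_equal(h$median_chi2, 50)

  # singleton
  s1 <- mk_stats("v1", p = 1e-9, T_stat = 40)
  h1 <- heritability_metrics(s1, clump(s1, data.frame(id1 = character(),
                                                      id2 = character(),
                                                      r2 = numeric())))
  expect_equal(h1$n_gws_hits, 1L)
  expect_equal(h1$mean_chi2, 40)

  # nothing genome-wide significant: zero hits, undefined chi-square summaries
  s0 <- mk_stats(c("v1", "v2"), p = c(1e-3, 0.5), T_stat = c(10, 1))
  h0 <- heritability_metrics(s0, clump(s0, data.frame(id1 = character(),
                                                      id2 = character(),
                                                      r2 = numeric())))
  expect_equal(h0$n_gws_hits, 0L)
  expect_true(is.na(h0$mean_chi2) && is.na(h0$median_chi2))
})
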