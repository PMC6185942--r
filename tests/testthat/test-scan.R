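test_that("pair and test bookkeeping is exact at genome scale", {
  expect_identical(count_pairs(352945), 62284910040)
  expect_identical(count_pairs(790527), 312466073601)
  expect_identical(count_pairs(3), 3)
  expect_identical(count_tests(352945), 498279280320)
  expect_identical(count_tests(790527), 2499728588808)
  expect_identical(count_tests(2), 8)
  expect_identical(count_pairs(0), 0)
})

test_that("lookup and naive engines produce identical scan reports", {
  sim <- simulate_gwas(n_snps = 100, n_cases = 150, n_controls = 150,
                       seed = 21)
  a <- epi_scan(sim$genotypes, p_threshold = 1e-3, engine = "lookup")
  b <- epi_scan(sim$genotypes, p_threshold = 1e-3, engine = "naive")
  for (field in c("hits", "top_p", "top_improvement", "n_pairs", "n_tests",
                  "n_significant", "best_chi2", "best_pattern",
                  "single_log10p")) {
    expect_identical(a[[field]], b[[field]])
  }
  expect_gt(a$n_significant, 0L)
})

test_that("scanning unordered pairs with all 8 patterns is exhaustive", {
  # ordered-pair oracle: for every ordered (i, j) and pattern, the best
  # chi2 over patterns must equal the unordered scan's best for {i, j},
  # because the pattern set is transpose-closed
  gm <- random_gm(n = 80, m = 20, seed = 33)
  sc <- epi_scan(gm, p_threshold = 1)
  pats <- enumerate_patterns()
  g <- gm$genotypes
  q <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    q <- q + 1
    chi_ij <- vapply(pats, function(p) chi_square_1df(
      count_pair_naive(g[, i], g[, j], gm$phenotype, p))$chi2, 0)
    chi_ji <- vapply(pats, function(p) chi_square_1df(
      count_pair_naive(g[, j], g[, i], gm$phenotype, p))$chi2, 0)
    expect_equal(max(chi_ij), max(chi_ji))
    expect_equal(sc$best_chi2[q], max(chi_ij))
  }
})

test_that("thresholding and significance accounting behave monotonically", {
  gm <- random_gm(n = 100, m = 25, seed = 8, missing_rate = 0)
  # impossible threshold: empty significant set, bookkeeping unchanged
  sc0 <- epi_scan(gm, p_threshold = 0)
  expect_identical(sc0$n_significant, 0L)
  expect_identical(sc0$n_tests, count_tests(25))
  expect_identical(nrow(sc0$top_p), 0L)

  # n_significant is monotone non-decreasing in the threshold
  ths <- c(1e-4, 1e-2, 0.5, 1)
  ns <- vapply(ths, function(th) epi_scan(gm, p_threshold = th,
                                          dedupe = "all-patterns")$n_significant, 0L)
  expect_true(all(diff(ns) >= 0))
  expect_identical(ns[length(ns)], as.integer(8 * count_pairs(25)))
})

test_that("a planted interaction is the top-ranked pair of a small scan", {
  sim <- simulate_gwas(n_snps = 100, n_cases = 500, n_controls = 500,
                       planted = list(snps = c(7, 42)), seed = 4)
  sc <- epi_scan(sim$genotypes)
  best <- top_pairs(sc, 1)
  expect_identical(c(best$i, best$j), c(7L, 42L))
  # the planted pair is also the top significant hit by p-value
  expect_identical(sort(c(sc$top_p$snp_i[1], sc$top_p$snp_j[1])),
                   sort(sim$truth$planted$snp_ids))
})

test_that("ranking sorts by key with documented tie-breaks", {
  hits <- data.frame(
    i = c(3L, 1L, 2L, 1L), j = c(4L, 5L, 6L, 2L), pattern = c(2L, 1L, 3L, 1L),
    log10_p = c(-3, -5, -3, -1), log10_improvement = c(2, 1, 1, 0.5)
  )
  hits$p <- 10^hits$log10_p
  hits$improvement <- 10^hits$log10_improvement
  by_p <- rank_results(hits, "p", 10)
  expect_identical(by_p$i, c(1L, 3L, 2L, 1L))  # tie at 1e-3: higher improvement first
  by_imp <- rank_results(hits, "improvement", 2)
  expect_identical(nrow(by_imp), 2L)
  expect_identical(by_imp$i[1], 3L)
  # ties broken by lower snp index
  hits2 <- hits
  hits2$log10_improvement <- rep(1, 4)
  hits2$log10_p <- rep(-2, 4)
  expect_identical(rank_results(hits2, "p", 4)$i, c(1L, 1L, 2L, 3L))
  # k beyond the list returns everything
  expect_identical(nrow(rank_results(hits, "p", 99)), 4L)
})

test_that("dedupe keeps one best-pattern row per pair by default", {
  sim <- simulate_gwas(n_snps = 30, n_cases = 200, n_controls = 200, seed = 2)
  all_rows <- epi_scan(sim$genotypes, p_threshold = 0.05,
                       dedupe = "all-patterns")
  best_rows <- epi_scan(sim$genotypes, p_threshold = 0.05,
                        dedupe = "best-pattern")
  key <- paste(best_rows$hits$i, best_rows$hits$j)
  expect_false(anyDuplicated(key) > 0)
  # every deduped row carries its pair's minimum p over patterns
  akey <- paste(all_rows$hits$i, all_rows$hits$j)
  for (r in seq_len(nrow(best_rows$hits))) {
    expect_equal(best_rows$hits$log10_p[r],
                 min(all_rows$hits$log10_p[akey == key[r]]))
  }
})

test_that("scan refuses degenerate phenotype splits and tiny matrices", {
  gm <- genotype_matrix(matrix(1L, 4, 3), rep("case", 4))
  expect_error(epi_scan(gm), "at least one case and one control")
  gm <- genotype_matrix(matrix(1L, 4, 1), rep(c("case", "control"), 2))
  expect_error(epi_scan(gm), "at least 2 SNPs")
})

test_that("MAF and call-rate pre-filters drop SNPs before pairing", {
  g <- cbind(rep(1L, 40),                 # monomorphic: MAF 0
             rep(c(1L, 2L), 20),          # MAF 0.25, complete calls
             c(rep(0L, 30), rep(2L, 10))) # MAF 0.5 but call rate 0.25
  gm <- genotype_matrix(g, rep(c("case", "control"), 20))
  # MAF filter alone drops the monomorphic SNP
  sc <- epi_scan(gm, min_maf = 0.05, p_threshold = 1)
  expect_identical(sc$n_snps_used, 2L)
  expect_identical(sc$snp_ids, gm$snp_ids[2:3])
  # call-rate filter alone drops the sparse SNP
  sc <- epi_scan(gm, min_callrate = 0.5, p_threshold = 1)
  expect_identical(sc$snp_ids, gm$snp_ids[1:2])
  # combined filters leave too few SNPs to pair
  expect_error(epi_scan(gm, min_maf = 0.05, min_callrate = 0.5),
               "at least 2 SNPs")
})
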