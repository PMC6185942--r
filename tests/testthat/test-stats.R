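test_that("1-d.f. chi-square matches the closed form and flags degeneracy", {
  # balanced table carries no association
  res <- chi_square_1df(contingency_table(10, 10, 10, 10))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # hand computation: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  res <- chi_square_1df(contingency_table(50, 10, 50, 90))
  expect_equal(res$chi2, 200 * (50 * 90 - 50 * 10)^2 / (100 * 100 * 60 * 140))
  expect_equal(res$chi2, 38.095238, tolerance = 1e-6)
  expect_equal(res$p, 6.7e-10, tolerance = 0.01)

  # independent oracle: stats::chisq.test without continuity correction
  set.seed(5)
  for (rep in 1:15) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    res <- chi_square_1df(contingency_table(tab[1, 1], tab[2, 1],
                                            tab[1, 2], tab[2, 2]))
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic))
    expect_equal(res$p, unname(ref$p.value))
  }

  # degenerate margins: zero row or column total
  res <- chi_square_1df(contingency_table(0, 0, 5, 5))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_false(chi_square_1df(contingency_table(5, 1, 2, 3))$degenerate)

  # no integer overflow on GWAS-scale counts
  res <- chi_square_1df(contingency_table(50000L, 40000L, 45000L, 55000L))
  expect_true(is.finite(res$chi2))
})

test_that("chi-square p agrees with a permutation null on a small table", {
  # 200 samples, black/white margin fixed, phenotype permuted
  black <- c(rep(TRUE, 100), rep(FALSE, 100))
  phen <- c(rep("case", 55), rep("control", 45), rep("case", 45),
            rep("control", 55))
  obs <- chi_square_1df(contingency_table(
    sum(black & phen == "case"), sum(black & phen == "control"),
    sum(!black & phen == "case"), sum(!black & phen == "control")))
  set.seed(11)
  perm <- replicate(4000, {
    ph <- sample(phen)
    chi_square_1df(contingency_table(
      sum(black & ph == "case"), sum(black & ph == "control"),
      sum(!black & ph == "case"), sum(!black & ph == "control")))$chi2
  })
  p_perm <- mean(perm >= obs$chi2 - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.1)

  # extreme 10-sample table: finite statistic, p strictly inside (0,1)
  res <- chi_square_1df(contingency_table(5, 0, 0, 5))
  expect_true(is.finite(res$chi2))
  expect_gt(res$p, 0)
  expect_lt(res$p, 1)
})

test_that("odds ratio follows the cross-product with zero-cell flags", {
  expect_equal(odds_ratio(contingency_table(10, 10, 10, 10))$or, 1)
  expect_equal(odds_ratio(contingency_table(50, 10, 50, 90))$or, 9)
  r <- odds_ratio(contingency_table(1, 1, 0, 1))
  expect_true(r$infinite)
  r <- odds_ratio(contingency_table(0, 1, 0, 1))
  expect_true(r$undefined)
})

test_that("single-SNP p-values use the best genotype dichotomy", {
  # identical case/control genotype distributions -> p = 1 under both methods
  col <- rep(c(1L, 2L, 3L), times = 4)
  ph <- rep(c("case", "control"), each = 6)
  expect_equal(single_snp_pvalue(col, ph, "best-dichotomy")$p, 1)
  expect_equal(single_snp_pvalue(col, ph, "allelic")$p, 1)

  # hand-built 20-sample column against the collapsed-table oracle
  col <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3, 1, 1, 1, 1, 1, 1, 2, 2, 3, 0)
  ph <- rep(c("case", "control"), each = 10)
  res <- single_snp_pvalue(col, ph)
  ok <- col != 0
  dom <- table(factor(col[ok] >= 2, c(FALSE, TRUE)), ph[ok])
  rec <- table(factor(col[ok] == 3, c(FALSE, TRUE)), ph[ok])
  p_dom <- suppressWarnings(chisq.test(dom, correct = FALSE))$p.value
  p_rec <- suppressWarnings(chisq.test(rec, correct = FALSE))$p.value
  expect_equal(res$p, min(p_dom, p_rec))
  # best dichotomy is never worse than either collapse (up to float noise)
  expect_lte(res$p, p_dom * (1 + 1e-10))
  expect_lte(res$p, p_rec * (1 + 1e-10))

  # allelic method equals the chi-square on the allele-count table
  res_a <- single_snp_pvalue(col, ph, "allelic")
  alle <- rbind(case = c(2 * sum(col == 1 & ph == "case") + sum(col == 2 & ph == "case"),
                         2 * sum(col == 3 & ph == "case") + sum(col == 2 & ph == "case")),
                control = c(2 * sum(col == 1 & ph == "control") + sum(col == 2 & ph == "control"),
                            2 * sum(col == 3 & ph == "control") + sum(col == 2 & ph == "control")))
  expect_equal(res_a$p,
               suppressWarnings(chisq.test(alle, correct = FALSE))$p.value)

  # monomorphic column is degenerate with p = 1
  res <- single_snp_pvalue(rep(1L, 10), rep(c("case", "control"), 5))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("improvement metric follows min(p1, p2) / p_pair and is scale-free", {
  # the published single-SNP and pairwise p-values of a strong interaction
  im <- improvement_metric(3.96e-6, 2.06e-5, 2.52e-14)
  expect_equal(im$improvement, 3.96e-6 / 2.52e-14)
  expect_equal(im$improvement, 1.57e8, tolerance = 0.005)

  expect_equal(improvement_metric(0.01, 0.01, 0.01)$improvement, 1)
  expect_equal(improvement_metric(1e-4, 1e-6, 1e-8)$improvement, 1e2)

  # scale-free: multiplying all three p-values leaves it unchanged
  a <- improvement_metric(1e-5, 3e-4, 2e-9)
  b <- improvement_metric(1e-5 * 0.037, 3e-4 * 0.037, 2e-9 * 0.037)
  expect_equal(a$improvement, b$improvement)

  # survives pairwise p far below double-precision underflow via log scale
  im <- improvement_metric(log10_p1 = -8, log10_p2 = -6, log10_p_pair = -320)
  expect_equal(im$log10_improvement, 312)  # min(-8, -6) - (-320)
  # p_pair underflowed to exactly 0 without a log-scale value is an error
  expect_error(improvement_metric(1e-8, 1e-6, 0), "log10_p_pair")
})
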