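# Scoring of 2x2 contingency tables: uncorrected 1-d.f. Pearson chi-square,
# odds ratio, single-SNP tests, and the improvement metric
#   min(p_snp1 / p_pair, p_snp2 / p_pair),
# which flags pairs far more significant jointly than either SNP alone.
# p-values are carried alongside their base-10 logarithms so that the
# improvement metric survives p-values below the double-precision floor.

#' 1-d.f. Pearson chi-square for a 2x2 case/control table
#'
#' Uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `a = n_db`, `b = n_dw`,
#' `c = n_hb`, `d = n_hw`, referred to the upper tail of the chi-square
#' distribution with 1 degree of freedom.  No Yates continuity correction
#' is applied.  A table with any zero row or column margin carries no
#' association information and is reported as `chi2 = 0`, `p = 1` with the
#' `degenerate` flag set.
#'
#' @param t a [contingency_table()].
#' @return A list with `chi2`, `p`, `log10_p` and `degenerate`.
#' @export
#' @examples
#' chi_square_1df(contingency_table(50, 10, 50, 90))
chi_square_1df <- function(t) {
  a <- as.numeric(t$n_db); b <- as.numeric(t$n_dw)
  c <- as.numeric(t$n_hb); d <- as.numeric(t$n_hw)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (n == 0 || denom == 0) {
    return(list(chi2 = 0, p = 1, log10_p = 0, degenerate = TRUE))
  }
  chi2 <- n * (a * d - b * c)^2 / denom
  log10_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE,
                           log.p = TRUE) / log(10)
  list(chi2 = chi2, p = 10^log10_p, log10_p = log10_p, degenerate = FALSE)
}

#' Odds ratio of a 2x2 case/control table
#'
#' `(n_db * n_hw) / (n_dw * n_hb)`.  A zero denominator with positive
#' numerator yields `Inf` with the `infinite` flag; 0/0 yields `NaN` with
#' the `undefined` flag.
#'
#' @param t a [contingency_table()].
#' @return A list with `or`, `infinite` and `undefined`.
#' @export
odds_ratio <- function(t) {
  num <- as.numeric(t$n_db) * as.numeric(t$n_hw)
  den <- as.numeric(t$n_dw) * as.numeric(t$n_hb)
  if (den == 0 && num == 0) {
    list(or = NaN, infinite = FALSE, undefined = TRUE)
  } else if (den == 0) {
    list(or = Inf, infinite = TRUE, undefined = FALSE)
  } else {
    list(or = num / den, infinite = FALSE, undefined = FALSE)
  }
}

#' Single-SNP 1-d.f. chi-square p-value
#'
#' Marginal association of one SNP with case/control status, as a 1-d.f.
#' chi-square on a 2x2 table.  `method = "best-dichotomy"` (default) takes
#' the smaller p over the two genotype collapses that are the marginal
#' projections of the interaction patterns: dominant-major (`{hom-major}`
#' vs `{het, hom-minor}`) and recessive-minor (`{hom-major, het}` vs
#' `{hom-minor}`).  `method = "allelic"` tests the 2x2 allele-count table
#' (2 alleles per non-missing genotype).  Missing genotypes are excluded.
#' A monomorphic column is degenerate and reports `p = 1`.
#'
#' @param column integer code vector.
#' @param phenotype `"case"`/`"control"` per sample (or logical).
#' @param method `"best-dichotomy"` or `"allelic"`.
#' @return A list with `p`, `log10_p`, `chi2` (of the reported test) and
#'   `degenerate`.
#' @export
single_snp_pvalue <- function(column, phenotype,
                              method = c("best-dichotomy", "allelic")) {
  method <- match.arg(method)
  if (is.logical(phenotype)) phenotype <- ifelse(phenotype, "case", "control")
  stopifnot(length(column) == length(phenotype))
  is_case <- phenotype == "case"
  ok <- column != 0L
  cnt <- function(code, case) sum(ok & is_case == case & column == code)
  n_case <- c(cnt(1L, TRUE), cnt(2L, TRUE), cnt(3L, TRUE))
  n_ctrl <- c(cnt(1L, FALSE), cnt(2L, FALSE), cnt(3L, FALSE))
  present <- (n_case + n_ctrl) > 0L
  if (sum(present) <= 1L) {
    return(list(p = 1, log10_p = 0, chi2 = 0, degenerate = TRUE))
  }
  if (method == "best-dichotomy") {
    dom <- chi_square_1df(contingency_table(
      n_db = n_case[2] + n_case[3], n_hb = n_ctrl[2] + n_ctrl[3],
      n_dw = n_case[1], n_hw = n_ctrl[1]))
    rec <- chi_square_1df(contingency_table(
      n_db = n_case[3], n_hb = n_ctrl[3],
      n_dw = n_case[1] + n_case[2], n_hw = n_ctrl[1] + n_ctrl[2]))
    best <- if (dom$log10_p <= rec$log10_p) dom else rec
    list(p = best$p, log10_p = best$log10_p, chi2 = best$chi2,
         degenerate = dom$degenerate && rec$degenerate)
  } else {
    res <- chi_square_1df(contingency_table(
      n_db = 2L * n_case[3] + n_case[2], n_hb = 2L * n_ctrl[3] + n_ctrl[2],
      n_dw = 2L * n_case[1] + n_case[2], n_hw = 2L * n_ctrl[1] + n_ctrl[2]))
    list(p = res$p, log10_p = res$log10_p, chi2 = res$chi2,
         degenerate = res$degenerate)
  }
}

# vectorised best-dichotomy log10 p for every column of a genotype_matrix
.single_snp_log10p_all <- function(x, method = "best-dichotomy") {
  g <- x$genotypes
  m <- ncol(g)
  out <- numeric(m)
  for (j in seq_len(m)) {
    out[j] <- single_snp_pvalue(g[, j], x$phenotype, method)$log10_p
  }
  out
}

#' Improvement metric of a SNP pair
#'
#' `min(p1 / p_pair, p2 / p_pair)`: how much more significant the pair is
#' than its better single SNP.  Values much larger than 1 indicate a joint
#' association not explained by either marginal effect.  The computation is
#' done on the log10 scale, so pairwise p-values that underflow double
#' precision can be supplied as logarithms via the `log10_*` arguments.
#'
#' @param p1,p2 single-SNP p-values of the two component SNPs.
#' @param p_pair pairwise p-value of the SNP combination.
#' @param log10_p1,log10_p2,log10_p_pair alternative log10-scale inputs;
#'   when given they take precedence over the plain values.
#' @return A list with `improvement` and `log10_improvement`.
#' @export
#' @examples
#' improvement_metric(3.96e-6, 2.06e-5, 2.52e-14)
improvement_metric <- function(p1 = NULL, p2 = NULL, p_pair = NULL,
                               log10_p1 = NULL, log10_p2 = NULL,
                               log10_p_pair = NULL) {
  if (is.null(log10_p1)) log10_p1 <- log10(p1)
  if (is.null(log10_p2)) log10_p2 <- log10(p2)
  if (is.null(log10_p_pair)) log10_p_pair <- log10(p_pair)
  if (!is.finite(log10_p_pair)) {
    stop("pairwise p-value is zero with no log-scale value supplied; ",
         "pass log10_p_pair")
  }
  li <- min(log10_p1, log10_p2) - log10_p_pair
  list(improvement = 10^li, log10_improvement = li)
}
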