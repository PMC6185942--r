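# Exhaustive pairwise interaction scan: every unordered SNP pair is tested
# under all 8 genotype interaction patterns; significant results are ranked
# by pairwise p-value and by improvement metric.  Because the pattern set
# is closed under transposition, scanning unordered pairs (i < j) with all
# 8 patterns covers every ordered combination.

#' Number of unordered SNP pairs
#'
#' `m * (m - 1) / 2`, computed in double precision (exact up to 2^53, far
#' beyond genome-wide SNP counts).
#'
#' @param m number of SNPs.
#' @return Number of unique second-order SNP combinations.
#' @export
#' @examples
#' count_pairs(352945)
count_pairs <- function(m) {
  stopifnot(m >= 0)
  m <- as.numeric(m)
  m * (m - 1) / 2
}

#' Number of statistical tests of an exhaustive scan
#'
#' Eight pattern tests per unordered pair: `8 * count_pairs(m)`.
#'
#' @param m number of SNPs.
#' @return Number of 1-d.f. chi-square tests performed.
#' @export
count_tests <- function(m) 8 * count_pairs(m)

# linear pair index (i<j, i-major order as emitted by the engines) -> (i, j)
.decode_pair_index <- function(q, m) {
  # pairs for fixed i occupy a block of (m - i) entries
  i <- integer(length(q)); j <- integer(length(q))
  block_ends <- cumsum(as.numeric((m - 1):1))
  for (k in seq_along(q)) {
    i[k] <- which(block_ends >= q[k])[1L]
    prev <- if (i[k] == 1L) 0 else block_ends[i[k] - 1L]
    j[k] <- as.integer(i[k] + (q[k] - prev))
  }
  cbind(i = i, j = j)
}

.pair_index <- function(i, j, m) {
  # inverse of .decode_pair_index, i < j
  (i - 1) * m - i * (i - 1) / 2 + (j - i)
}

#' Exhaustive SNP-SNP interaction scan
#'
#' Tests every unordered SNP pair under all eight genotype interaction
#' patterns with the 1-d.f. chi-square test, retains results with pairwise
#' p-value at or below `p_threshold`, attaches odds ratios and improvement
#' metrics (against cached single-SNP p-values), and ranks the significant
#' results by pairwise p-value and by improvement metric.  The scan is
#' deterministic given the data and configuration, and its output is
#' identical between the two counting engines.
#'
#' @param x a [genotype_matrix()].
#' @param p_threshold pairwise p-value cutoff; default is the Bonferroni
#'   bound `0.05 / count_tests(m)` over all tests performed.
#' @param top_k_p,top_k_improvement sizes of the two ranked lists.
#' @param dedupe `"best-pattern"` (default: one row per significant pair,
#'   its minimum-p pattern) or `"all-patterns"`.
#' @param engine `"lookup"` (bit-packed lookup-table counting, default) or
#'   `"naive"` (direct per-sample counting).
#' @param single_snp_method method for the cached single-SNP p-values, see
#'   [single_snp_pvalue()].
#' @param min_maf,min_callrate optional SNP pre-filters (default off):
#'   minimum minor-allele frequency and minimum non-missing call rate.
#' @return An object of class `epi_scan`: list with `hits` (data.frame of
#'   significant results), `top_p` and `top_improvement` (ranked
#'   data.frames), `n_snps_used`, `n_pairs`, `n_tests`, `n_significant`,
#'   `best_chi2`/`best_pattern` (per-pair best over patterns, pairs in
#'   `i < j` order), `single_log10p`, `config` and `runtime` (seconds).
#' @export
epi_scan <- function(x, p_threshold = NULL, top_k_p = 20,
                     top_k_improvement = 10000,
                     dedupe = c("best-pattern", "all-patterns"),
                     engine = c("lookup", "naive"),
                     single_snp_method = c("best-dichotomy", "allelic"),
                     min_maf = 0, min_callrate = 0) {
  stopifnot(inherits(x, "genotype_matrix"))
  dedupe <- match.arg(dedupe)
  engine <- match.arg(engine)
  single_snp_method <- match.arg(single_snp_method)
  if (!any(x$phenotype == "case") || !any(x$phenotype == "control")) {
    stop("scan requires at least one case and one control")
  }

  keep <- rep(TRUE, ncol(x$genotypes))
  if (min_maf > 0 || min_callrate > 0) {
    g <- x$genotypes
    nonmiss <- colSums(g != 0L)
    if (min_callrate > 0) keep <- keep & nonmiss / nrow(g) >= min_callrate
    minor <- colSums(g == 2L) + 2 * colSums(g == 3L)
    maf <- ifelse(nonmiss > 0, minor / (2 * nonmiss), 0)
    if (min_maf > 0) keep <- keep & maf >= min_maf
  }
  idx_used <- which(keep)
  m <- length(idx_used)
  if (m < 2L) stop("scan requires at least 2 SNPs after filtering")
  g <- x$genotypes[, idx_used, drop = FALSE]
  snp_ids <- x$snp_ids[idx_used]

  n_pairs <- count_pairs(m)
  n_tests <- count_tests(m)
  if (is.null(p_threshold)) p_threshold <- 0.05 / n_tests
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold must be in [0, 1]")
  # p <= threshold  <=>  chi2 >= chi2_keep; keep marginally loose and
  # re-filter on the exact p below so float rounding cannot drop a hit
  chi2_keep <- if (p_threshold <= 0) Inf else
    stats::qchisq(p_threshold, df = 1, lower.tail = FALSE) * (1 - 1e-12)

  is_case <- x$phenotype == "case"
  t0 <- proc.time()[["elapsed"]]
  if (engine == "lookup") {
    lut <- .cached_lookup_table()
    wcase <- .pack_matrix(g[is_case, , drop = FALSE])
    wctrl <- .pack_matrix(g[!is_case, , drop = FALSE])
    raw <- scan_lookup_cpp(wcase, wctrl, lut$black, lut$nonmiss, chi2_keep)
  } else {
    gcase <- g[is_case, , drop = FALSE]
    gctrl <- g[!is_case, , drop = FALSE]
    raw <- scan_naive_cpp(gcase, gctrl, .pattern_mask16(), chi2_keep)
  }

  single_log10p <- .single_snp_log10p_all(
    list(genotypes = g, phenotype = x$phenotype), single_snp_method)

  hits <- data.frame(
    i = raw$hit_i, j = raw$hit_j, pattern = raw$hit_pattern,
    n_db = raw$n_db, n_dw = raw$n_dw, n_hb = raw$n_hb, n_hw = raw$n_hw,
    chi2 = raw$hit_chi2
  )
  hits$log10_p <- stats::pchisq(hits$chi2, df = 1, lower.tail = FALSE,
                                log.p = TRUE) / log(10)
  hits$p <- 10^hits$log10_p
  hits$degenerate <- hits$chi2 == 0 &
    ((hits$n_db + hits$n_dw == 0) | (hits$n_hb + hits$n_hw == 0) |
     (hits$n_db + hits$n_hb == 0) | (hits$n_dw + hits$n_hw == 0))
  hits <- hits[hits$p <= p_threshold, , drop = FALSE]

  if (dedupe == "best-pattern" && nrow(hits) > 0L) {
    key <- paste(hits$i, hits$j)
    ord <- order(key, hits$log10_p, hits$pattern)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$i, hits$j)), , drop = FALSE]
  }

  if (nrow(hits) > 0L) {
    or <- mapply(function(a, b, c, d) odds_ratio(
      contingency_table(a, c, b, d))$or,
      hits$n_db, hits$n_dw, hits$n_hb, hits$n_hw)
    hits$odds_ratio <- as.numeric(or)
    hits$log10_p_i <- single_log10p[hits$i]
    hits$log10_p_j <- single_log10p[hits$j]
    li <- pmin(hits$log10_p_i, hits$log10_p_j) - hits$log10_p
    hits$improvement <- 10^li
    hits$log10_improvement <- li
    hits$snp_i <- snp_ids[hits$i]
    hits$snp_j <- snp_ids[hits$j]
  } else {
    hits$odds_ratio <- numeric(0); hits$log10_p_i <- numeric(0)
    hits$log10_p_j <- numeric(0); hits$improvement <- numeric(0)
    hits$log10_improvement <- numeric(0)
    hits$snp_i <- character(0); hits$snp_j <- character(0)
  }
  rownames(hits) <- NULL
  runtime <- proc.time()[["elapsed"]] - t0

  res <- structure(
    list(
      hits = hits,
      top_p = rank_results(hits, "p", top_k_p),
      top_improvement = rank_results(hits, "improvement", top_k_improvement),
      n_snps_used = m, snp_ids = snp_ids,
      n_pairs = n_pairs, n_tests = n_tests, n_significant = nrow(hits),
      best_chi2 = raw$best_chi2, best_pattern = raw$best_pattern,
      single_log10p = single_log10p,
      config = list(p_threshold = p_threshold, top_k_p = top_k_p,
                    top_k_improvement = top_k_improvement, dedupe = dedupe,
                    engine = engine, single_snp_method = single_snp_method,
                    min_maf = min_maf, min_callrate = min_callrate),
      runtime = runtime
    ),
    class = "epi_scan"
  )
  res
}

# pack every column of a code matrix into words; returns n_words x m matrix
.pack_matrix <- function(g) {
  n <- nrow(g)
  n_words <- max(1L, ceiling(n / .GENOS_PER_WORD))
  pad <- n_words * .GENOS_PER_WORD - n
  if (pad > 0L) g <- rbind(g, matrix(0L, pad, ncol(g)))
  mult <- c(1L, 4L, 16L, 64L)
  out <- matrix(0L, n_words, ncol(g))
  for (k in 1:4) {
    out <- out + g[seq(k, nrow(g), by = 4L), , drop = FALSE] * mult[k]
  }
  storage.mode(out) <- "integer"
  out
}

#' Rank scan results
#'
#' Stable top-k ranking of result rows by pairwise p-value (ascending) or by
#' improvement metric (descending).  Ties are broken by the other key, then
#' by `i`, `j`, `pattern`.
#'
#' @param results data.frame of scan hits (as in the `hits` element of an
#'   [epi_scan()] result).
#' @param key `"p"` or `"improvement"`.
#' @param k list size; a `k` beyond the number of rows returns all rows.
#' @return The top-k rows, re-ordered.
#' @export
rank_results <- function(results, key = c("p", "improvement"), k = 20) {
  key <- match.arg(key)
  stopifnot(k >= 1)
  if (nrow(results) == 0L) return(results)
  ord <- if (key == "p") {
    order(results$log10_p, -results$log10_improvement, results$i, results$j,
          results$pattern)
  } else {
    order(-results$log10_improvement, results$log10_p, results$i, results$j,
          results$pattern)
  }
  out <- results[ord, , drop = FALSE][seq_len(min(k, nrow(results))), ,
                                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.epi_scan <- function(x, ...) {
  cat(sprintf(
    "Exhaustive SNP-SNP interaction scan (%s engine)\n", x$config$engine))
  cat(sprintf("  %d SNPs -> %s pairs, %s pattern tests\n", x$n_snps_used,
              format(x$n_pairs, big.mark = ","),
              format(x$n_tests, big.mark = ",")))
  cat(sprintf("  significant at p <= %.3g: %d\n", x$config$p_threshold,
              x$n_significant))
  if (x$n_significant > 0L) {
    top <- x$top_p[1L, ]
    cat(sprintf("  best pair: %s x %s (pattern %d, p = %.3g, OR = %.4g)\n",
                top$snp_i, top$snp_j, top$pattern, top$p, top$odds_ratio))
  }
  cat(sprintf("  runtime: %.2f s\n", x$runtime))
  invisible(x)
}

#' @method summary epi_scan
#' @export
summary.epi_scan <- function(object, ...) {
  cat(sprintf("Scan of %d SNPs: %s tests, %d significant hits\n",
              object$n_snps_used, format(object$n_tests, big.mark = ","),
              object$n_significant))
  if (object$n_significant > 0L) {
    cat("\nTop hits by pairwise p-value:\n")
    print(utils::head(object$top_p[, c("snp_i", "snp_j", "pattern", "chi2",
                                       "p", "odds_ratio", "improvement")],
                      10L), digits = 4)
    cat("\nTop hits by improvement metric:\n")
    print(utils::head(
      object$top_improvement[, c("snp_i", "snp_j", "pattern", "p",
                                 "improvement")], 10L), digits = 4)
  }
  invisible(object)
}

#' Plot a scan result
#'
#' Scatter of significance against improvement for the significant hits:
#' `-log10(p_pair)` on the x axis, `log10(improvement)` on the y axis.
#' Pairs high on both axes are strong joint signals unexplained by marginal
#' effects.
#'
#' @param x an `epi_scan` object.
#' @param ... passed to [graphics::plot()].
#' @method plot epi_scan
#' @export
plot.epi_scan <- function(x, ...) {
  h <- x$hits
  if (nrow(h) == 0L) {
    graphics::plot.new()
    graphics::title(main = "no significant interactions")
    return(invisible(x))
  }
  graphics::plot(-h$log10_p, h$log10_improvement,
                 xlab = expression(-log[10](p[pair])),
                 ylab = expression(log[10](improvement)),
                 main = "SNP-SNP interaction scan", pch = 20, ...)
  graphics::abline(h = 0, lty = 2, col = "grey")
  invisible(x)
}

#' Best-scoring pairs regardless of significance threshold
#'
#' Decodes the per-pair best chi-square track of a scan into the `k`
#' top-ranked SNP pairs (by best-pattern chi-square, i.e. minimum pairwise
#' p), whether or not they passed the significance threshold.
#'
#' @param scan an `epi_scan` object.
#' @param k number of pairs.
#' @return data.frame with `i`, `j`, `snp_i`, `snp_j`, `pattern`, `chi2`,
#'   `p`.
#' @export
top_pairs <- function(scan, k = 1) {
  stopifnot(inherits(scan, "epi_scan"))
  k <- min(k, length(scan$best_chi2))
  ord <- order(-scan$best_chi2)[seq_len(k)]
  ij <- .decode_pair_index(ord, scan$n_snps_used)
  data.frame(
    i = ij[, "i"], j = ij[, "j"],
    snp_i = scan$snp_ids[ij[, "i"]], snp_j = scan$snp_ids[ij[, "j"]],
    pattern = scan$best_pattern[ord], chi2 = scan$best_chi2[ord],
    p = stats::pchisq(scan$best_chi2[ord], df = 1, lower.tail = FALSE)
  )
}
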