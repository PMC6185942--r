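# Case-control GWAS simulator with a planted pattern interaction.
#
# Null SNPs are drawn under Hardy-Weinberg equilibrium at per-SNP minor
# allele frequencies sampled uniformly from maf_range, independently of the
# phenotype.  The planted SNP pair follows a two-level penetrance model:
# the pattern's black genotype group carries penetrance f_black and the
# white group f_white, calibrated so that the population prevalence is K
# and the broad-sense heritability of the 0/1 disease trait is h2.
# Individuals are generated from population genotype frequencies (linkage
# equilibrium between the two loci), assigned disease status by their
# group's penetrance, and accumulated by rejection until the requested case
# and control counts are met (retrospective ascertainment, so phenotype
# counts are exact).

# HWE genotype probabilities for codes (1, 2, 3) at minor allele freq q
.hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Calibrate a two-level penetrance model
#'
#' Given a pattern, the two minor allele frequencies, a target broad-sense
#' heritability `h2` of the binary disease trait and a population
#' prevalence `K`, solve for the black/white penetrances.  With
#' `p = p_black` the population frequency of black genotypes (HWE, linkage
#' equilibrium), the model satisfies
#' `K = p f_black + (1 - p) f_white` and
#' `h2 = p (1 - p) (f_black - f_white)^2 / (K (1 - K))`,
#' so `f_black - f_white = sqrt(h2 K (1 - K) / (p (1 - p)))`.
#'
#' @param pattern an `epi_pattern`.
#' @param maf1,maf2 minor allele frequencies of the two loci, in (0, 0.5].
#' @param h2 broad-sense heritability in `[0, 1)`.
#' @param K population prevalence in `(0, 1)`.
#' @return An object of class `penetrance_model`: list with `f_black`,
#'   `f_white`, `p_black`, `h2`, `K`.
#' @export
#' @examples
#' calibrate_penetrance(enumerate_patterns()[[5]], 0.5, 0.5, 0.05, 0.2)
calibrate_penetrance <- function(pattern, maf1, maf2, h2, K) {
  stopifnot(inherits(pattern, "epi_pattern"),
            maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            h2 >= 0, h2 < 1, K > 0, K < 1)
  cellp <- outer(.hwe_probs(maf1), .hwe_probs(maf2))
  p_black <- sum(cellp[pattern$mask])
  if (p_black <= 0 || p_black >= 1) {
    stop("pattern has a degenerate black-genotype frequency at these MAFs")
  }
  d <- sqrt(h2 * K * (1 - K) / (p_black * (1 - p_black)))
  f_black <- K + (1 - p_black) * d
  f_white <- K - p_black * d
  if (f_white < 0 || f_black > 1) {
    stop(sprintf(
      paste0("penetrance calibration infeasible: h2 = %g with prevalence ",
             "K = %g and black-genotype frequency p = %.4f requires ",
             "f_black = %.4f, f_white = %.4f outside [0, 1]"),
      h2, K, p_black, f_black, f_white))
  }
  structure(list(f_black = f_black, f_white = f_white, p_black = p_black,
                 h2 = h2, K = K),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(
    "penetrance model: f_black = %.4f, f_white = %.4f (p_black = %.4f)\n",
    x$f_black, x$f_white, x$p_black))
  cat(sprintf("  prevalence K = %g, broad-sense h2 = %g\n", x$K, x$h2))
  invisible(x)
}

# draw n genotype codes (1..3) under HWE at minor allele frequency q
.draw_hwe <- function(n, q) {
  sample.int(3L, n, replace = TRUE, prob = .hwe_probs(q))
}

#' Simulate a case-control GWAS dataset with a planted interaction
#'
#' Generates `n_snps` biallelic SNPs over `n_cases + n_controls` samples.
#' All SNPs but the planted pair are null: HWE genotypes at a per-SNP MAF
#' drawn from `maf_range`, independent of phenotype.  The planted pair (by
#' default SNPs 1 and 2) follows the penetrance model calibrated by
#' [calibrate_penetrance()]; its genotypes are drawn retrospectively by
#' rejection sampling so that case/control counts are exact.  Setting
#' `planted = NULL` yields a fully null dataset.
#'
#' Defaults mirror the simulation conditions of the package's validation
#' suite: 1000 SNPs, 1000 cases + 1000 controls, planted presence-pattern
#' interaction (pattern 1) between two common variants (MAF 0.5) at
#' heritability 0.1 and prevalence 0.2, no missing data.
#'
#' @param n_snps,n_cases,n_controls dataset dimensions.
#' @param maf_range interval for the null SNPs' minor allele frequencies.
#' @param planted list with `pattern` (id 1-8), `maf1`, `maf2`, `h2`,
#'   `prevalence`, `snps` (two column indices); or `NULL` for no planted
#'   effect.  Missing elements take the defaults above.
#' @param missing_rate proportion of genotype calls set to missing.
#' @param seed integer; fully determines the dataset.
#' @return An object of class `epi_sim`: list with `genotypes` (a
#'   [genotype_matrix()]) and `truth` (planted indices, pattern id,
#'   penetrance model, seed and configuration).
#' @export
simulate_gwas <- function(n_snps = 1000, n_cases = 1000, n_controls = 1000,
                          maf_range = c(0.05, 0.5),
                          planted = list(pattern = 1, maf1 = 0.5, maf2 = 0.5,
                                         h2 = 0.1, prevalence = 0.2,
                                         snps = c(1, 2)),
                          missing_rate = 0, seed = 1) {
  stopifnot(n_snps >= 1, n_cases >= 1, n_controls >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(planted)) {
    defaults <- list(pattern = 1, maf1 = 0.5, maf2 = 0.5, h2 = 0.1,
                     prevalence = 0.2, snps = c(1, 2))
    planted <- utils::modifyList(defaults, planted)
    planted$snps <- as.integer(planted$snps)
    planted$pattern <- as.integer(planted$pattern)
    stopifnot(planted$pattern %in% 1:8, length(planted$snps) == 2,
              all(planted$snps >= 1), all(planted$snps <= n_snps),
              planted$snps[1] != planted$snps[2])
  }
  set.seed(as.integer(seed))
  n <- n_cases + n_controls
  phenotype <- c(rep("case", n_cases), rep("control", n_controls))

  # model calibrated before any sampling so infeasible configs fail fast
  model <- NULL
  if (!is.null(planted)) {
    pat <- enumerate_patterns()[[planted$pattern]]
    model <- calibrate_penetrance(pat, planted$maf1, planted$maf2,
                                  planted$h2, planted$prevalence)
  }

  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  geno <- matrix(0L, n, n_snps)
  for (j in seq_len(n_snps)) geno[, j] <- .draw_hwe(n, mafs[j])

  if (!is.null(planted)) {
    # retrospective rejection sampling of the planted pair
    need_case <- n_cases; need_ctrl <- n_controls
    case_g <- matrix(0L, 0L, 2L); ctrl_g <- matrix(0L, 0L, 2L)
    guard <- 0L
    while (need_case > 0L || need_ctrl > 0L) {
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed to accumulate ",
                               "cases/controls; penetrance too extreme")
      b <- max(1000L, 4L * (need_case + need_ctrl))
      g1 <- .draw_hwe(b, planted$maf1)
      g2 <- .draw_hwe(b, planted$maf2)
      black <- pat$mask[cbind(g1, g2)]
      f <- ifelse(black, model$f_black, model$f_white)
      dis <- stats::rbinom(b, 1L, f) == 1L
      if (need_case > 0L) {
        take <- which(dis)[seq_len(min(need_case, sum(dis)))]
        case_g <- rbind(case_g, cbind(g1[take], g2[take]))
        need_case <- need_case - length(take)
      }
      if (need_ctrl > 0L) {
        take <- which(!dis)[seq_len(min(need_ctrl, sum(!dis)))]
        ctrl_g <- rbind(ctrl_g, cbind(g1[take], g2[take]))
        need_ctrl <- need_ctrl - length(take)
      }
    }
    geno[, planted$snps[1]] <- c(case_g[, 1L], ctrl_g[, 1L])
    geno[, planted$snps[2]] <- c(case_g[, 2L], ctrl_g[, 2L])
    mafs[planted$snps] <- c(planted$maf1, planted$maf2)
  }

  if (missing_rate > 0) {
    drop <- stats::runif(length(geno)) < missing_rate
    geno[drop] <- 0L
  }

  # deterministic SNP metadata (one chromosome, evenly spaced loci)
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  bases <- c("A", "C", "G", "T")
  major <- sample(bases, n_snps, replace = TRUE)
  minor <- vapply(major, function(a) sample(setdiff(bases, a), 1L), "")
  gm <- genotype_matrix(
    geno, phenotype, snp_ids = snp_ids,
    snp_loci = data.frame(chrom = rep("1", n_snps),
                          pos = 1000L * seq_len(n_snps)),
    alleles = data.frame(major = major, minor = unname(minor),
                         stringsAsFactors = FALSE),
    sample_ids = sprintf("%s_%05d", ifelse(phenotype == "case", "D", "H"),
                         seq_len(n))
  )
  truth <- list(
    planted = if (is.null(planted)) NULL else
      list(snps = planted$snps, snp_ids = snp_ids[planted$snps],
           pattern = planted$pattern, model = model,
           maf1 = planted$maf1, maf2 = planted$maf2),
    mafs = mafs, seed = as.integer(seed),
    config = list(n_snps = n_snps, n_cases = n_cases,
                  n_controls = n_controls, maf_range = maf_range,
                  missing_rate = missing_rate)
  )
  structure(list(genotypes = gm, truth = truth), class = "epi_sim")
}

#' @export
print.epi_sim <- function(x, ...) {
  cat("Simulated case-control GWAS dataset\n")
  print(x$genotypes)
  if (!is.null(x$truth$planted)) {
    pl <- x$truth$planted
    cat(sprintf(
      "  planted pair: %s x %s (pattern %d, h2 = %g, prevalence K = %g)\n",
      pl$snp_ids[1], pl$snp_ids[2], pl$pattern, pl$model$h2, pl$model$K))
  } else {
    cat("  fully null (no planted interaction)\n")
  }
  invisible(x)
}

#' Write a simulated dataset to disk as text fixtures
#'
#' Emits `matrix.tsv` (the encoded genotype table), `data.ped`/`data.map`
#' (PLINK text) and `truth.json` (ground-truth record) into `dir`.  The
#' output is byte-identical for identical simulation configurations and
#' seeds.
#'
#' @param sim an `epi_sim` from [simulate_gwas()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "epi_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "matrix.tsv")
  ped <- file.path(dir, "data.ped")
  map <- file.path(dir, "data.map")
  truth <- file.path(dir, "truth.json")
  write_matrix_tsv(sim$genotypes, tsv)
  write_plink_text(sim$genotypes, ped, map)
  tr <- sim$truth
  if (!is.null(tr$planted)) tr$planted$model <- unclass(tr$planted$model)
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, ped = ped, map = map, truth = truth))
}
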