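# Case-control genotype containers and PLINK-text / TSV input-output.
#
# Genotypes are stored under the integer encoding
#   0 = missing, 1 = hom-major, 2 = het, 3 = hom-minor
# with major/minor determined per SNP from allele counts over non-missing
# calls (ties at MAF 0.5 broken toward the lexicographically smaller allele
# label, so encoding is dataset-order independent).

.MISSING_ALLELE <- "0"

#' Construct a case-control genotype matrix
#'
#' The central container of the package: an integer matrix of encoded
#' genotypes (samples x SNPs, codes 0-3) with a case/control phenotype and
#' optional SNP metadata.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns, every
#'   entry in `{0,1,2,3}` (0 = missing, 1 = hom-major, 2 = het,
#'   3 = hom-minor).
#' @param phenotype character vector (`"case"`/`"control"`), or logical
#'   (`TRUE` = case), one per sample.
#' @param snp_ids,sample_ids identifiers; default to column/row names or
#'   generated labels.
#' @param snp_loci optional data.frame with columns `chrom` and `pos`
#'   (1-based), one row per SNP.
#' @param alleles optional data.frame with columns `major` and `minor`
#'   (allele labels), one row per SNP; `NA` minor marks a monomorphic or
#'   all-missing SNP.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, phenotype, snp_ids = NULL,
                            snp_loci = NULL, alleles = NULL,
                            sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes) || !all(genotypes %in% 0:3)) {
    bad <- which(is.na(genotypes) | !(genotypes %in% 0:3), arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype code outside {0,1,2,3} at (row %d, col %d)",
                 bad[1L], bad[2L]))
  }
  if (is.logical(phenotype)) phenotype <- ifelse(phenotype, "case", "control")
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% c("case", "control"))) {
    stop("phenotype must be 'case' or 'control' for every sample")
  }
  if (length(phenotype) != nrow(genotypes)) {
    stop("phenotype length does not match the number of samples")
  }
  m <- ncol(genotypes)
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(m))
  }
  if (length(snp_ids) != m) stop("snp_ids length does not match SNP count")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(genotypes)))
  }
  if (!is.null(snp_loci)) {
    snp_loci <- as.data.frame(snp_loci)
    stopifnot(all(c("chrom", "pos") %in% names(snp_loci)),
              nrow(snp_loci) == m)
  }
  if (!is.null(alleles)) {
    alleles <- as.data.frame(alleles)
    stopifnot(all(c("major", "minor") %in% names(alleles)),
              nrow(alleles) == m)
  }
  dimnames(genotypes) <- list(sample_ids, snp_ids)
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_ids = as.character(snp_ids), sample_ids = as.character(sample_ids),
         snp_loci = snp_loci, alleles = alleles),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples (%d cases, %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == "case"),
              sum(x$phenotype == "control"), ncol(x$genotypes)))
  miss <- mean(x$genotypes == 0L)
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  if (!is.null(x$snp_loci)) {
    cat(sprintf("  loci on chromosome(s): %s\n",
                paste(unique(x$snp_loci$chrom), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Encode raw allele calls of one SNP
#'
#' Applies the genotype encoding: missing call -> 0, homozygous major -> 1,
#' heterozygous -> 2, homozygous minor -> 3.  The major allele is the more
#' frequent allele over non-missing calls; an exact 50/50 tie is broken
#' toward the lexicographically smaller allele label.  A call with either
#' allele missing (the `"0"` sentinel or `NA`) counts as missing.
#'
#' @param calls a 2-column character matrix (or data.frame) of allele
#'   labels, one row per sample.
#' @return A list with `codes` (integer vector), `major`, `minor` (allele
#'   labels; `NA` when undefined) and `defined` (FALSE when all calls are
#'   missing).
#' @export
#' @examples
#' encode_genotypes(rbind(c("A", "A"), c("A", "G"), c("G", "G"), c("0", "0")))
encode_genotypes <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) != 2L) stop("calls must have two allele columns")
  calls[is.na(calls)] <- .MISSING_ALLELE
  miss <- calls[, 1L] == .MISSING_ALLELE | calls[, 2L] == .MISSING_ALLELE
  obs <- c(calls[!miss, 1L], calls[!miss, 2L])
  if (length(obs) == 0L) {
    return(list(codes = rep(0L, nrow(calls)), major = NA_character_,
                minor = NA_character_, defined = FALSE))
  }
  tab <- table(obs)
  if (length(tab) > 2L) {
    stop(sprintf("multi-allelic SNP not supported (%d distinct alleles: %s)",
                 length(tab), paste(names(tab), collapse = ", ")))
  }
  labs <- names(tab)
  if (length(tab) == 1L) {
    major <- labs
    minor <- NA_character_
  } else if (tab[1L] != tab[2L]) {
    major <- labs[which.max(tab)]
    minor <- labs[which.min(tab)]
  } else {
    major <- min(labs)   # MAF 0.5 tie: lexicographically smaller label
    minor <- max(labs)
  }
  n_minor <- (calls[, 1L] == minor) + (calls[, 2L] == minor)
  if (is.na(minor)) n_minor <- rep(0L, nrow(calls))
  codes <- ifelse(miss, 0L, 1L + n_minor)
  list(codes = as.integer(codes), major = major, minor = minor,
       defined = TRUE)
}

# decode one column back to allele-pair calls (for the PLINK writer)
.decode_column <- function(codes, major, minor) {
  if (is.na(major)) major <- "A"
  if (is.na(minor)) minor <- "B"
  a1 <- c(.MISSING_ALLELE, major, major, minor)[codes + 1L]
  a2 <- c(.MISSING_ALLELE, major, minor, minor)[codes + 1L]
  cbind(a1, a2)
}

#' Read PLINK text pedigree files (.ped/.map)
#'
#' Parses the whitespace-separated PLINK text format: `.ped` rows are
#' `FID IID PAT MAT SEX PHENO` followed by two allele columns per SNP
#' (missing allele = `0`), phenotype coded 1 = control, 2 = case; `.map`
#' rows are `chrom snp_id [cM] pos`.  Samples with unknown phenotype
#' (0 or -9) are dropped with a message.  Genotypes are encoded via
#' [encode_genotypes()].
#'
#' @param ped_path,map_path file paths.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines) == 0L) stop(".map file is empty: ", map_path)
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nfld <- lengths(map_tok)
  if (any(!nfld %in% c(3L, 4L))) {
    stop(sprintf("malformed .map line %d: expected 3 or 4 fields, got %d",
                 which(!nfld %in% c(3L, 4L))[1L],
                 nfld[which(!nfld %in% c(3L, 4L))[1L]]))
  }
  chrom <- vapply(map_tok, `[`, "", 1L)
  snp_ids <- vapply(map_tok, `[`, "", 2L)
  pos <- as.integer(vapply(map_tok, function(x) x[length(x)], ""))
  m <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (length(ped_lines) == 0L) stop(".ped file is empty: ", ped_path)
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * m
  nfld <- lengths(ped_tok)
  if (any(nfld != want)) {
    i <- which(nfld != want)[1L]
    stop(sprintf(
      "malformed .ped line %d: expected %d fields for %d SNPs, got %d",
      i, want, m, nfld[i]))
  }
  ped <- do.call(rbind, ped_tok)
  pheno_raw <- ped[, 6L]
  known <- pheno_raw %in% c("1", "2")
  if (any(!known)) {
    message(sprintf("dropping %d sample(s) with unknown phenotype", sum(!known)))
  }
  ped <- ped[known, , drop = FALSE]
  if (nrow(ped) == 0L) stop("no samples with known phenotype in ", ped_path)
  phenotype <- ifelse(ped[, 6L] == "2", "case", "control")
  sample_ids <- ped[, 2L]

  n <- nrow(ped)
  geno <- matrix(0L, n, m)
  alleles <- data.frame(major = character(m), minor = character(m),
                        stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a1 <- ped[, 6L + 2L * j - 1L]
    a2 <- ped[, 6L + 2L * j]
    enc <- encode_genotypes(cbind(a1, a2))
    geno[, j] <- enc$codes
    alleles$major[j] <- enc$major
    alleles$minor[j] <- enc$minor
  }
  genotype_matrix(geno, phenotype, snp_ids = snp_ids,
                  snp_loci = data.frame(chrom = chrom, pos = pos,
                                        stringsAsFactors = FALSE),
                  alleles = alleles, sample_ids = sample_ids)
}

#' Write PLINK text pedigree files
#'
#' @param x a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(x, ped_path, map_path) {
  stopifnot(inherits(x, "genotype_matrix"))
  m <- ncol(x$genotypes)
  loci <- x$snp_loci
  if (is.null(loci)) {
    loci <- data.frame(chrom = rep("1", m), pos = seq_len(m))
  }
  map <- sprintf("%s\t%s\t0\t%d", loci$chrom, x$snp_ids, as.integer(loci$pos))
  writeLines(map, map_path)

  al <- x$alleles
  if (is.null(al)) al <- data.frame(major = rep("A", m), minor = rep("B", m))
  allele_cols <- matrix("", nrow(x$genotypes), 2L * m)
  for (j in seq_len(m)) {
    dec <- .decode_column(x$genotypes[, j], al$major[j], al$minor[j])
    allele_cols[, 2L * j - 1L] <- dec[, 1L]
    allele_cols[, 2L * j] <- dec[, 2L]
  }
  pheno <- ifelse(x$phenotype == "case", "2", "1")
  lead <- cbind(x$sample_ids, x$sample_ids, "0", "0", "0", pheno)
  writeLines(apply(cbind(lead, allele_cols), 1L, paste, collapse = "\t"),
             ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

.parse_status <- function(s, path = "") {
  s <- tolower(trimws(s))
  out <- rep(NA_character_, length(s))
  out[s %in% c("t", "1", "case", "true")] <- "case"
  out[s %in% c("f", "0", "control", "false")] <- "control"
  if (anyNA(out)) {
    stop(sprintf("unrecognised Status value '%s' in %s", s[which(is.na(out))[1L]],
                 path))
  }
  out
}

#' Read a pre-encoded genotype matrix from TSV
#'
#' Expects a tab-separated file with a header of SNP identifiers and a final
#' `Status` column, one row per sample, cells already coded 0-3.  An
#' optional leading `Sample` column supplies sample identifiers.  `Status`
#' accepts `T/F`, `1/0`, `case/control`.
#'
#' @param path file path.
#' @return A [genotype_matrix()] (without loci/allele metadata).
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("TSV matrix needs a header row and >=1 sample: ", path)
  tok <- strsplit(lines, "\t", fixed = TRUE)
  header <- tok[[1L]]
  if (tolower(header[length(header)]) != "status") {
    stop("last header column must be 'Status' in ", path)
  }
  has_sample_col <- tolower(header[1L]) %in% c("sample", "sample_id", "id")
  first_snp <- if (has_sample_col) 2L else 1L
  snp_ids <- header[first_snp:(length(header) - 1L)]
  m <- length(snp_ids)
  if (m < 1L) stop("no SNP columns in ", path)
  n <- length(lines) - 1L
  geno <- matrix(0L, n, m)
  status <- character(n)
  sample_ids <- sprintf("Sample_%d", seq_len(n))
  for (i in seq_len(n)) {
    fields <- tok[[i + 1L]]
    if (length(fields) != length(header)) {
      stop(sprintf("row %d of %s has %d fields, expected %d", i, path,
                   length(fields), length(header)))
    }
    if (has_sample_col) sample_ids[i] <- fields[1L]
    cells <- fields[first_snp:(length(fields) - 1L)]
    v <- suppressWarnings(as.integer(cells))
    bad <- is.na(v) | v < 0L | v > 3L
    if (any(bad)) {
      j <- which(bad)[1L]
      stop(sprintf("genotype cell '%s' outside {0,1,2,3} at (row %d, col %s)",
                   cells[j], i, snp_ids[j]))
    }
    geno[i, ] <- v
    status[i] <- fields[length(fields)]
  }
  genotype_matrix(geno, .parse_status(status, path), snp_ids = snp_ids,
                  sample_ids = sample_ids)
}

#' Write a genotype matrix as TSV
#'
#' Emits the tabular layout read back by [read_matrix_tsv()]: a `Sample`
#' column, one column of codes per SNP, and a final `Status` column (`T` for
#' cases, `F` for controls).
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  header <- paste(c("Sample", x$snp_ids, "Status"), collapse = "\t")
  status <- ifelse(x$phenotype == "case", "T", "F")
  body <- apply(cbind(x$sample_ids, x$genotypes, status), 1L, paste,
                collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
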