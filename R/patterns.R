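# Biologically plausible two-locus genotype interaction patterns.
#
# The model: each of two functional sites carries a biallelic SNP; each
# allele gives rise to one bio-molecule subtype (p_A from the major allele
# at site 1, p_a from the minor, and likewise p_B/p_b at site 2), and the
# subtypes from the two sites dock into at most four complexes.  A complex
# is disease-associated either whenever it is present ("presence"
# condition) or only when it is the sole complex formed ("solo" condition,
# which requires both loci homozygous).  Labelling the 3x3 joint-genotype
# table by whether the associated complex can form yields exactly eight
# distinct black/white masks; every other of the 2^9 labellings lacks this
# mechanistic reading.

# genotype codes over the mask domain: 1 = hom-major, 2 = het, 3 = hom-minor
.carrier_codes <- function(allele) {
  if (allele == "major") c(1L, 2L) else c(2L, 3L)
}

.homozygote_code <- function(allele) {
  if (allele == "major") 1L else 3L
}

#' Derive one genotype interaction pattern from a disease-associated complex
#'
#' Given the bio-molecule complex (which allele's product at each site forms
#' the complex) and the condition under which the complex is
#' disease-associated, construct the 3x3 black/white genotype mask over the
#' joint genotypes of the two SNPs.
#'
#' Under the `"presence"` condition the complex matters whenever it can
#' form, so every cell whose site-1 genotype carries at least one copy of
#' the first allele *and* whose site-2 genotype carries at least one copy of
#' the second allele is black (4 cells).  Under the `"solo"` condition only
#' the double homozygote for the two alleles is black (1 cell), since any
#' heterozygous site produces a competing complex.
#'
#' @param complex character vector of length 2, each element `"major"` or
#'   `"minor"`: which allele's bio-molecule at site 1 and site 2 forms the
#'   disease-associated complex.
#' @param condition `"presence"` or `"solo"`.
#' @param id optional integer identifier attached to the pattern.
#' @return An object of class `epi_pattern`: a list with elements
#'   `id`, `complex`, `condition` and `mask`, where `mask` is a 3x3 logical
#'   matrix indexed by genotype codes (1 = hom-major, 2 = het,
#'   3 = hom-minor) of SNP_i (rows) and SNP_j (columns); `TRUE` marks a
#'   black (risk-grouped) genotype.  Missing genotypes (code 0) lie outside
#'   the mask domain.
#' @seealso [enumerate_patterns()], [transpose_pattern()]
#' @export
#' @examples
#' derive_pattern(c("major", "major"), "presence")
derive_pattern <- function(complex, condition = c("presence", "solo"),
                           id = NA_integer_) {
  condition <- match.arg(condition)
  complex <- match.arg(complex[1L], c("major", "minor"), several.ok = FALSE) |>
    c(match.arg(complex[2L], c("major", "minor")))
  mask <- matrix(FALSE, 3L, 3L,
                 dimnames = list(snp_i = 1:3, snp_j = 1:3))
  if (condition == "presence") {
    mask[.carrier_codes(complex[1L]), .carrier_codes(complex[2L])] <- TRUE
  } else {
    mask[.homozygote_code(complex[1L]), .homozygote_code(complex[2L])] <- TRUE
  }
  structure(
    list(id = as.integer(id), complex = complex, condition = condition,
         mask = mask),
    class = "epi_pattern"
  )
}

#' Enumerate the eight biologically plausible interaction patterns
#'
#' Enumerates all four disease-associated complexes (major/major,
#' major/minor, minor/major, minor/minor) under both the presence and the
#' solo condition, deduplicates the resulting 3x3 masks, and returns them in
#' a fixed order: patterns 1-4 are the presence patterns and 5-8 the solo
#' patterns, complexes ordered (major,major), (major,minor), (minor,major),
#' (minor,minor).  The set is closed under transposition (swapping the two
#' SNPs), which is what makes scanning unordered SNP pairs with all eight
#' patterns exhaustive.
#'
#' @return A list of 8 [derive_pattern()] objects, class `epi_pattern_set`.
#' @export
#' @examples
#' pats <- enumerate_patterns()
#' length(pats)
enumerate_patterns <- function() {
  alleles <- c("major", "minor")
  complexes <- list()
  for (a1 in alleles) for (a2 in alleles) {
    complexes[[length(complexes) + 1L]] <- c(a1, a2)
  }
  pats <- list()
  for (cond in c("presence", "solo")) {
    for (cx in complexes) {
      cand <- derive_pattern(cx, cond, id = length(pats) + 1L)
      seen <- any(vapply(pats, function(p) identical(p$mask, cand$mask),
                         logical(1)))
      if (!seen) pats[[length(pats) + 1L]] <- cand
    }
  }
  structure(pats, class = "epi_pattern_set")
}

#' Transpose a genotype interaction pattern
#'
#' Swapping the roles of the two SNPs transposes the 3x3 mask.  The eight
#' patterns are closed under this operation, so the result is again one of
#' the eight (with its canonical id).
#'
#' @param p an `epi_pattern`.
#' @return The `epi_pattern` whose mask is `t(p$mask)`.
#' @export
transpose_pattern <- function(p) {
  stopifnot(inherits(p, "epi_pattern"))
  tm <- t(p$mask)
  dimnames(tm) <- dimnames(p$mask)
  for (q in enumerate_patterns()) {
    if (identical(unname(q$mask), unname(tm))) return(q)
  }
  # unreachable for the canonical eight; kept for safety
  structure(list(id = NA_integer_, complex = rev(p$complex),
                 condition = p$condition, mask = tm),
            class = "epi_pattern")
}

#' Tabulate the pattern set
#'
#' Flat description of the eight patterns (id, complex, condition and the
#' nine mask bits in row-major order), suitable for export as TSV/JSON and
#' for test fixtures.
#'
#' @param pats a pattern set from [enumerate_patterns()] (the default).
#' @return A data.frame with one row per pattern.
#' @export
patterns_as_table <- function(pats = enumerate_patterns()) {
  rows <- lapply(pats, function(p) {
    bits <- as.integer(t(p$mask))  # row-major
    df <- data.frame(id = p$id, site1 = p$complex[1L], site2 = p$complex[2L],
                     condition = p$condition, stringsAsFactors = FALSE)
    for (k in seq_len(9L)) df[[paste0("m", k)]] <- bits[k]
    df
  })
  do.call(rbind, rows)
}

# masks as a 3x3x8 logical array, for the counting engines
.pattern_mask_array <- function(pats = enumerate_patterns()) {
  arr <- array(FALSE, dim = c(3L, 3L, length(pats)))
  for (k in seq_along(pats)) arr[, , k] <- pats[[k]]$mask
  arr
}

# masks over raw code pairs 0..3 x 0..3 flattened as c1*4 + c2 (0-based),
# missing codes always FALSE; integer matrix 8 x 16 for the C++ engines
.pattern_mask16 <- function(pats = enumerate_patterns()) {
  m16 <- matrix(0L, nrow = length(pats), ncol = 16L)
  for (k in seq_along(pats)) {
    for (c1 in 1:3) for (c2 in 1:3) {
      if (pats[[k]]$mask[c1, c2]) m16[k, c1 * 4L + c2 + 1L] <- 1L
    }
  }
  m16
}

#' @export
print.epi_pattern <- function(x, ...) {
  cat(sprintf("Genotype interaction pattern %s: %s complex (%s, %s)\n",
              ifelse(is.na(x$id), "?", x$id), x$condition,
              x$complex[1L], x$complex[2L]))
  disp <- ifelse(x$mask, "B", ".")
  dimnames(disp) <- list(snp_i = c("hom-maj", "het", "hom-min"),
                         snp_j = c("hom-maj", "het", "hom-min"))
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
print.epi_pattern_set <- function(x, ...) {
  cat(sprintf("Set of %d genotype interaction patterns\n", length(x)))
  for (p in x) {
    cat(sprintf("  %d: %-8s (%s, %s)  black cells: %d\n", p$id, p$condition,
                p$complex[1L], p$complex[2L], sum(p$mask)))
  }
  invisible(x)
}
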