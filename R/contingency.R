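# 2x2 case/control contingency tables for SNP pairs under a pattern,
# counted naively or via a pre-computed lookup table over bit-packed
# genotype words.
#
# Each genotype code (0..3) is a 2-bit integer; p = 4 codes pack into one
# byte-valued word, so a word pair indexes a 256 x 256 table.  For every
# pattern and word pair the number of black and of mutually non-missing
# positions is pre-computed once; counting a pair's contingency table then
# reduces to summing table entries over the words of the case and control
# vectors.  A sample contributes to neither black nor white if either
# genotype is missing.

.GENOS_PER_WORD <- 4L

#' Construct a 2x2 case/control contingency table
#'
#' Counts of cases/controls falling in the black (risk-grouped) and white
#' genotype groups of a pattern: `n_db` (cases, black), `n_hb` (controls,
#' black), `n_dw` (cases, white), `n_hw` (controls, white).  Samples with a
#' missing genotype at either SNP belong to neither group.
#'
#' @param n_db,n_hb,n_dw,n_hw non-negative counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(n_db, n_hb, n_dw, n_hw) {
  counts <- c(n_db = n_db, n_hb = n_hb, n_dw = n_dw, n_hw = n_hw)
  if (any(counts < 0)) stop("contingency counts must be non-negative")
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n_db, x$n_hb, x$n_dw, x$n_hw), 2L, 2L,
              dimnames = list(c("case", "control"), c("black", "white")))
  print(m)
  invisible(x)
}

#' Pack one genotype column into case and control bit-packed vectors
#'
#' Splits the column by phenotype, preserving sample order within each
#' group, and packs every 4 genotype codes (2 bits each, little-endian
#' within the word) into one byte-valued word.  The final word is padded
#' with the missing code 0, so padding never contributes to any count.
#'
#' @param column integer vector of codes in `{0,1,2,3}`.
#' @param phenotype `"case"`/`"control"` per sample (or logical, TRUE = case).
#' @return A list of two `packed_vector` objects (`case` and `control`),
#'   each a list with `words` (integer, values 0-255), `n_genotypes` and
#'   `group`.
#' @export
pack_column <- function(column, phenotype) {
  if (is.logical(phenotype)) phenotype <- ifelse(phenotype, "case", "control")
  stopifnot(length(column) == length(phenotype))
  if (!all(column %in% 0:3)) stop("genotype codes must be in {0,1,2,3}")
  pack1 <- function(g, group) {
    n <- length(g)
    n_words <- max(1L, ceiling(n / .GENOS_PER_WORD))
    padded <- c(g, integer(n_words * .GENOS_PER_WORD - n))
    gm <- matrix(padded, nrow = .GENOS_PER_WORD)
    words <- as.integer(colSums(gm * c(1L, 4L, 16L, 64L)))
    structure(list(words = words, n_genotypes = n, group = group),
              class = "packed_vector")
  }
  list(case = pack1(as.integer(column[phenotype == "case"]), "case"),
       control = pack1(as.integer(column[phenotype == "control"]), "control"))
}

#' Unpack a packed genotype vector
#'
#' Inverse of the packing in [pack_column()]; recovers the genotype codes of
#' one phenotype group, dropping the zero padding of the final word.
#'
#' @param pv a `packed_vector`.
#' @return Integer vector of codes.
#' @export
unpack_vector <- function(pv) {
  stopifnot(inherits(pv, "packed_vector"))
  w <- pv$words
  codes <- rbind(w %% 4L, (w %/% 4L) %% 4L, (w %/% 16L) %% 4L,
                 (w %/% 64L) %% 4L)
  as.integer(codes)[seq_len(pv$n_genotypes)]
}

# word value -> 4 genotype codes, as a 256 x 4 integer matrix
.word_codes <- function() {
  w <- 0:255
  cbind(w %% 4L, (w %/% 4L) %% 4L, (w %/% 16L) %% 4L, (w %/% 64L) %% 4L)
}

#' Pre-compute the black/non-missing counts for every word pair
#'
#' For each of the 8 patterns and each ordered word-value pair
#' `(x, y)` in `0..255 x 0..255`, counts the positions where both packed
#' genotypes are non-missing and the genotype-code pair is black under the
#' pattern.  The white count of a word pair is the number of mutually
#' non-missing positions minus the black count, so only black and
#' non-missing tables are stored (8 x 65536 and 65536 entries; about 2 MiB
#' as R integers).
#'
#' @param pats pattern set, default [enumerate_patterns()].
#' @return An object of class `epi_lookup_table`: list with `black`
#'   (integer matrix, 8 x 65536, column `x*256 + y + 1`), `nonmiss`
#'   (integer vector, 65536) and `n_patterns`.
#' @export
build_lookup_table <- function(pats = enumerate_patterns()) {
  wc <- .word_codes()
  # all 65536 ordered word pairs; x varies slowest so index = x*256 + y + 1
  x <- rep(0:255, each = 256L)
  y <- rep(0:255, times = 256L)
  cx <- wc[x + 1L, , drop = FALSE]       # 65536 x 4 codes of word x
  cy <- wc[y + 1L, , drop = FALSE]
  both <- (cx != 0L) & (cy != 0L)
  nonmiss <- as.integer(rowSums(both))
  m16 <- .pattern_mask16(pats)           # 8 x 16, index c1*4 + c2 + 1
  pair_idx <- cx * 4L + cy + 1L          # 65536 x 4, values 1..16
  black <- matrix(0L, nrow = nrow(m16), ncol = length(x))
  for (t in seq_len(nrow(m16))) {
    bt <- matrix(m16[t, pair_idx], nrow = nrow(pair_idx))
    black[t, ] <- as.integer(rowSums(bt))
  }
  structure(list(black = black, nonmiss = nonmiss, n_patterns = nrow(m16)),
            class = "epi_lookup_table")
}

# session cache: the table depends only on the fixed pattern set
.lookup_cache <- new.env(parent = emptyenv())

.cached_lookup_table <- function() {
  if (is.null(.lookup_cache$table)) .lookup_cache$table <- build_lookup_table()
  .lookup_cache$table
}

#' Count a pair's contingency table by direct sample iteration
#'
#' The reference counting path: for every sample, skip it if either
#' genotype is missing, otherwise increment the cell given by its
#' case/control status and by whether the genotype pair is black under the
#' pattern.
#'
#' @param col_i,col_j integer code vectors of the two SNPs.
#' @param phenotype `"case"`/`"control"` per sample (or logical).
#' @param pattern an `epi_pattern`.
#' @return A [contingency_table()].
#' @export
count_pair_naive <- function(col_i, col_j, phenotype, pattern) {
  if (is.logical(phenotype)) phenotype <- ifelse(phenotype, "case", "control")
  if (length(col_i) != length(col_j) || length(col_i) != length(phenotype)) {
    stop("col_i, col_j and phenotype must have equal length")
  }
  ok <- col_i != 0L & col_j != 0L
  black <- logical(length(col_i))
  black[ok] <- pattern$mask[cbind(col_i[ok], col_j[ok])]
  is_case <- phenotype == "case"
  contingency_table(
    n_db = sum(ok & is_case & black),
    n_hb = sum(ok & !is_case & black),
    n_dw = sum(ok & is_case & !black),
    n_hw = sum(ok & !is_case & !black)
  )
}

#' Count a pair's contingency table through the lookup table
#'
#' Sums pre-computed black/non-missing counts over the aligned words of the
#' two SNPs' packed case vectors and, separately, their packed control
#' vectors.  Bit-identical to [count_pair_naive()] by construction.
#'
#' @param packed_i,packed_j packed pairs from [pack_column()] (lists with
#'   `case` and `control` elements) for the two SNPs.
#' @param pattern_id integer 1-8.
#' @param table a lookup table from [build_lookup_table()]; the default is
#'   built once per session and cached.
#' @return A [contingency_table()].
#' @export
count_pair_lookup <- function(packed_i, packed_j, pattern_id,
                              table = .cached_lookup_table()) {
  stopifnot(inherits(table, "epi_lookup_table"),
            pattern_id %in% seq_len(table$n_patterns))
  count_group <- function(pi, pj) {
    if (length(pi$words) != length(pj$words) ||
        pi$n_genotypes != pj$n_genotypes) {
      stop("packed vectors disagree in word count; were they packed from ",
           "the same phenotype split?")
    }
    idx <- pi$words * 256L + pj$words + 1L
    b <- sum(table$black[pattern_id, idx])
    nm <- sum(table$nonmiss[idx])
    c(black = b, white = nm - b)
  }
  ca <- count_group(packed_i$case, packed_j$case)
  co <- count_group(packed_i$control, packed_j$control)
  contingency_table(n_db = ca[["black"]], n_hb = co[["black"]],
                    n_dw = ca[["white"]], n_hw = co[["white"]])
}
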