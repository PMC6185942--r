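# shared test utilities: random fixtures and independent oracles

# random encoded genotype matrix with a balanced phenotype
random_gm <- function(n = 50, m = 10, seed = 1, missing_rate = 0.05) {
  set.seed(seed)
  g <- matrix(sample(0:3, n * m, replace = TRUE,
                     prob = c(missing_rate, (1 - missing_rate) / 3,
                              (1 - missing_rate) / 3,
                              (1 - missing_rate) / 3)), n, m)
  genotype_matrix(g, rep(c("case", "control"), length.out = n))
}

# independent contingency-table oracle: plain per-sample loop, written
# without reference to the package's counting code
oracle_table <- function(col_i, col_j, phenotype, mask) {
  counts <- c(n_db = 0, n_hb = 0, n_dw = 0, n_hw = 0)
  for (s in seq_along(col_i)) {
    if (col_i[s] == 0 || col_j[s] == 0) next
    black <- mask[col_i[s], col_j[s]]
    if (phenotype[s] == "case") {
      if (black) counts["n_db"] <- counts["n_db"] + 1
      else counts["n_dw"] <- counts["n_dw"] + 1
    } else {
      if (black) counts["n_hb"] <- counts["n_hb"] + 1
      else counts["n_hw"] <- counts["n_hw"] + 1
    }
  }
  counts
}

as_counts <- function(ct) {
  c(n_db = as.numeric(ct$n_db), n_hb = as.numeric(ct$n_hb),
    n_dw = as.numeric(ct$n_dw), n_hw = as.numeric(ct$n_hw))
}

# write a tiny ped/map fixture; returns the two paths
write_toy_ped <- function(dir, ped_lines, map_lines) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  c(ped = ped, map = map)
}

# three-gene toy annotation on two chromosomes
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("G1", "G2", "G3"),
    chrom = c("1", "1", "2"),
    start = c(1000L, 5000L, 100L),
    end = c(2000L, 6000L, 200L)
  ))
}
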