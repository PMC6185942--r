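test_that("nearest gene uses interval distance with declared tie-breaks", {
  ann <- toy_annotation()
  # inside a gene: distance 0
  hit <- nearest_gene("1", 1500, ann)
  expect_identical(hit$gene_id, "G1")
  expect_identical(hit$distance, 0)
  # boundary positions are inside (1-based inclusive)
  expect_identical(nearest_gene("1", 2000, ann)$gene_id, "G1")
  # equidistant between G1 (end 2000) and G2 (start 5000): smaller start wins
  expect_identical(nearest_gene("1", 3500, ann)$gene_id, "G1")
  expect_identical(nearest_gene("1", 3500, ann)$distance, 1500)
  # no gene on the chromosome
  expect_true(is.na(nearest_gene("7", 100, ann)$gene_id))

  # brute-force oracle over probe positions
  probes <- c(1, 999, 2500, 4999, 6001)
  for (pos in probes) {
    cand <- ann[ann$chrom == "1", ]
    d <- numeric(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      d[r] <- if (pos >= cand$start[r] && pos <= cand$end[r]) 0 else
        min(abs(pos - cand$start[r]), abs(pos - cand$end[r]))
    }
    best <- min(d)
    got <- nearest_gene("1", pos, ann)
    expect_identical(got$distance, best)
    expect_true(got$gene_id %in% cand$gene_id[d == best])
  }
})

test_that("gene networks collapse SNP pairs onto gene pairs with support", {
  ann <- toy_annotation()
  res <- data.frame(
    snp_i = c("rs1", "rs2", "rs3"), snp_j = c("rs4", "rs5", "rs6"),
    chrom_i = c("1", "1", "1"), pos_i = c(1500, 1800, 1200),
    chrom_j = c("1", "1", "1"), pos_j = c(5100, 5900, 1900),
    p = c(1e-20, 1e-15, 1e-10), improvement = c(1e6, 1e8, 1e2)
  )
  net <- infer_gene_network(res, ann)
  # rs1xrs4 and rs2xrs5 both map to G1-G2; rs3xrs6 maps to G1-G1
  e <- net$edges
  expect_identical(nrow(e), 2L)
  g12 <- e[e$gene_b == "G2", ]
  expect_identical(g12$n_support, 2L)
  expect_equal(g12$best_p, 1e-20)
  expect_equal(g12$best_improvement, 1e8)
  expect_identical(nrow(g12$support[[1]]), 2L)
  # pair mapping twice to one gene is a flagged self-loop
  loop <- e[e$gene_a == e$gene_b, ]
  expect_identical(nrow(loop), 1L)
  expect_true(loop$self_loop)

  # SNP on a gene-free chromosome is dropped with a message
  res2 <- rbind(res, data.frame(snp_i = "rs9", snp_j = "rs10",
                                chrom_i = "9", pos_i = 5, chrom_j = "1",
                                pos_j = 100, p = 1e-5, improvement = 10))
  expect_message(net2 <- infer_gene_network(res2, ann), "dropping 1")
  expect_identical(net2$n_dropped, 1L)
})

test_that("network intersection is symmetric and handles self-loops", {
  mk <- function(pairs) {
    edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                        n_support = 1L, best_p = 1e-10,
                        best_improvement = 10, stringsAsFactors = FALSE)
    edges$self_loop <- edges$gene_a == edges$gene_b
    edges$support <- replicate(nrow(edges), data.frame(
      snp_i = "x", snp_j = "y"), simplify = FALSE)
    structure(list(edges = edges, n_dropped = 0L), class = "gene_network")
  }
  na <- mk(rbind(c("A", "B"), c("B", "C"), c("C", "C")))
  nb <- mk(rbind(c("A", "B"), c("C", "C")))
  # {AB, BC, CC} n {AB, CC} dropping self-loops -> {AB}
  out <- intersect_networks(na, nb, drop_self_loops = TRUE)
  expect_identical(out$edges$gene_a, "A")
  expect_identical(out$edges$n_support, 2L)
  # keeping self-loops -> {AB, CC}
  out2 <- intersect_networks(na, nb, drop_self_loops = FALSE)
  expect_identical(nrow(out2$edges), 2L)
  # symmetry and idempotence
  out_ba <- intersect_networks(nb, na, drop_self_loops = TRUE)
  expect_identical(out$edges[c("gene_a", "gene_b", "n_support")],
                   out_ba$edges[c("gene_a", "gene_b", "n_support")])
  self <- intersect_networks(na, na, drop_self_loops = TRUE)
  expect_setequal(paste(self$edges$gene_a, self$edges$gene_b),
                  c("A B", "B C"))
  # disjoint networks intersect to nothing
  nc <- mk(rbind(c("X", "Y")))
  expect_identical(nrow(intersect_networks(na, nc)$edges), 0L)
})

test_that("network export round trips and SIF lines match edge count", {
  dir <- withr::local_tempdir()
  ann <- toy_annotation()
  res <- data.frame(
    snp_i = c("rs1", "rs3"), snp_j = c("rs4", "rs6"),
    chrom_i = "1", pos_i = c(1500, 1200),
    chrom_j = "1", pos_j = c(5100, 1900),
    p = c(1e-20, 1e-10), improvement = c(1e6, 1e2)
  )
  net <- infer_gene_network(res, ann)
  tsv <- file.path(dir, "net.tsv")
  export_network(net, tsv, "tsv", drop_self_loops = FALSE)
  back <- read_network(tsv)
  expect_identical(back$edges$gene_a, net$edges$gene_a)
  expect_identical(back$edges$n_support, net$edges$n_support)
  expect_identical(back$edges$self_loop, net$edges$self_loop)

  sif <- file.path(dir, "net.sif")
  export_network(net, sif, "sif")  # self-loops dropped by default
  expect_length(readLines(sif), sum(!net$edges$self_loop))

  # empty network exports a header-only TSV
  empty <- structure(list(edges = net$edges[0, ], n_dropped = 0L),
                     class = "gene_network")
  export_network(empty, tsv, "tsv")
  expect_length(readLines(tsv), 1L)
})

test_that("BED annotations convert to 1-based inclusive intervals", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  # BED is 0-based half-open: [999, 2000) is 1-based 1000..2000
  writeLines(c("1\t999\t2000\tG1\t0\t+",
               "1\t4999\t6000\tG2\t0\t-"), bed)
  ann <- read_gene_bed(bed)
  expect_identical(ann$start, c(1000L, 5000L))
  expect_identical(ann$end, c(2000L, 6000L))
  expect_identical(ann$gene_id, c("G1", "G2"))
})

test_that("scan hits gain loci for network inference", {
  sim <- simulate_gwas(n_snps = 20, n_cases = 200, n_controls = 200, seed = 6)
  sc <- epi_scan(sim$genotypes, p_threshold = 0.5)
  hits <- scan_loci(sc$top_p, sim$genotypes)
  expect_true(all(c("chrom_i", "pos_i", "chrom_j", "pos_j") %in% names(hits)))
  expect_identical(hits$pos_i,
                   sim$genotypes$snp_loci$pos[match(hits$snp_i,
                                                    sim$genotypes$snp_ids)])
})
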