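# Nearest-gene annotation of SNPs and gene-gene network inference from
# top-ranked SNP-SNP interactions: if SNP_i and SNP_j interact, their
# nearest genes are predicted to interact.  Networks from independent
# datasets can be intersected; self-loops (both SNPs mapping to one gene)
# are flagged and excluded from exports by default.

#' Read a gene annotation from BED
#'
#' Imports a BED file (0-based, half-open) via `rtracklayer` and converts
#' it to the package's internal 1-based inclusive interval table.  The BED
#' name column supplies the gene identifiers and must be present and
#' unique.
#'
#' @param path BED file path.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- GenomicRanges::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) {
    stop("BED gene annotation requires a name column: ", path)
  }
  ann <- data.frame(
    gene_id = as.character(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer yields 1-based inclusive
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  gene_annotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   intervals are 1-based inclusive.
#' @return The validated data.frame, class `gene_annotation`.
#' @export
gene_annotation <- function(ann) {
  ann <- as.data.frame(ann)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(ann)),
            all(ann$start <= ann$end))
  if (anyDuplicated(ann$gene_id)) stop("gene_ids must be unique")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Nearest gene to a genomic position
#'
#' Distance 0 if the position falls inside a gene interval; otherwise the
#' minimum gap to an interval endpoint on the same chromosome.  Ties are
#' broken toward the gene with the smaller start, then the
#' lexicographically smaller identifier.  Returns `NA` when the chromosome
#' carries no annotated gene.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param annotation a [gene_annotation()] table.
#' @return A list with `gene_id` and `distance` (both `NA` if no gene on
#'   the chromosome).
#' @export
nearest_gene <- function(chrom, pos, annotation) {
  stopifnot(pos >= 1, nrow(annotation) > 0)
  cand <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(gene_id = NA_character_, distance = NA_real_))
  }
  dist <- pmax(0, pmax(cand$start - pos, pos - cand$end))
  ord <- order(dist, cand$start, cand$gene_id)
  list(gene_id = cand$gene_id[ord[1L]], distance = dist[ord[1L]])
}

#' Infer a gene-gene interaction network from SNP-SNP interactions
#'
#' Maps each SNP of every interaction to its nearest gene and adds one edge
#' per mapped gene pair; multiple SNP pairs supporting the same gene pair
#' collapse onto one edge with a merged support list.  SNPs whose
#' chromosome has no annotated gene (or beyond `max_distance`, if set) are
#' dropped with a message.  Edges whose two SNPs map to the same gene are
#' flagged as self-loops.
#'
#' @param results data.frame of ranked interactions with columns `snp_i`,
#'   `snp_j`, `chrom_i`, `pos_i`, `chrom_j`, `pos_j` and optionally `p` and
#'   `improvement` (see [scan_loci()] for attaching loci to scan hits).
#' @param annotation a [gene_annotation()] table.
#' @param max_distance optional cap on SNP-to-gene distance (bp); SNPs
#'   farther from every gene are dropped.  Default `Inf` (no cap).
#' @return An object of class `gene_network`: list with `edges` (data.frame
#'   `gene_a`, `gene_b`, `n_support`, `best_p`, `best_improvement`,
#'   `self_loop`, `support` list-column of supporting SNP pairs) and
#'   `n_dropped` (interactions lost to unmappable SNPs).
#' @export
infer_gene_network <- function(results, annotation, max_distance = Inf) {
  need <- c("snp_i", "snp_j", "chrom_i", "pos_i", "chrom_j", "pos_j")
  stopifnot(all(need %in% names(results)))
  n <- nrow(results)
  gene_i <- character(n); gene_j <- character(n)
  for (k in seq_len(n)) {
    gi <- nearest_gene(results$chrom_i[k], results$pos_i[k], annotation)
    gj <- nearest_gene(results$chrom_j[k], results$pos_j[k], annotation)
    gene_i[k] <- if (!is.na(gi$distance) && gi$distance <= max_distance)
      gi$gene_id else NA_character_
    gene_j[k] <- if (!is.na(gj$distance) && gj$distance <= max_distance)
      gj$gene_id else NA_character_
  }
  mappable <- !is.na(gene_i) & !is.na(gene_j)
  if (any(!mappable)) {
    message(sprintf("dropping %d interaction(s) with unmappable SNPs",
                    sum(!mappable)))
  }
  res <- results[mappable, , drop = FALSE]
  gene_i <- gene_i[mappable]; gene_j <- gene_j[mappable]
  # unordered edge key
  ga <- pmin(gene_i, gene_j); gb <- pmax(gene_i, gene_j)
  key <- paste(ga, gb, sep = "\r")
  p <- if ("p" %in% names(res)) res$p else rep(NA_real_, nrow(res))
  imp <- if ("improvement" %in% names(res)) res$improvement else
    rep(NA_real_, nrow(res))
  ukey <- sort(unique(key))
  edges <- data.frame(
    gene_a = vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 1L),
    gene_b = vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  edges$n_support <- as.integer(table(key)[ukey])
  edges$best_p <- vapply(ukey, function(k) suppressWarnings(
    min(p[key == k], na.rm = TRUE)), 0)
  edges$best_improvement <- vapply(ukey, function(k) suppressWarnings(
    max(imp[key == k], na.rm = TRUE)), 0)
  edges$best_p[!is.finite(edges$best_p)] <- NA_real_
  edges$best_improvement[!is.finite(edges$best_improvement)] <- NA_real_
  edges$self_loop <- edges$gene_a == edges$gene_b
  edges$support <- lapply(ukey, function(k) {
    data.frame(snp_i = res$snp_i[key == k], snp_j = res$snp_j[key == k],
               stringsAsFactors = FALSE)
  })
  rownames(edges) <- NULL
  structure(list(edges = edges, n_dropped = sum(!mappable)),
            class = "gene_network")
}

#' Attach SNP loci to scan hits
#'
#' Joins the `chrom_i/pos_i/chrom_j/pos_j` columns needed by
#' [infer_gene_network()] onto a data.frame of scan hits, using the locus
#' metadata of the scanned genotype matrix.
#'
#' @param hits data.frame with `snp_i`, `snp_j` columns of SNP identifiers.
#' @param x the [genotype_matrix()] that was scanned (must carry
#'   `snp_loci`).
#' @return `hits` with the four locus columns appended.
#' @export
scan_loci <- function(hits, x) {
  stopifnot(inherits(x, "genotype_matrix"), !is.null(x$snp_loci))
  loc <- x$snp_loci
  ii <- match(hits$snp_i, x$snp_ids)
  jj <- match(hits$snp_j, x$snp_ids)
  if (anyNA(ii) || anyNA(jj)) stop("hit SNP ids not found in the matrix")
  hits$chrom_i <- loc$chrom[ii]; hits$pos_i <- loc$pos[ii]
  hits$chrom_j <- loc$chrom[jj]; hits$pos_j <- loc$pos[jj]
  hits
}

#' Intersect two gene networks
#'
#' Keeps the edges (unordered gene pairs) present in both networks, merging
#' their supports; optionally removes self-loops.
#'
#' @param net_a,net_b `gene_network` objects.
#' @param drop_self_loops remove self-loop edges from the result.
#' @return A `gene_network` with the common edges.
#' @export
intersect_networks <- function(net_a, net_b, drop_self_loops = TRUE) {
  stopifnot(inherits(net_a, "gene_network"), inherits(net_b, "gene_network"))
  ea <- net_a$edges; eb <- net_b$edges
  ka <- paste(ea$gene_a, ea$gene_b, sep = "\r")
  kb <- paste(eb$gene_a, eb$gene_b, sep = "\r")
  common <- intersect(ka, kb)
  ea <- ea[match(common, ka), , drop = FALSE]
  eb <- eb[match(common, kb), , drop = FALSE]
  out <- ea
  if (length(common) > 0L) {
    out$n_support <- ea$n_support + eb$n_support
    out$best_p <- pmin(ea$best_p, eb$best_p, na.rm = TRUE)
    out$best_improvement <- pmax(ea$best_improvement, eb$best_improvement,
                                 na.rm = TRUE)
    out$support <- mapply(rbind, ea$support, eb$support, SIMPLIFY = FALSE)
  }
  if (drop_self_loops) out <- out[!out$self_loop, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(edges = out, n_dropped = 0L), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  e <- x$edges
  cat(sprintf("gene network: %d edge(s) over %d gene(s)", nrow(e),
              length(unique(c(e$gene_a, e$gene_b)))))
  if (any(e$self_loop)) cat(sprintf(" (%d self-loop(s))", sum(e$self_loop)))
  cat("\n")
  if (nrow(e) > 0L) {
    print(utils::head(e[, c("gene_a", "gene_b", "n_support", "best_p",
                            "best_improvement", "self_loop")], 10L),
          digits = 4)
  }
  invisible(x)
}

#' Export a gene network
#'
#' `"tsv"` writes an edge table (gene_a, gene_b, n_support, best_p,
#' best_improvement, self_loop); `"sif"` writes Cytoscape SIF lines
#' (`gene_a interacts gene_b`).  Edges are ordered lexicographically and
#' self-loops are excluded by default.
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @param drop_self_loops exclude flagged self-loops (default TRUE).
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("tsv", "sif"),
                           drop_self_loops = TRUE) {
  format <- match.arg(format)
  e <- net$edges
  if (drop_self_loops) e <- e[!e$self_loop, , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  if (format == "tsv") {
    cols <- c("gene_a", "gene_b", "n_support", "best_p", "best_improvement",
              "self_loop")
    utils::write.table(e[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(sprintf("%s\tinteracts\t%s", e$gene_a, e$gene_b), path)
  }
  invisible(path)
}

#' Read a gene network edge table written by [export_network()]
#'
#' @param path TSV path.
#' @return A `gene_network` (without support lists).
#' @export
read_network <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(e)))
  if (is.null(e$self_loop)) e$self_loop <- e$gene_a == e$gene_b
  e$support <- replicate(nrow(e), NULL, simplify = FALSE)
  structure(list(edges = e, n_dropped = 0L), class = "gene_network")
}
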