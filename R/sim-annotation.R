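#' Simulate gene models on the synthetic chromosomes
#'
#' Emits non-pathological gene models on both strands of the configured
#' chromosomes, a configurable fraction named with the uncharacterised
#' `LOC...` convention, each with 1-5 exons.  Inter-gene gaps are drawn from
#' a mixture that includes gaps of 11-18 kb, so neighbouring genes routinely
#' have overlapping 10-kb up/downstream windows -- the ambiguous case the
#' annotation tie-break rules must resolve.
#'
#' @param config a [sim_config()] object (`n_genes`, `fraction_loc`,
#'   `chrom_lengths`).
#' @return a `gene_models` object: list with `genes` (one row per gene:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `characterized`)
#'   and `exons` (`gene_id`, `start`, `end`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_child_seed(config, "annotation", {
    chroms <- names(config$chrom_lengths)
    per_chrom <- table(factor(sample(chroms, config$n_genes, replace = TRUE,
                                     prob = config$chrom_lengths),
                              levels = chroms))
    genes <- list(); exons <- list(); gid <- 0L
    for (ch in chroms) {
      cursor <- 1L
      for (g in seq_len(per_chrom[[ch]])) {
        gap <- if (runif(1) < 0.35) runif(1, 11000, 18000) else runif(1, 22000, 60000)
        len <- runif(1, 2000, 15000)
        start <- as.integer(cursor + gap)
        end <- as.integer(start + len)
        if (end + 1000 > config$chrom_lengths[[ch]]) break
        cursor <- end
        gid <- gid + 1L
        strand <- sample(c("+", "-"), 1L)
        characterized <- runif(1) >= config$fraction_loc
        gene_id <- if (characterized) sprintf("GENE%03d", gid)
                   else sprintf("LOC1%05d", gid)
        n_ex <- sample(1:5, 1L)
        ex <- gene_exons(start, end, n_ex)
        genes[[gid]] <- data.frame(
          gene_id = gene_id, chrom = ch, strand = strand,
          start = start, end = end,
          tss = if (strand == "+") start else end,
          characterized = characterized, stringsAsFactors = FALSE)
        exons[[gid]] <- data.frame(gene_id = gene_id, start = ex$start,
                                   end = ex$end, stringsAsFactors = FALSE)
      }
    }
    gene_models(do.call(rbind, genes), do.call(rbind, exons))
  })
}

# split [start, end] into n_ex exons separated by interior gaps; the first
# exon starts at `start` and the last ends at `end`
gene_exons <- function(start, end, n_ex) {
  if (n_ex == 1L) return(data.frame(start = start, end = end))
  cuts <- sort(sample(seq(start + 1L, end - 1L), 2L * (n_ex - 1L)))
  starts <- c(start, cuts[seq(2, length(cuts), 2)] + 1L)
  ends <- c(cuts[seq(1, length(cuts), 2)], end)
  keep <- starts <= ends
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Gene-model container
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `characterized` (`tss` derived if absent: 5' end on the
#'   gene's own strand).
#' @param exons `data.frame` with `gene_id`, `start`, `end`.
#' @return a validated `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end",
                  "characterized") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(genes$start > genes$end)) stop("gene start > end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  gi <- match(exons$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("exon references unknown gene id")
  if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi]))
    stop("exon outside gene span for gene ", exons$gene_id[
      which(exons$start < genes$start[gi] | exons$end > genes$end[gi])[1]])
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes (",
      sum(!x$genes$characterized), "uncharacterised ) on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Coordinates are 1-based inclusive.  Gene features carry `ID` and `Name`;
#' exons carry `Parent`.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  e <- models$exons
  gi <- match(e$gene_id, g$gene_id)
  lines <- c("##gff-version 3",
             sprintf("%s\tnestmeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id),
             sprintf("%s\tnestmeth\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                     g$chrom[gi], e$start, e$end, g$strand[gi], e$gene_id,
                     seq_len(nrow(e)), e$gene_id))
  writeLines(lines, path)
  invisible(path)
}
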