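#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (1-based, inclusive coordinates) via
#' rtracklayer.  The gene identifier is taken from the `ID`, `Name` or
#' `gene_id` attribute, in that order; exons are matched to genes through
#' `Parent`.  Introns are derived downstream as the gaps between a gene's
#' exons.  A gene is flagged uncharacterised when its name follows the
#' `LOC...` convention.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  pick <- function(i, fields) {
    for (f in fields) {
      v <- md[[f]]
      if (!is.null(v)) {
        vi <- if (inherits(v, "List") || is.list(v)) {
          el <- v[[i]]
          if (length(el)) el[1] else NA_character_
        } else as.character(v[i])
        if (!is.na(vi) && nzchar(vi)) return(vi)
      }
    }
    NA_character_
  }
  types <- as.character(md$type)
  gi <- which(types == "gene")
  if (!length(gi)) stop("no gene features in ", path)
  ids <- vapply(gi, pick, "", fields = c("ID", "Name", "gene_id"))
  if (anyNA(ids)) stop("gene feature without ID/Name/gene_id attribute")
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    start = GenomicRanges::start(gr)[gi],
    end = GenomicRanges::end(gr)[gi],
    characterized = !grepl("^LOC", ids),
    stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene feature with unstranded coordinates: ",
         genes$gene_id[!genes$strand %in% c("+", "-")][1])
  ei <- which(types == "exon")
  parents <- vapply(ei, pick, "", fields = c("Parent"))
  exons <- data.frame(gene_id = parents,
                      start = GenomicRanges::start(gr)[ei],
                      end = GenomicRanges::end(gr)[ei],
                      stringsAsFactors = FALSE)
  exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
  # genes without annotated exons are treated as single-exon
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) {
    mi <- match(missing_ex, genes$gene_id)
    exons <- rbind(exons, data.frame(gene_id = missing_ex,
                                     start = genes$start[mi],
                                     end = genes$end[mi],
                                     stringsAsFactors = FALSE))
  }
  gene_models(genes, exons)
}

REGION_PRIORITY <- c("TSS", "promoter", "exon", "intron",
                     "upstream", "downstream")

# strand-aware windows for one gene; closed 1-based intervals.
# "upstream" is 5' of the gene body on the gene's own strand.
gene_windows <- function(g, tss_up = 300, tss_down = 50,
                         prom_up = 2000, prom_down = 200, flank = 10000) {
  if (g$strand == "+") {
    list(TSS = c(g$tss - tss_up, g$tss + tss_down),
         promoter = c(g$tss - prom_up, g$tss + prom_down),
         body = c(g$start, g$end),
         upstream = c(g$start - flank, g$start - 1),
         downstream = c(g$end + 1, g$end + flank))
  } else {
    list(TSS = c(g$tss - tss_down, g$tss + tss_up),
         promoter = c(g$tss - prom_down, g$tss + prom_up),
         body = c(g$start, g$end),
         upstream = c(g$end + 1, g$end + flank),
         downstream = c(g$start - flank, g$start - 1))
  }
}

# distance from a position to the gene body (0 inside)
body_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos > end, pos - end, 0L))
}

#' Assign a CpG site to a genomic region and gene
#'
#' Region classes, in priority order: TSS region (300 bp upstream to 50 bp
#' downstream of the transcription start, on the gene's own strand),
#' promoter (2000 bp upstream to 200 bp downstream of the TSS), gene body
#' (exon or intron), then the 10-kb upstream and downstream flanks.  A site
#' matching several genes in the same class goes to the gene with the
#' nearest TSS.  Up- and downstream candidates form a single tier resolved
#' by the flank tie-break -- characterised genes first, then smallest
#' distance to the gene body, then lexicographic gene id -- so a
#' characterised gene's downstream flank beats an uncharacterised gene's
#' upstream flank.  A site matching nothing is intergenic.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param models a [gene_models()] object.
#' @return one-row `data.frame`: `region` (one of TSS, promoter, exon,
#'   intron, upstream, downstream, intergenic), `gene_id` (`NA` when
#'   intergenic), `distance` (bp to the gene body, 0 inside).
#' @export
assign_region <- function(chrom, pos, models) {
  annotate_all(data.frame(chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE), models)$assignments
}

#' Annotate many CpG sites against gene models
#'
#' Vectorized [assign_region()] over a site table, using an interval index
#' (GenomicRanges) over all gene windows; returns per-region counts along
#' with the assignments.
#'
#' @param sites `data.frame` with `chrom` and `pos` columns (a
#'   [methylation_matrix()]`$sites` table works directly).
#' @param models a [gene_models()] object.
#' @return list with `assignments` (one row per site: `region`, `gene_id`,
#'   `distance`) and `counts` (named per-region site counts).
#' @export
annotate_all <- function(sites, models) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)),
            inherits(models, "gene_models"))
  genes <- models$genes[order(models$genes$gene_id), , drop = FALSE]
  exons <- models$exons
  ns <- nrow(sites)

  # window table: one row per (gene, region class)
  wins <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    w <- gene_windows(g)
    data.frame(gene = i, chrom = g$chrom,
               class = c("TSS", "promoter", "body", "upstream", "downstream"),
               start = pmax(1L, vapply(w, `[`, 0, 1)),
               end = vapply(w, `[`, 0, 2), stringsAsFactors = FALSE)
  }))
  wins <- wins[wins$end >= wins$start, , drop = FALSE]

  chrom_universe <- union(unique(wins$chrom), unique(sites$chrom))
  wgr <- GenomicRanges::GRanges(
    factor(wins$chrom, chrom_universe),
    IRanges::IRanges(wins$start, wins$end))
  sgr <- GenomicRanges::GRanges(
    factor(sites$chrom, chrom_universe),
    IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(sgr, wgr)
  hs <- S4Vectors::queryHits(hits)
  hw <- S4Vectors::subjectHits(hits)

  region <- rep("intergenic", ns)
  gene_id <- rep(NA_character_, ns)
  distance <- rep(NA_integer_, ns)

  class_rank <- c(TSS = 1, promoter = 2, body = 3, updown = 4)
  for (s in unique(hs)) {
    wi <- hw[hs == s]
    cand <- wins[wi, , drop = FALSE]
    g <- genes[cand$gene, , drop = FALSE]
    tier <- ifelse(cand$class %in% c("upstream", "downstream"),
                   "updown", cand$class)
    best_tier <- min(class_rank[tier])
    in_tier <- which(class_rank[tier] == best_tier)
    cand <- cand[in_tier, , drop = FALSE]
    g <- g[in_tier, , drop = FALSE]
    pos <- sites$pos[s]
    if (best_tier < 4) {
      # same-class candidates: nearest TSS wins
      pick <- which.min(abs(g$tss - pos))
      gene <- g[pick, ]
      reg <- cand$class[pick]
      if (reg == "body") {
        ex <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
        reg <- if (any(pos >= ex$start & pos <= ex$end)) "exon" else "intron"
      }
    } else {
      # up/down tier: characterised first, then nearest gene body, then id
      d <- body_distance(pos, g$start, g$end)
      ord <- order(!g$characterized, d, g$gene_id)
      pick <- ord[1]
      gene <- g[pick, ]
      reg <- cand$class[pick]
    }
    region[s] <- reg
    gene_id[s] <- gene$gene_id
    distance[s] <- body_distance(pos, gene$start, gene$end)
  }

  assignments <- data.frame(chrom = sites$chrom, pos = sites$pos,
                            region = region, gene_id = gene_id,
                            distance = distance, stringsAsFactors = FALSE)
  counts <- table(factor(region, levels = c(REGION_PRIORITY, "intergenic")))
  list(assignments = assignments, counts = counts)
}
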