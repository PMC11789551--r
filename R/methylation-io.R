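#' Read and write methylation count tables
#'
#' Tab-delimited format: columns `chrom`, `pos` (1-based), `strand`, then
#' two columns per individual named `<id>.meth` and `<id>.cov`.  Missing
#' observations are empty fields (written as `NA`).  On reading, counts are
#' validated cell-wise (`0 <= meth <= cov`, `cov >= 1`); violations abort
#' with the offending row and column named.
#'
#' @param path file path.
#' @param matrix a [methylation_matrix()].
#' @return `read_methylation` returns a `methylation_matrix`.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("chrom", "pos", "strand")
  if (!all(fixed %in% names(tab)))
    stop("methylation table must start with columns chrom, pos, strand")
  rest <- setdiff(names(tab), fixed)
  meth_cols <- grep("\\.meth$", rest, value = TRUE)
  ids <- sub("\\.meth$", "", meth_cols)
  cov_cols <- paste0(ids, ".cov")
  if (!all(cov_cols %in% rest))
    stop("every <id>.meth column needs a matching <id>.cov column")
  meth <- as.matrix(tab[meth_cols])
  cov <- as.matrix(tab[cov_cols])
  if (!is.numeric(meth) || !is.numeric(cov))
    stop("non-numeric counts in methylation table")
  bad <- which(!is.na(meth) & !is.na(cov) & meth > cov, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("methylated count exceeds coverage at line %d (site %s:%s), individual '%s'",
                 bad[1, 1] + 1L, tab$chrom[bad[1, 1]], tab$pos[bad[1, 1]],
                 ids[bad[1, 2]]))
  half <- xor(is.na(meth), is.na(cov))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)
    stop(sprintf("half-missing cell at line %d, individual '%s'",
                 w[1, 1] + 1L, ids[w[1, 2]]))
  }
  methylation_matrix(tab[fixed], ids, meth, cov)
}

#' @rdname read_methylation
#' @export
write_methylation <- function(matrix, path) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  out <- matrix$sites
  for (i in seq_along(matrix$individuals)) {
    id <- matrix$individuals[i]
    out[[paste0(id, ".meth")]] <- matrix$meth[, i]
    out[[paste0(id, ".cov")]] <- matrix$cov[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge complementary CpG strands
#'
#' A CpG dinucleotide is measured on both strands: the `+` strand cytosine
#' at position `k` pairs with the `-` strand cytosine at `k + 1`.  Counts of
#' such pairs are summed cell-wise (treating a missing half as zero reads;
#' both halves missing stays missing) and reported at the `+` strand
#' position with strand `"merged"`.  Unpaired sites pass through with their
#' counts unchanged; an unpaired `-` site is reported at `pos - 1`, the
#' position of the `+` strand C of its dinucleotide.  Total read counts are
#' conserved.
#'
#' @param matrix a [methylation_matrix()] with strands `+` / `-`.
#' @return a merged `methylation_matrix` (all strands `"merged"`).
#' @export
merge_complementary_cpgs <- function(matrix) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  s <- matrix$sites
  if (any(s$strand == "merged"))
    stop("matrix already contains merged sites")
  key <- paste0(s$chrom, ":", ifelse(s$strand == "-", s$pos - 1L, s$pos))
  groups <- split(seq_len(nrow(s)), key)
  n_out <- length(groups)
  meth <- matrix(NA_real_, n_out, length(matrix$individuals))
  cov <- matrix(NA_real_, n_out, length(matrix$individuals))
  chrom <- character(n_out); pos <- integer(n_out)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    plus <- rows[s$strand[rows] == "+"]
    chrom[g] <- s$chrom[rows[1]]
    # report at the + strand C of the dinucleotide
    pos[g] <- if (length(plus)) s$pos[plus[1]] else s$pos[rows[1]] - 1L
    m <- matrix$meth[rows, , drop = FALSE]
    n <- matrix$cov[rows, , drop = FALSE]
    all_na <- colSums(!is.na(n)) == 0L
    meth[g, ] <- ifelse(all_na, NA_real_, colSums(m, na.rm = TRUE))
    cov[g, ] <- ifelse(all_na, NA_real_, colSums(n, na.rm = TRUE))
  }
  methylation_matrix(
    data.frame(chrom = chrom, pos = pos, strand = "merged",
               stringsAsFactors = FALSE),
    matrix$individuals, meth, cov)
}
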