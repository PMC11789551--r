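#' Construct a per-CpG methylation count matrix
#'
#' The container every stage of the pipeline operates on: an ordered table
#' of CpG sites, an ordered vector of individual ids, and two aligned
#' integer matrices of methylated counts and total coverage (methylated +
#' unmethylated reads).  Missing observations are `NA` in both matrices.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based),
#'   `strand` (`"+"`, `"-"` or `"merged"`).
#' @param individuals character vector of unique individual ids.
#' @param meth,cov numeric matrices, sites x individuals; `meth <= cov`
#'   cell-wise, `cov >= 1` where non-missing.
#' @return an object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(sites, individuals, meth, cov) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand") %in% names(sites)),
            nrow(meth) == nrow(sites), ncol(meth) == length(individuals),
            all(dim(meth) == dim(cov)))
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (!all(sites$strand %in% c("+", "-", "merged")))
    stop("strand must be '+', '-' or 'merged'")
  miss_ok <- is.na(meth) == is.na(cov)
  if (!all(miss_ok)) stop("meth and cov must share the same missing cells")
  bad <- which(!is.na(meth) & (meth > cov | meth < 0 | cov < 1))
  if (length(bad))
    stop("invalid counts (need 0 <= meth <= cov, cov >= 1) in ",
         length(bad), " cell(s); first at matrix index ", bad[1])
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  meth <- meth[ord, , drop = FALSE]
  cov <- cov[ord, , drop = FALSE]
  dimnames(meth) <- dimnames(cov) <-
    list(site_label(sites), individuals)
  structure(list(sites = sites, individuals = individuals,
                 meth = meth, cov = cov),
            class = "methylation_matrix")
}

site_label <- function(sites) paste0(sites$chrom, ":", sites$pos)

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("<methylation_matrix>", nrow(x$sites), "sites x",
      length(x$individuals), "individuals;",
      sum(is.na(x$meth)), "missing cells\n")
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$meth)

n_sites <- function(m) nrow(m$sites)

subset_sites <- function(m, keep) {
  methylation_matrix(m$sites[keep, , drop = FALSE], m$individuals,
                     m$meth[keep, , drop = FALSE],
                     m$cov[keep, , drop = FALSE])
}
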