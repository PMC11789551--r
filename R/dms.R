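#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' returned in input order (delegates to [stats::p.adjust()]).  `NaN`
#' input is an error; the genome-wide scan treats untested sites
#' explicitly rather than feeding them in as missing.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p))) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Keep values inside the empirical highest density interval
#'
#' Computes the shortest contiguous window of the sorted values containing
#' `ceiling(mass * n)` of them (the sample HDI; ties between equally short
#' windows break towards the lower window start) and returns the indices of
#' values lying inside the closed interval.  Used to drop CpG sites whose
#' Pearson dispersion statistic is extreme relative to the genome-wide
#' distribution -- the overdispersion correction of the scan.
#'
#' @param x numeric vector (at least 20 values).
#' @param mass probability mass of the interval, in (0, 1).
#' @return list with `keep` (integer indices into `x` inside the HDI),
#'   `interval` (the closed `[lo, hi]` window).
#' @export
hdi_exclude <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  n <- length(x)
  if (n < 20) stop("need at least 20 values to estimate the HDI")
  if (any(!is.finite(x))) stop("non-finite dispersion values")
  s <- sort(x)
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- starts[which.min(widths)]      # which.min takes the first (lowest) tie
  lo <- s[i]; hi <- s[i + k - 1L]
  list(keep = which(x >= lo & x <= hi), interval = c(lo, hi))
}

#' Categorize a sex-specific differentially methylated site
#'
#' Applies the category rules for sites with a significant
#' treatment-by-sex interaction, based on the FDR-corrected within-sex
#' treatment contrasts: significant in females only gives
#' `female_specific`; in males only, `male_specific`; in both sexes with
#' opposite directions, `antagonistic`; in both sexes with the same
#' direction, `concordant` (an explicit extension -- the four classical
#' categories leave this combination undefined, and silently misfiling it
#' would corrupt the counts); in neither sex but with some other cell
#' contrast significant (e.g. testosterone-treated females vs control
#' males), `other`; otherwise `unclassified`.
#'
#' @param sig_f,sig_m logical; within-sex treatment contrast significant
#'   (q below the FDR threshold) in females / males.
#' @param dir_f,dir_m direction of the within-sex logit-scale
#'   testosterone-minus-control contrast, `"up"` or `"down"`; required
#'   whenever the corresponding significance flag is set.
#' @param other_sig logical; any other cell contrast significant.
#' @return one of `"female_specific"`, `"male_specific"`, `"antagonistic"`,
#'   `"concordant"`, `"other"`, `"unclassified"`.
#' @export
categorize_dms <- function(sig_f, sig_m, dir_f = NA, dir_m = NA,
                           other_sig = FALSE) {
  stopifnot(is.logical(sig_f), is.logical(sig_m))
  if (sig_f && (is.na(dir_f) || !dir_f %in% c("up", "down")))
    stop("dir_f must be 'up' or 'down' when sig_f is TRUE")
  if (sig_m && (is.na(dir_m) || !dir_m %in% c("up", "down")))
    stop("dir_m must be 'up' or 'down' when sig_m is TRUE")
  if (sig_f && !sig_m) return("female_specific")
  if (sig_m && !sig_f) return("male_specific")
  if (sig_f && sig_m) {
    return(if (dir_f != dir_m) "antagonistic" else "concordant")
  }
  if (isTRUE(other_sig)) "other" else "unclassified"
}
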