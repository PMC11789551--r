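#' Mask observations with out-of-range coverage
#'
#' Cells with coverage below `min_cov`, or above the per-individual
#' `pct_cap` percentile of that individual's non-missing coverages, become
#' missing.  The percentile cap is computed per individual with
#' linear-interpolation quantiles (the usual guard against PCR-duplicate
#' towers in reduced-representation bisulfite data); both thresholds are
#' recorded in the report.
#'
#' @param matrix a [methylation_matrix()].
#' @param min_cov minimum coverage; cells with `cov < min_cov` are masked
#'   (strict inequality: a cell at exactly `min_cov` is retained).
#' @param pct_cap percentile (in percent) above which cells are masked.
#' @param caps optional named vector of fixed per-individual caps (e.g.
#'   from a previous report): the percentile cap is data-relative, so
#'   re-running the mask is guaranteed a no-op only when the recorded caps
#'   are reused.
#' @return list with `matrix` (masked) and `report` (a `filter_report`).
#' @export
apply_coverage_mask <- function(matrix, min_cov = 10, pct_cap = 99.9,
                                caps = NULL) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  cov <- matrix$cov
  if (is.null(caps)) {
    caps <- apply(cov, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) Inf else quantile(x, pct_cap / 100, type = 7,
                                        names = FALSE)
    })
  } else {
    caps <- caps[matrix$individuals]
    if (anyNA(caps)) stop("caps must name every individual in the matrix")
  }
  low <- !is.na(cov) & cov < min_cov
  high <- !is.na(cov) & sweep(cov, 2, caps, ">")
  mask <- low | high
  meth <- matrix$meth; covm <- cov
  meth[mask] <- NA; covm[mask] <- NA
  report <- filter_report(
    stage = "coverage_mask",
    thresholds = list(min_cov = min_cov, pct_cap = pct_cap,
                      per_individual_cap = setNames(as.numeric(caps),
                                                    matrix$individuals)),
    input = list(cells = sum(!is.na(cov))),
    removed = list(cells_low_coverage = sum(low),
                   cells_high_coverage = sum(high & !low)),
    retained = list(cells = sum(!is.na(cov)) - sum(mask)))
  list(matrix = methylation_matrix(matrix$sites, matrix$individuals,
                                   meth, covm),
       report = report)
}

#' Discard CpG sites by coverage breadth and mean methylation
#'
#' A site is retained only if it has at least `min_per_treatment`
#' non-missing observations in each treatment group, and the unweighted
#' mean of per-individual methylation proportions (`meth / cov`) across all
#' non-missing cells lies within `[mean_lo, mean_hi]` (sites with nearly
#' invariant methylation carry no usable signal for a binomial model).
#'
#' @param matrix a [methylation_matrix()] (after [apply_coverage_mask()]).
#' @param design a design table covering all individuals in `matrix`.
#' @param min_per_treatment minimum non-missing individuals per treatment.
#' @param mean_lo,mean_hi retained range of mean methylation (inclusive).
#' @return list with `matrix` (sites dropped) and `report`.
#' @export
filter_sites <- function(matrix, design, min_per_treatment = 15,
                         mean_lo = 0.05, mean_hi = 0.95) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  validate_design(design)
  idx <- match(matrix$individuals, design$individual)
  if (anyNA(idx)) stop("design does not cover all individuals in matrix")
  trt <- design$treatment[idx]
  obs <- !is.na(matrix$cov)
  n_ctrl <- rowSums(obs[, trt == "control", drop = FALSE])
  n_test <- rowSums(obs[, trt == "testosterone", drop = FALSE])
  prop <- matrix$meth / matrix$cov
  mean_meth <- rowMeans(prop, na.rm = TRUE)
  fail_breadth <- n_ctrl < min_per_treatment | n_test < min_per_treatment
  fail_mean <- !is.nan(mean_meth) & (mean_meth < mean_lo | mean_meth > mean_hi)
  fail_mean[is.nan(mean_meth)] <- TRUE   # no observations at all
  keep <- !fail_breadth & !fail_mean
  report <- filter_report(
    stage = "site_filter",
    thresholds = list(min_per_treatment = min_per_treatment,
                      mean_lo = mean_lo, mean_hi = mean_hi),
    input = list(sites = n_sites(matrix)),
    removed = list(sites_low_breadth = sum(fail_breadth),
                   sites_extreme_mean = sum(fail_mean & !fail_breadth)),
    retained = list(sites = sum(keep)))
  list(matrix = subset_sites(matrix, keep), report = report)
}

#' Filter accounting record
#'
#' Per-rule removal counts with the thresholds used; `removed + retained`
#' always reconciles with the input totals (checked at construction).
#'
#' @param stage character label.
#' @param thresholds,input,removed,retained named lists.
#' @return a `filter_report` object.
#' @export
filter_report <- function(stage, thresholds, input, removed, retained) {
  total_in <- sum(unlist(input))
  if (sum(unlist(removed)) + sum(unlist(retained)) != total_in)
    stop("filter report does not reconcile: removed + retained != input")
  structure(list(stage = stage, thresholds = thresholds, input = input,
                 removed = removed, retained = retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$stage, "| input:", sum(unlist(x$input)),
      "| removed:", sum(unlist(x$removed)), "\n")
  for (nm in names(x$removed)) cat("  ", nm, ":", x$removed[[nm]], "\n")
  invisible(x)
}

#' @param report a `filter_report`.
#' @param path output JSON path.
#' @rdname filter_report
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
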