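#' Likelihood-ratio test between nested mixed-model fits
#'
#' `statistic = 2 (logLik_full - logLik_reduced)`, floored at zero to
#' absorb numerical noise, referred to a chi-square with degrees of freedom
#' equal to the difference in fixed-effect counts.  Both fits must be
#' converged, on the same data, with the reduced fixed effects nested in
#' the full ones.
#'
#' @param fit_full,fit_reduced fits from [fit_glmm()] or [fit_lmm()].
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  if (!isTRUE(fit_full$converged) || !isTRUE(fit_reduced$converged))
    stop("likelihood-ratio test requires two converged fits")
  if (fit_full$n_obs != fit_reduced$n_obs ||
      !isTRUE(all.equal(fit_full$response_checksum,
                        fit_reduced$response_checksum)))
    stop("fits are not on the same data")
  if (!all(names(fit_reduced$beta) %in% names(fit_full$beta)))
    stop("reduced model is not nested in the full model")
  df <- fit_full$p_fixed - fit_reduced$p_fixed
  if (df < 1) stop("models have the same number of fixed effects")
  statistic <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE))
}

#' Pearson dispersion statistic of a binomial GLMM fit
#'
#' `phi = sum((m - n p)^2 / (n p (1 - p))) / (N - p_fixed)` with `p` the
#' conditional (random-effect-including) fitted proportions, clamped away
#' from 0/1.  Under a correctly specified binomial model `phi` is near 1;
#' values well above 1 indicate extra-binomial variation, and the
#' genome-wide scan excludes sites whose `phi` falls outside the highest
#' density interval of the per-site distribution (see [hdi_exclude()]).
#'
#' @param fit a converged [fit_glmm()] result.
#' @return the dispersion statistic (scalar).
#' @export
pearson_dispersion <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!isTRUE(fit$converged)) stop("dispersion requires a converged fit")
  p <- pmin(pmax(fit$fitted_p, 1e-10), 1 - 1e-10)
  num <- (fit$m - fit$size * p)^2 / (fit$size * p * (1 - p))
  sum(num) / (fit$n_obs - fit$p_fixed)
}

# the four treatment-by-sex cells on the link scale, as rows of a matrix L
# such that cell means = L %*% beta (works whether or not the interaction
# column is present in the fit)
cell_L <- function(fit) {
  grid <- expand.grid(treatment = c("control", "testosterone"),
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  L <- build_fixed_X(fit$fixed, grid)
  rownames(L) <- c("CF", "TF", "CM", "TM")
  L[, names(fit$beta), drop = FALSE]
}

CONTRAST_DEFS <- list(
  "F: T-C"  = c("TF", "CF"),
  "M: T-C"  = c("TM", "CM"),
  "C: M-F"  = c("CM", "CF"),
  "T: M-F"  = c("TM", "TF"),
  "TF-CM"   = c("TF", "CM"),
  "TM-CF"   = c("TM", "CF"))

#' Marginal-means contrasts between treatment-by-sex cells
#'
#' Forms the four cell means on the link scale as linear combinations of
#' the fixed effects and returns pairwise differences with Wald tests:
#' z-tests for GLMM fits, t-tests with residual degrees of freedom
#' (`N - p_fixed`) for LMM fits.  The requested multiplicity adjustment is
#' applied over the returned family.
#'
#' @param fit a converged [fit_glmm()] or [fit_lmm()] with treatment and
#'   sex terms.
#' @param which contrast family: `"all"` (six pairwise), `"within_sex"`
#'   (treatment effect within each sex), `"within_treatment"` (sex effect
#'   within each treatment), `"cross"` (the two crossed pairs, e.g.
#'   testosterone females vs control males).
#' @param adjustment `"bonferroni"`, `"BH"`, or `"none"`.
#' @return a `data.frame` with `label`, `estimate`, `se`, `statistic`,
#'   `p_raw`, `p_adjusted`.
#' @export
marginal_means_contrasts <- function(fit,
                                     which = c("all", "within_sex",
                                               "within_treatment", "cross"),
                                     adjustment = c("bonferroni", "BH",
                                                    "none")) {
  which <- match.arg(which)
  adjustment <- match.arg(adjustment)
  if (!isTRUE(fit$converged)) stop("contrasts require a converged fit")
  vars <- all.vars(fit$fixed)
  if (!all(c("treatment", "sex") %in% vars))
    stop("fit must include treatment and sex fixed effects")
  L <- cell_L(fit)
  family <- switch(which,
                   all = names(CONTRAST_DEFS),
                   within_sex = c("F: T-C", "M: T-C"),
                   within_treatment = c("C: M-F", "T: M-F"),
                   cross = c("TF-CM", "TM-CF"))
  rows <- lapply(family, function(lbl) {
    cells <- CONTRAST_DEFS[[lbl]]
    l <- L[cells[1], ] - L[cells[2], ]
    est <- sum(l * fit$beta)
    se <- sqrt(drop(t(l) %*% fit$vcov_beta %*% l))
    stat <- if (se > 0) est / se else 0
    p <- if (inherits(fit, "lmm_fit"))
      2 * pt(-abs(stat), df = fit$n_obs - fit$p_fixed)
    else 2 * pnorm(-abs(stat))
    data.frame(label = lbl, estimate = est, se = se, statistic = stat,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(adjustment,
                           bonferroni = pmin(1, out$p_raw * nrow(out)),
                           BH = p.adjust(out$p_raw, "BH"),
                           none = out$p_raw)
  out$adjustment <- adjustment
  out
}
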