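#' Analyse treatment effects on nestling weight
#'
#' ML linear mixed model of weight on the requested day with treatment,
#' sex and their interaction as fixed effects and brood-of-origin and
#' brood-of-rearing random intercepts -- except day 2, measured before
#' cross-fostering, which carries the origin intercept only.  The
#' interaction is tested by likelihood-ratio test and eliminated backwards
#' when `p >= drop_threshold`; the minimal model always keeps treatment
#' and sex, whose LRTs are reported from the mains model.  When the
#' interaction is retained, Bonferroni-adjusted pairwise cell contrasts
#' are returned.
#'
#' @param phenotypes per-individual phenotype table (the `individuals`
#'   element of [simulate_phenotypes()], or any table with matching
#'   columns).
#' @param design the design table.
#' @param day one of 2, 6, 8, 14.
#' @param drop_threshold backward-elimination threshold for the
#'   interaction.
#' @return list with `fit` (the final model), `fit_full` (interaction
#'   model), `terms` (one row per tested term: LRT statistic, df, p,
#'   retained flag) and `contrasts` (cell contrasts, `NULL` when the
#'   interaction was dropped).
#' @export
analyze_weight <- function(phenotypes, design, day,
                           drop_threshold = 0.05) {
  if (!day %in% c(2, 6, 8, 14)) stop("day must be one of 2, 6, 8, 14")
  col <- paste0("weight_d", day)
  random <- if (day == 2) list("brood_origin")
            else list("brood_origin", "brood_rearing")
  analyze_trait(phenotypes[[col]], phenotypes$individual, design, random,
                drop_threshold)
}

#' Analyse treatment effects on day-14 tarsus length
#'
#' Same model structure and backward elimination as day-14 weight.
#'
#' @inheritParams analyze_weight
#' @return as [analyze_weight()].
#' @export
analyze_tarsus <- function(phenotypes, design, drop_threshold = 0.05) {
  analyze_trait(phenotypes$tarsus_d14, phenotypes$individual, design,
                list("brood_origin", "brood_rearing"), drop_threshold)
}

# shared LMM + backward elimination for a per-individual trait
analyze_trait <- function(y, individuals, design, random, drop_threshold) {
  idx <- match(individuals, design$individual)
  if (anyNA(idx)) stop("phenotype table has individuals missing from design")
  d <- design[idx, , drop = FALSE]
  ok <- !is.na(y)
  y <- y[ok]; d <- d[ok, , drop = FALSE]
  fit_full <- fit_lmm(y, d, ~ treatment * sex, random)
  if (fit_full$degenerate) {
    return(list(fit = fit_full, fit_full = fit_full,
                terms = data.frame(term = "treatment:sex", statistic = 0,
                                   df = 1, p = 1, retained = FALSE),
                contrasts = NULL, degenerate = TRUE))
  }
  fit_main <- fit_lmm(y, d, ~ treatment + sex, random)
  t_int <- lrt(fit_full, fit_main)
  retained <- t_int$p < drop_threshold
  terms <- data.frame(term = "treatment:sex", statistic = t_int$statistic,
                      df = t_int$df, p = t_int$p, retained = retained,
                      stringsAsFactors = FALSE)
  if (!retained) {
    fit_trt <- fit_lmm(y, d, ~ sex, random)
    fit_sex <- fit_lmm(y, d, ~ treatment, random)
    terms <- rbind(terms,
                   data.frame(term = "treatment",
                              statistic = lrt(fit_main, fit_trt)$statistic,
                              df = 1, p = lrt(fit_main, fit_trt)$p,
                              retained = TRUE),
                   data.frame(term = "sex",
                              statistic = lrt(fit_main, fit_sex)$statistic,
                              df = 1, p = lrt(fit_main, fit_sex)$p,
                              retained = TRUE))
  }
  contrasts <- if (retained)
    marginal_means_contrasts(fit_full, "all", "bonferroni") else NULL
  list(fit = if (retained) fit_full else fit_main, fit_full = fit_full,
       terms = terms, contrasts = contrasts, degenerate = FALSE)
}

#' Analyse begging (or feeding) probability per parental visit
#'
#' Bernoulli GLMM (logit link) of the per-visit outcome with treatment,
#' sex and their interaction as fixed effects and brood-of-origin,
#' brood-of-rearing and nestling random intercepts.  The interaction is
#' tested first by LRT (chi-square, 1 df) and dropped when
#' `p >= drop_threshold`; the treatment test is then reported from the
#' mains model.  Marginal predicted probabilities per treatment group
#' (cell probabilities averaged over the sexes) are emitted.
#'
#' @param visits per-visit table with columns `individual` and the outcome
#'   column (`begged` or `fed`).
#' @param design the design table.
#' @param outcome outcome column name.
#' @param drop_threshold backward-elimination threshold.
#' @return list with `fit`, `fit_full`, `terms`, and
#'   `predicted_probability` (named per-treatment marginal probability).
#' @export
analyze_begging <- function(visits, design, outcome = "begged",
                            drop_threshold = 0.05) {
  idx <- match(visits$individual, design$individual)
  if (anyNA(idx)) stop("visit table has individuals missing from design")
  d <- design[idx, , drop = FALSE]
  d$nestling <- visits$individual
  y <- as.numeric(visits[[outcome]])
  random <- c("brood_origin", "brood_rearing", "nestling")
  fit_full <- fit_glmm(y, rep(1, length(y)), d, ~ treatment * sex, random)
  fit_main <- fit_glmm(y, rep(1, length(y)), d, ~ treatment + sex, random)
  t_int <- lrt(fit_full, fit_main)
  retained <- t_int$p < drop_threshold
  fit_trt <- fit_glmm(y, rep(1, length(y)), d, ~ sex, random)
  t_trt <- lrt(fit_main, fit_trt)
  terms <- data.frame(
    term = c("treatment:sex", "treatment"),
    statistic = c(t_int$statistic, t_trt$statistic), df = 1,
    p = c(t_int$p, t_trt$p),
    retained = c(retained, TRUE), stringsAsFactors = FALSE)
  fit <- if (retained) fit_full else fit_main
  L <- cell_L(fit)
  cellp <- plogis(drop(L %*% fit$beta))
  pred <- c(control = mean(cellp[c("CF", "CM")]),
            testosterone = mean(cellp[c("TF", "TM")]))
  list(fit = fit, fit_full = fit_full, terms = terms,
       predicted_probability = pred)
}

#' Handling-stress response pipeline
#'
#' Stage 1: ML linear mixed model of the breath count per 15-s bout on
#' bout number (fixed linear trend) with a correlated random intercept and
#' slope per individual; the conditional-mode slope deviations (BLUPs) are
#' the per-individual handling-stress responses.  Stage 2: those estimates
#' are analysed like any day-14 trait (treatment, sex, interaction; brood
#' random effects; backward elimination of the interaction).
#'
#' Individuals with fewer than 2 recorded bouts are dropped with a log
#' entry in the returned `dropped` element.
#'
#' @param phenotypes per-individual table with columns `breath_1` ..
#'   `breath_4`.
#' @param design the design table.
#' @param drop_threshold backward-elimination threshold for stage 2.
#' @return list with `responses` (named per-individual slope deviations),
#'   `stage1` (the bout-level fit), `stage2` (as [analyze_weight()]) and
#'   `dropped` (ids with insufficient bouts).
#' @export
handling_stress_pipeline <- function(phenotypes, design,
                                     drop_threshold = 0.05) {
  bout_cols <- paste0("breath_", 1:4)
  stopifnot(all(bout_cols %in% names(phenotypes)))
  counts <- as.matrix(phenotypes[bout_cols])
  n_bouts <- rowSums(!is.na(counts))
  dropped <- phenotypes$individual[n_bouts < 2]
  keep <- n_bouts >= 2
  long <- data.frame(
    individual = rep(phenotypes$individual[keep], each = 4),
    bout = rep(1:4, sum(keep)),
    count = as.vector(t(counts[keep, , drop = FALSE])))
  long <- long[!is.na(long$count), , drop = FALSE]
  stage1 <- fit_lmm(long$count, long, ~ bout,
                    list(list(factor = "individual", slope = "bout")))
  responses <- random_slope_blups(stage1, "individual")
  stage2 <- analyze_trait(responses, names(responses), design,
                          list("brood_origin", "brood_rearing"),
                          drop_threshold)
  list(responses = responses, stage1 = stage1, stage2 = stage2,
       dropped = dropped)
}
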