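#' Simulation configuration for the cross-fostered methylation experiment
#'
#' Bundles every generative parameter used by [simulate_design()],
#' [simulate_methylation()], [simulate_phenotypes()] and
#' [simulate_annotation()].  Defaults emulate the field design the package
#' targets: clutches alternately assigned to a control or
#' testosterone-injection group, partial cross-fostering into mixed rearing
#' broods, roughly even sex ratios, logit-scale brood-of-origin and
#' brood-of-rearing random intercepts on per-CpG methylation, negative
#' binomial read coverage around 30x, and a small minority of CpGs with
#' beta-binomial extra-binomial dispersion.
#'
#' A single global `seed` drives independent child generators per component
#' (design, methylation, phenotypes, annotation), so e.g. changing `n_cpgs`
#' never perturbs the sampled design.
#'
#' @param seed integer; global seed for the child generators.
#' @param n_brood_pairs number of cross-fostering pairs; each pair holds one
#'   control and one testosterone clutch, so there are `2 * n_brood_pairs`
#'   broods of origin and the same number of rearing broods.
#' @param brood_size_mean mean nestlings per brood (Poisson, truncated at 2).
#' @param p_male probability an individual is male.
#' @param sigma_origin,sigma_rearing SDs (logit scale) of the per-CpG
#'   brood-of-origin and brood-of-rearing random intercepts.
#' @param baseline_logit_range length-2 numeric; per-CpG baseline logit
#'   methylation is drawn uniformly from this interval.
#' @param n_cpgs number of CpG sites to simulate.
#' @param n_dms_per_category named integer vector with entries
#'   `female_specific`, `male_specific`, `antagonistic`: number of true DMS
#'   planted per category.
#' @param effect_logit magnitude of the within-sex treatment effect at true
#'   DMS (logit scale); signs alternate site by site.
#' @param sex_logit baseline male-female methylation offset (logit scale).
#' @param coverage_mean,coverage_dispersion negative binomial coverage model
#'   (mean and size); zero-coverage draws become missing cells.
#' @param rho_overdispersion beta-binomial intra-class correlation at sites
#'   flagged as extra-dispersed.
#' @param frac_extreme_dispersion fraction of CpGs flagged extra-dispersed.
#' @param chrom_lengths named integer vector of synthetic chromosome lengths.
#' @param n_genes number of synthetic gene models.
#' @param fraction_loc fraction of genes named with the uncharacterised
#'   `LOC...` convention.
#' @param weight_means named numeric: mean weight (g) on days 2, 6, 8, 14.
#' @param weight_sex_d14 additive male-minus-female weight difference on day
#'   14 (g).
#' @param weight_trt_female_d14 day-14 weight offset (g) applied to
#'   testosterone-treated females: the treatment-by-sex interaction the
#'   phenotype stage should recover.
#' @param weight_sigma_origin,weight_sigma_rearing,weight_sigma_resid brood
#'   and residual SDs (g) for the weight models.
#' @param tarsus_mean,tarsus_sex,tarsus_trt,tarsus_sigma_resid tarsus model
#'   (mm): mean, male offset, treatment offset, residual SD (brood SDs are
#'   shared with the weight model, scaled to mm).
#' @param breath_intercept,breath_slope mean breaths per 15-s bout at bout 1
#'   and the mean per-bout change.
#' @param breath_slope_sd SD of individual slope deviations (the
#'   handling-stress response being simulated).
#' @param breath_intercept_sd,breath_sigma_resid individual intercept SD and
#'   residual SD of bout counts.
#' @param begging_intercept baseline begging log-odds per parental visit.
#' @param begging_trt treatment effect on begging log-odds.
#' @param begging_sigma_nestling per-nestling random intercept SD
#'   (log-odds); brood SDs reuse `sigma_origin`/`sigma_rearing`.
#' @param visit_rate_mean mean number of parental visits per rearing brood
#'   (Poisson).
#'
#' @return an object of class `sim_config` (validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_brood_pairs = 2, n_cpgs = 20)
#' design <- simulate_design(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_brood_pairs = 16L,
                       brood_size_mean = 6,
                       p_male = 0.5,
                       sigma_origin = 0.3,
                       sigma_rearing = 0.2,
                       baseline_logit_range = c(-2.5, 2.5),
                       n_cpgs = 1000L,
                       n_dms_per_category = c(female_specific = 0L,
                                              male_specific = 0L,
                                              antagonistic = 0L),
                       effect_logit = 1.5,
                       sex_logit = 0,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       rho_overdispersion = 0.3,
                       frac_extreme_dispersion = 0,
                       chrom_lengths = c(chr1 = 1200000L, chr2 = 900000L,
                                         chr3 = 600000L),
                       n_genes = 60L,
                       fraction_loc = 0.3,
                       weight_means = c(d2 = 2.5, d6 = 8.0, d8 = 11.0,
                                        d14 = 16.5),
                       weight_sex_d14 = 0.7,
                       weight_trt_female_d14 = 0,
                       weight_sigma_origin = 0.5,
                       weight_sigma_rearing = 0.5,
                       weight_sigma_resid = 0.8,
                       tarsus_mean = 19.2,
                       tarsus_sex = 0.35,
                       tarsus_trt = 0,
                       tarsus_sigma_resid = 0.4,
                       breath_intercept = 25,
                       breath_slope = -1.0,
                       breath_slope_sd = 0.8,
                       breath_intercept_sd = 3.0,
                       breath_sigma_resid = 1.5,
                       begging_intercept = 0.3,
                       begging_trt = 0,
                       begging_sigma_nestling = 0.5,
                       visit_rate_mean = 20) {
  cfg <- list(seed = as.integer(seed), n_brood_pairs = as.integer(n_brood_pairs),
              brood_size_mean = brood_size_mean, p_male = p_male,
              sigma_origin = sigma_origin, sigma_rearing = sigma_rearing,
              baseline_logit_range = baseline_logit_range,
              n_cpgs = as.integer(n_cpgs),
              n_dms_per_category = vapply(n_dms_per_category, as.integer, 1L),
              effect_logit = effect_logit, sex_logit = sex_logit,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              rho_overdispersion = rho_overdispersion,
              frac_extreme_dispersion = frac_extreme_dispersion,
              chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
              fraction_loc = fraction_loc, weight_means = weight_means,
              weight_sex_d14 = weight_sex_d14,
              weight_trt_female_d14 = weight_trt_female_d14,
              weight_sigma_origin = weight_sigma_origin,
              weight_sigma_rearing = weight_sigma_rearing,
              weight_sigma_resid = weight_sigma_resid,
              tarsus_mean = tarsus_mean, tarsus_sex = tarsus_sex,
              tarsus_trt = tarsus_trt,
              tarsus_sigma_resid = tarsus_sigma_resid,
              breath_intercept = breath_intercept, breath_slope = breath_slope,
              breath_slope_sd = breath_slope_sd,
              breath_intercept_sd = breath_intercept_sd,
              breath_sigma_resid = breath_sigma_resid,
              begging_intercept = begging_intercept, begging_trt = begging_trt,
              begging_sigma_nestling = begging_sigma_nestling,
              visit_rate_mean = visit_rate_mean)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_brood_pairs >= 1L,
            cfg$brood_size_mean > 0,
            cfg$coverage_mean > 0,
            cfg$coverage_dispersion > 0,
            length(cfg$baseline_logit_range) == 2L,
            diff(cfg$baseline_logit_range) >= 0,
            cfg$n_cpgs >= 1L,
            all(cfg$n_dms_per_category >= 0L))
  probs <- c(cfg$p_male, cfg$rho_overdispersion, cfg$frac_extreme_dispersion,
             cfg$fraction_loc)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sds <- c(cfg$sigma_origin, cfg$sigma_rearing, cfg$weight_sigma_origin,
           cfg$weight_sigma_rearing, cfg$weight_sigma_resid,
           cfg$tarsus_sigma_resid, cfg$breath_slope_sd,
           cfg$breath_intercept_sd, cfg$breath_sigma_resid,
           cfg$begging_sigma_nestling)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  need <- c("female_specific", "male_specific", "antagonistic")
  if (!all(need %in% names(cfg$n_dms_per_category)))
    stop("n_dms_per_category needs entries: ",
         paste(need, collapse = ", "))
  if (sum(cfg$n_dms_per_category) > cfg$n_cpgs)
    stop("total planted DMS exceeds n_cpgs")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_brood_pairs, "brood pairs |",
      x$n_cpgs, "CpGs |", sum(x$n_dms_per_category), "true DMS\n")
  invisible(x)
}

# Independent child RNG streams: one global seed, fixed per-component
# offsets, so components can be regenerated in isolation.
child_seed <- function(cfg, component) {
  offset <- c(design = 1L, methylation = 2L, phenotypes = 3L,
              annotation = 4L)[[component]]
  (cfg$seed %% 2000000L) * 1000L + offset
}

with_child_seed <- function(cfg, component, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(cfg, component))
  expr
}
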