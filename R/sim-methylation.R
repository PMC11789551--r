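#' Simulate per-CpG methylation counts with known ground truth
#'
#' For CpG `j` and individual `i` the methylation probability follows
#' `logit p_ij = b0_j + bT_j T_i + bS_j S_i + bTS_j T_i S_i +
#' u_origin(i),j + u_rearing(i),j`, with brood random intercepts drawn
#' `N(0, sigma^2)` independently per site.  Coverage is negative binomial
#' (zero draws become missing cells) and methylated counts are binomial, or
#' beta-binomial with intra-class correlation `rho_overdispersion` at the
#' minority of sites flagged extra-dispersed.  True DMS are planted so the
#' within-sex treatment contrasts match the requested category:
#' female-specific (`bT = e, bTS = -e`), male-specific (`bT = 0, bTS = e`),
#' antagonistic (`bT = e, bTS = -2e`), with the sign of `e` alternating
#' site by site.
#'
#' @param config a [sim_config()] object.
#' @param design a design table from [simulate_design()].
#' @return a list with elements
#'   \describe{
#'     \item{matrix}{a [methylation_matrix()] (sites carry strand
#'       `"merged"`, i.e. complementary strands already pooled).}
#'     \item{truth}{a list: `sites` (per-CpG truth table with `is_dms`,
#'       `category`, coefficient vector, within-sex contrasts and the
#'       extra-dispersion flag) and the brood random-effect draw matrices
#'       `u_origin`, `u_rearing`.}
#'   }
#' @export
simulate_methylation <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  validate_design(design)
  with_child_seed(config, "methylation", {
    S <- config$n_cpgs
    N <- nrow(design)

    # site coordinates on the synthetic chromosomes
    chrom <- sample(names(config$chrom_lengths), S, replace = TRUE,
                    prob = config$chrom_lengths)
    pos <- floor(runif(S, 1, config$chrom_lengths[chrom])) + 1L
    while (anyDuplicated(paste(chrom, pos))) {   # resample clashes
      dup <- duplicated(paste(chrom, pos))
      pos[dup] <- floor(runif(sum(dup), 1, config$chrom_lengths[chrom[dup]])) + 1L
    }
    sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                        strand = "merged", stringsAsFactors = FALSE)
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL

    # plant true DMS
    ndms <- config$n_dms_per_category
    n_true <- sum(ndms)
    category <- rep("none", S)
    if (n_true > 0) {
      idx <- sample.int(S, n_true)
      category[idx] <- rep(names(ndms), ndms)
    }
    e <- config$effect_logit
    sgn <- rep_len(c(1, -1), S)  # alternate effect signs across sites
    beta0 <- runif(S, config$baseline_logit_range[1],
                   config$baseline_logit_range[2])
    beta_trt <- ifelse(category %in% c("female_specific", "antagonistic"),
                       sgn * e, 0)
    beta_int <- ifelse(category == "female_specific", -sgn * e,
                ifelse(category == "male_specific", sgn * e,
                ifelse(category == "antagonistic", -2 * sgn * e, 0)))
    beta_sex <- rep(config$sex_logit, S)
    contrast_f <- beta_trt
    contrast_m <- beta_trt + beta_int

    extreme <- rep(FALSE, S)
    n_ext <- round(config$frac_extreme_dispersion * S)
    if (n_ext > 0) extreme[sample.int(S, n_ext)] <- TRUE

    origin_levels <- sort(unique(design$brood_origin))
    rearing_levels <- sort(unique(design$brood_rearing))
    u_origin <- matrix(rnorm(length(origin_levels) * S, 0, config$sigma_origin),
                       length(origin_levels), S,
                       dimnames = list(origin_levels, NULL))
    u_rearing <- matrix(rnorm(length(rearing_levels) * S, 0, config$sigma_rearing),
                        length(rearing_levels), S,
                        dimnames = list(rearing_levels, NULL))

    Ti <- as.numeric(design$treatment == "testosterone")
    Si <- as.numeric(design$sex == "M")
    io <- match(design$brood_origin, origin_levels)
    ir <- match(design$brood_rearing, rearing_levels)

    # logit matrix, S x N
    eta <- outer(beta0, rep(1, N)) +
      outer(beta_trt, Ti) + outer(beta_sex, Si) + outer(beta_int, Ti * Si) +
      t(u_origin[io, , drop = FALSE]) + t(u_rearing[ir, , drop = FALSE])
    p <- plogis(eta)

    cov <- matrix(rnbinom(S * N, mu = config$coverage_mean,
                          size = config$coverage_dispersion), S, N)
    cov[cov == 0L] <- NA_integer_  # zero coverage recorded as missing

    pm <- as.vector(p)
    nn <- as.vector(cov)
    meth <- rep(NA_integer_, S * N)
    obs <- !is.na(nn)
    ext_cell <- rep(extreme, N) & obs
    plain <- obs & !ext_cell
    meth[plain] <- rbinom(sum(plain), nn[plain], pm[plain])
    if (any(ext_cell)) {
      rho <- config$rho_overdispersion
      if (rho <= 0) {
        meth[ext_cell] <- rbinom(sum(ext_cell), nn[ext_cell], pm[ext_cell])
      } else {
        nu <- (1 - rho) / rho
        pstar <- rbeta(sum(ext_cell), pm[ext_cell] * nu,
                       (1 - pm[ext_cell]) * nu)
        meth[ext_cell] <- rbinom(sum(ext_cell), nn[ext_cell], pstar)
      }
    }
    meth <- matrix(meth, S, N)

    truth_sites <- data.frame(
      site = site_label(sites), chrom = sites$chrom, pos = sites$pos,
      is_dms = category != "none", category = category,
      beta0 = beta0, beta_trt = beta_trt, beta_sex = beta_sex,
      beta_int = beta_int, contrast_f = contrast_f, contrast_m = contrast_m,
      extreme_dispersion = extreme, stringsAsFactors = FALSE)

    mm <- methylation_matrix(sites, design$individual, meth, cov)
    # methylation_matrix re-sorts; truth rows were built in the same order
    list(matrix = mm,
         truth = list(sites = truth_sites,
                      u_origin = u_origin, u_rearing = u_rearing))
  })
}

#' Write the simulation truth table
#'
#' The per-CpG truth table goes to `<stem>_truth.tsv`; the generating
#' configuration to a JSON sidecar `<stem>_config.json`.
#'
#' @param sim result of [simulate_methylation()].
#' @param config the [sim_config()] that produced it.
#' @param stem file path stem.
#' @return the stem, invisibly.
#' @export
write_truth <- function(sim, config, stem) {
  utils::write.table(sim$truth$sites, paste0(stem, "_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), paste0(stem, "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
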