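#' Genome-wide scan for sex-specific differentially methylated sites
#'
#' For every CpG in an (already filtered) methylation matrix, fits the full
#' binomial GLMM (`~ treatment * sex` with crossed brood-of-origin and
#' brood-of-rearing random intercepts) and the no-interaction model on the
#' non-missing observations, then:
#' \enumerate{
#'   \item excludes sites whose fits fail for any reason other than a
#'     singular (zero) random-effect variance;
#'   \item computes each remaining site's Pearson dispersion statistic and
#'     excludes sites outside the `hdi_mass` highest density interval of
#'     the genome-wide dispersion distribution (the overdispersion
#'     correction) -- this runs before FDR adjustment so the tested-site
#'     family is final when q-values are computed;
#'   \item tests the treatment-by-sex interaction by likelihood-ratio test
#'     and adjusts across tested sites with Benjamini-Hochberg;
#'   \item for sites with interaction `q < fdr`, computes the six
#'     treatment-by-sex cell contrasts (Wald), BH-adjusts each contrast
#'     type separately across those sites, and assigns the
#'     female-specific / male-specific / antagonistic / concordant / other
#'     category from the within-sex significance flags and directions.
#' }
#' An exclusion ledger accounts for every input site at every stage.
#'
#' @param matrix a filtered [methylation_matrix()].
#' @param design design table covering all individuals in the matrix.
#' @param fdr FDR threshold for the interaction and the categorizing
#'   contrasts.
#' @param hdi_mass mass of the dispersion HDI (set `NA` to skip the
#'   dispersion exclusion; it also requires at least 20 candidate sites).
#' @return a `scan_result`: list with `records` (one row per input site:
#'   `status`, full-model fixed effects and SEs, random-effect SDs,
#'   `loglik_full`, `loglik_reduced`, `singular`, `phi`, `p_interaction`,
#'   `q_interaction`), `dms` (one row per declared DMS with contrasts and
#'   `category`), `ledger` (per-stage counts), `params`.
#' @examples
#' cfg <- sim_config(seed = 11, n_brood_pairs = 6, n_cpgs = 30,
#'                   n_dms_per_category = c(female_specific = 3,
#'                                          male_specific = 0,
#'                                          antagonistic = 0),
#'                   effect_logit = 2.5)
#' d <- simulate_design(cfg)
#' sim <- simulate_methylation(cfg, d)
#' res <- run_scan(sim$matrix, d, hdi_mass = NA)
#' res$ledger
#' @export
run_scan <- function(matrix, design, fdr = 0.1, hdi_mass = 0.95) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  validate_design(design)
  idx <- match(matrix$individuals, design$individual)
  if (anyNA(idx)) stop("design does not cover all individuals in matrix")
  design <- design[idx, , drop = FALSE]

  X_full <- build_fixed_X(~ treatment * sex, design)
  X_red <- X_full[, 1:3, drop = FALSE]
  f_or <- factor(design$brood_origin)
  f_re <- factor(design$brood_rearing)
  G_all <- cbind(as.integer(f_or) - 1L, as.integer(f_re) - 1L)
  nlev <- c(nlevels(f_or), nlevels(f_re))
  trt <- design$treatment
  sex <- design$sex

  S <- n_sites(matrix)
  status <- character(S)
  phi <- rep(NA_real_, S)
  p_int <- rep(NA_real_, S)
  n_obs <- rep(NA_integer_, S)
  betas <- matrix(NA_real_, S, 4,
                  dimnames = list(NULL, colnames(X_full)))
  ses <- betas
  sigmas <- matrix(NA_real_, S, 2,
                   dimnames = list(NULL, c("sigma_origin", "sigma_rearing")))
  ll_full <- rep(NA_real_, S)
  ll_red <- rep(NA_real_, S)
  singular <- rep(NA, S)
  vcovs <- vector("list", S)

  for (i in seq_len(S)) {
    obs <- which(!is.na(matrix$cov[i, ]))
    if (length(unique(trt[obs])) < 2 || length(unique(sex[obs])) < 2) {
      status[i] <- "untestable"
      next
    }
    m <- matrix$meth[i, obs]
    n <- matrix$cov[i, obs]
    full <- glmm_engine(m, n, X_full[obs, , drop = FALSE],
                        G_all[obs, , drop = FALSE], nlev)
    if (!full$converged) { status[i] <- "failed_fit"; next }
    red <- glmm_engine(m, n, X_red[obs, , drop = FALSE],
                       G_all[obs, , drop = FALSE], nlev)
    if (!red$converged) { status[i] <- "failed_fit"; next }
    stat <- max(0, 2 * (full$loglik - red$loglik))
    p_int[i] <- pchisq(stat, 1, lower.tail = FALSE)
    pp <- pmin(pmax(plogis(full$eta), 1e-10), 1 - 1e-10)
    phi[i] <- sum((m - n * pp)^2 / (n * pp * (1 - pp))) /
      (length(m) - ncol(X_full))
    n_obs[i] <- length(m)
    betas[i, ] <- full$beta
    ses[i, ] <- full$se_beta
    sigmas[i, ] <- full$sigma
    ll_full[i] <- full$loglik
    ll_red[i] <- red$loglik
    singular[i] <- full$singular
    vcovs[[i]] <- full$vcov_beta
    status[i] <- "fitted"
  }

  cand <- which(status == "fitted")
  if (!is.na(hdi_mass) && length(cand) >= 20) {
    hdi <- hdi_exclude(phi[cand], hdi_mass)
    outside <- setdiff(seq_along(cand), hdi$keep)
    status[cand[outside]] <- "dispersion_excluded"
    hdi_interval <- hdi$interval
  } else {
    hdi_interval <- c(NA_real_, NA_real_)
  }
  tested <- which(status == "fitted")
  status[tested] <- "tested"

  q_int <- rep(NA_real_, S)
  if (length(tested)) q_int[tested] <- bh_adjust(p_int[tested])

  beta_cols <- as.data.frame(betas)
  names(beta_cols) <- c("beta_intercept", "beta_trt", "beta_sex", "beta_int")
  se_cols <- as.data.frame(ses)
  names(se_cols) <- paste0("se_", c("intercept", "trt", "sex", "int"))
  records <- data.frame(site = site_label(matrix$sites),
                        chrom = matrix$sites$chrom, pos = matrix$sites$pos,
                        status = status, n_obs = n_obs,
                        beta_cols, se_cols, as.data.frame(sigmas),
                        loglik_full = ll_full, loglik_reduced = ll_red,
                        singular = singular, phi = phi,
                        p_interaction = p_int, q_interaction = q_int,
                        stringsAsFactors = FALSE)

  dms_idx <- tested[!is.na(q_int[tested]) & q_int[tested] < fdr]
  dms <- dms_table(matrix, dms_idx, betas, vcovs, q_int, fdr)

  ledger <- list(input = S,
                 untestable = sum(status == "untestable"),
                 failed_fit = sum(status == "failed_fit"),
                 dispersion_excluded = sum(status == "dispersion_excluded"),
                 tested = length(tested),
                 dms = length(dms_idx))
  stopifnot(ledger$untestable + ledger$failed_fit +
              ledger$dispersion_excluded + ledger$tested == S)

  structure(list(records = records, dms = dms, ledger = ledger,
                 params = list(fdr = fdr, hdi_mass = hdi_mass,
                               hdi_interval = hdi_interval)),
            class = "scan_result")
}

# Wald contrasts and categories for the declared DMS.  Each of the six
# contrast types forms its own BH family across the DMS sites.
dms_table <- function(matrix, dms_idx, betas, vcovs, q_int, fdr) {
  if (!length(dms_idx)) {
    out <- data.frame(site = character(0), chrom = character(0),
                      pos = integer(0), q_interaction = numeric(0),
                      contrast_f = numeric(0), contrast_m = numeric(0),
                      q_f = numeric(0), q_m = numeric(0),
                      sig_f = logical(0), sig_m = logical(0),
                      dir_f = character(0), dir_m = character(0),
                      other_sig = logical(0), category = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  grid <- expand.grid(treatment = c("control", "testosterone"),
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  L <- build_fixed_X(~ treatment * sex, grid)
  rownames(L) <- c("CF", "TF", "CM", "TM")
  nd <- length(dms_idx)
  labels <- names(CONTRAST_DEFS)
  est <- p_raw <- matrix(NA_real_, nd, length(labels),
                         dimnames = list(NULL, labels))
  for (j in seq_len(nd)) {
    i <- dms_idx[j]
    b <- betas[i, ]
    V <- vcovs[[i]]
    for (lbl in labels) {
      cells <- CONTRAST_DEFS[[lbl]]
      l <- L[cells[1], ] - L[cells[2], ]
      e <- sum(l * b)
      se <- sqrt(drop(t(l) %*% V %*% l))
      est[j, lbl] <- e
      p_raw[j, lbl] <- if (se > 0) 2 * pnorm(-abs(e / se)) else 1
    }
  }
  q <- apply(p_raw, 2, bh_adjust)
  if (nd == 1) q <- matrix(q, 1, dimnames = list(NULL, labels))
  sig <- q < fdr
  other_sig <- rowSums(sig[, c("C: M-F", "T: M-F", "TF-CM", "TM-CF"),
                           drop = FALSE]) > 0
  dir_f <- ifelse(est[, "F: T-C"] > 0, "up", "down")
  dir_m <- ifelse(est[, "M: T-C"] > 0, "up", "down")
  category <- vapply(seq_len(nd), function(j)
    categorize_dms(sig[j, "F: T-C"], sig[j, "M: T-C"],
                   dir_f[j], dir_m[j], other_sig[j]), "")
  data.frame(site = site_label(matrix$sites)[dms_idx],
             chrom = matrix$sites$chrom[dms_idx],
             pos = matrix$sites$pos[dms_idx],
             q_interaction = q_int[dms_idx],
             contrast_f = est[, "F: T-C"], contrast_m = est[, "M: T-C"],
             q_f = q[, "F: T-C"], q_m = q[, "M: T-C"],
             sig_f = sig[, "F: T-C"], sig_m = sig[, "M: T-C"],
             dir_f = ifelse(sig[, "F: T-C"], dir_f, "ns"),
             dir_m = ifelse(sig[, "M: T-C"], dir_m, "ns"),
             other_sig = other_sig, category = category,
             stringsAsFactors = FALSE)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result>\n")
  for (nm in names(x$ledger)) cat("  ", nm, ":", x$ledger[[nm]], "\n")
  if (nrow(x$dms)) {
    cat("categories:\n")
    print(table(x$dms$category))
  }
  invisible(x)
}

#' Write scan results to disk
#'
#' `write_scan_results` writes the per-site record table as TSV
#' (chromosome-ordered, ready for a Manhattan plot), the DMS table as TSV,
#' a BED file (0-based, half-open) of DMS with the category in the name
#' field, and a JSON summary with the per-category counts and the
#' exclusion ledger.
#'
#' @param scan a `scan_result`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return the output directory, invisibly.
#' @export
write_scan_results <- function(scan, dir, stem = "scan") {
  stopifnot(inherits(scan, "scan_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(scan$records, file.path(dir, paste0(stem, "_sites.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$dms, file.path(dir, paste0(stem, "_dms.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(scan$dms)) {
    bed <- data.frame(scan$dms$chrom, scan$dms$pos - 1L, scan$dms$pos,
                      scan$dms$category)
    utils::write.table(bed, file.path(dir, paste0(stem, "_dms.bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  counts <- as.list(table(factor(scan$dms$category,
                                 levels = c("female_specific", "male_specific",
                                            "antagonistic", "concordant",
                                            "other", "unclassified"))))
  jsonlite::write_json(list(categories = counts, ledger = scan$ledger,
                            params = scan$params[c("fdr", "hdi_mass")]),
                       file.path(dir, paste0(stem, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
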