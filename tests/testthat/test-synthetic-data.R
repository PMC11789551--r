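test_that("simulated designs alternate treatments and mix every rearing brood", {
  cfg <- sim_config(seed = 1, n_brood_pairs = 16, brood_size_mean = 6)
  d <- simulate_design(cfg)
  expect_s3_class(d, "sample_design")
  # clutches alternately assigned: odd broods control, even testosterone
  per_brood <- unique(d[c("brood_origin", "treatment")])
  per_brood <- per_brood[order(per_brood$brood_origin), ]
  expect_equal(per_brood$treatment,
               rep(c("control", "testosterone"), 16))
  # every rearing brood holds nestlings of both treatments
  mix <- table(d$brood_rearing, d$treatment)
  expect_true(all(mix >= 1))
  # one origin and one rearing brood per individual, ids unique
  expect_false(anyDuplicated(d$individual) > 0)
  # group sizes differ by no more than the brood-size imbalance
  sizes <- table(d$brood_origin)
  expect_lte(abs(sum(d$treatment == "control") -
                   sum(d$treatment == "testosterone")),
             sum(abs(sizes[seq(1, 31, 2)] - sizes[seq(2, 32, 2)])))
})

test_that("degenerate sex probability and single-pair designs behave", {
  d_f <- simulate_design(sim_config(seed = 3, n_brood_pairs = 3, p_male = 0))
  expect_true(all(d_f$sex == "F"))
  d_m <- simulate_design(sim_config(seed = 3, n_brood_pairs = 3, p_male = 1))
  expect_true(all(d_m$sex == "M"))
  d1 <- simulate_design(sim_config(seed = 5, n_brood_pairs = 1))
  expect_length(unique(d1$brood_origin), 2)
  expect_length(unique(d1$brood_rearing), 2)
  expect_true(all(table(d1$brood_rearing, d1$treatment) >= 1))
})

test_that("child generators are independent and byte-reproducible", {
  cfg_a <- tiny_config(seed = 7)
  cfg_b <- tiny_config(seed = 7, n_cpgs = 50)  # more CpGs, same seed
  expect_identical(simulate_design(cfg_a), simulate_design(cfg_b))
  sim1 <- simulate_methylation(cfg_a, simulate_design(cfg_a))
  sim2 <- simulate_methylation(cfg_a, simulate_design(cfg_a))
  expect_identical(sim1, sim2)
  ph1 <- simulate_phenotypes(cfg_a, simulate_design(cfg_a))
  ph2 <- simulate_phenotypes(cfg_a, simulate_design(cfg_a))
  expect_identical(ph1, ph2)
})

test_that("methylation counts respect conservation and truth categories", {
  cfg <- tiny_config(seed = 11, n_cpgs = 60,
                     n_dms_per_category = c(female_specific = 5,
                                            male_specific = 5,
                                            antagonistic = 5),
                     effect_logit = 1.5)
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  expect_true(all(is.na(sim$matrix$meth) |
                    sim$matrix$meth <= sim$matrix$cov))
  expect_true(all(is.na(sim$matrix$meth) | sim$matrix$meth >= 0))
  tr <- sim$truth$sites
  expect_equal(sum(tr$is_dms), 15)
  # sign pattern of true within-sex contrasts matches the category
  fs <- tr[tr$category == "female_specific", ]
  expect_true(all(abs(fs$contrast_f) == 1.5 & fs$contrast_m == 0))
  ms <- tr[tr$category == "male_specific", ]
  expect_true(all(ms$contrast_f == 0 & abs(ms$contrast_m) == 1.5))
  an <- tr[tr$category == "antagonistic", ]
  expect_true(all(sign(an$contrast_f) == -sign(an$contrast_m) &
                    abs(an$contrast_f) == abs(an$contrast_m)))
  none <- tr[tr$category == "none", ]
  expect_true(all(none$contrast_f == 0 & none$contrast_m == 0))
})

test_that("null configuration has no DMS and near-zero mean contrasts", {
  cfg <- sim_config(seed = 13, n_brood_pairs = 12, n_cpgs = 150,
                    effect_logit = 0,
                    n_dms_per_category = c(female_specific = 5,
                                           male_specific = 5,
                                           antagonistic = 5))
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  tr <- sim$truth$sites
  expect_true(all(tr$contrast_f == 0 & tr$contrast_m == 0))
  # empirical within-sex treatment difference on proportions is small
  prop <- sim$matrix$meth / sim$matrix$cov
  f <- d$sex == "F"
  tt <- d$treatment == "testosterone"
  dif <- rowMeans(prop[, f & tt, drop = FALSE], na.rm = TRUE) -
    rowMeans(prop[, f & !tt, drop = FALSE], na.rm = TRUE)
  expect_lt(abs(mean(dif, na.rm = TRUE)), 0.02)
})

test_that("flagged sites show beta-binomial extra-dispersion", {
  # one p = 0.5 site replicated: compare the empirical variance of m with
  # the beta-binomial law n p (1-p) (1 + (n-1) rho) averaged over coverage
  cfg <- sim_config(seed = 17, n_brood_pairs = 16, brood_size_mean = 7,
                    n_cpgs = 80, baseline_logit_range = c(0, 0),
                    sigma_origin = 0, sigma_rearing = 0,
                    frac_extreme_dispersion = 1, rho_overdispersion = 0.3,
                    coverage_mean = 30)
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  m <- as.vector(sim$matrix$meth)
  n <- as.vector(sim$matrix$cov)
  keep <- !is.na(n)
  m <- m[keep]; n <- n[keep]   # > 10,000 draws
  expect_gt(length(m), 10000)
  p <- 0.5
  expected <- mean(n * p * (1 - p) * (1 + (n - 1) * 0.3)) + p^2 * var(n)
  binom_only <- mean(n * p * (1 - p)) + p^2 * var(n)
  expect_gt(var(m), 2 * binom_only)          # clearly overdispersed
  expect_lt(abs(var(m) / expected - 1), 0.1) # matches the moment formula
})

test_that("zero-variance phenotype configuration is exact and effects recover", {
  cfg0 <- tiny_config(seed = 19, weight_sigma_origin = 0,
                      weight_sigma_rearing = 0, weight_sigma_resid = 0,
                      weight_sex_d14 = 0)
  d0 <- simulate_design(cfg0)
  ph0 <- simulate_phenotypes(cfg0, d0)
  for (day in c("d2", "d6", "d8", "d14"))
    expect_true(all(ph0$individuals[[paste0("weight_", day)]] ==
                      cfg0$weight_means[[day]]))
  # day-14 interaction: cell-mean contrast recovers the planted effect
  reps <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = 100 + s, n_brood_pairs = 8, brood_size_mean = 4,
                      weight_trt_female_d14 = -1)
    d <- simulate_design(cfg)
    ph <- simulate_phenotypes(cfg, d)
    w <- ph$individuals$weight_d14
    cells <- tapply(w, paste(d$treatment, d$sex), mean)
    (cells["testosterone F"] - cells["control F"]) -
      (cells["testosterone M"] - cells["control M"])
  }, 0)
  expect_lt(abs(mean(reps) + 1), 0.25)
  # begging log-odds effect shows as a lower begging proportion
  cfg_b <- sim_config(seed = 23, n_brood_pairs = 20, begging_trt = -0.5,
                      visit_rate_mean = 30)
  db <- simulate_design(cfg_b)
  phb <- simulate_phenotypes(cfg_b, db)
  v <- merge(phb$visits, db, by = "individual")
  rate <- tapply(v$begged, v$treatment, mean)
  expect_lt(rate[["testosterone"]], rate[["control"]])
  # every fed event belongs to a recorded visit, one per visit
  fed_per_visit <- tapply(phb$visits$fed, paste(phb$visits$brood,
                                                phb$visits$visit), sum)
  expect_true(all(fed_per_visit == 1))
})

test_that("synthetic gene models cover all region classes and ambiguities", {
  cfg <- sim_config(seed = 29, n_cpgs = 600)
  models <- simulate_annotation(cfg)
  expect_s3_class(models, "gene_models")
  g <- models$genes
  expect_true(all(g$start <= g$end))
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_true(any(!g$characterized) && any(g$characterized))
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  ann <- annotate_all(sim$matrix$sites, models)
  expect_true(all(c("TSS", "promoter", "exon", "intron", "upstream",
                    "downstream", "intergenic") %in%
                    names(ann$counts[ann$counts > 0])))
  # ambiguous geometry exists: some site inside both an upstream and a
  # downstream flank of different genes
  both <- vapply(seq_len(nrow(sim$matrix$sites)), function(i) {
    pos <- sim$matrix$sites$pos[i]
    ch <- sim$matrix$sites$chrom[i]
    sub <- g[g$chrom == ch, ]
    up <- (sub$strand == "+" & pos >= sub$start - 10000 & pos < sub$start) |
      (sub$strand == "-" & pos > sub$end & pos <= sub$end + 10000)
    dn <- (sub$strand == "+" & pos > sub$end & pos <= sub$end + 10000) |
      (sub$strand == "-" & pos >= sub$start - 10000 & pos < sub$start)
    any(up) && any(dn)
  }, TRUE)
  expect_gt(sum(both), 0)
  # all-LOC configuration
  loc <- simulate_annotation(sim_config(seed = 29, fraction_loc = 1))
  expect_true(all(!loc$genes$characterized))
  expect_true(all(grepl("^LOC", loc$genes$gene_id)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(p_male = 1.5), "probabilities")
  expect_error(sim_config(sigma_origin = -1), "non-negative")
  expect_error(sim_config(n_cpgs = 10,
                          n_dms_per_category = c(female_specific = 6,
                                                 male_specific = 6,
                                                 antagonistic = 0)),
               "exceeds")
})
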