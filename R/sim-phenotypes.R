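#' Simulate nestling phenotypes under the cross-fostered design
#'
#' Generates weights on days 2, 6, 8 and 14, day-14 tarsus length, breath
#' counts for the four 15-s handling-stress bouts, and per-parental-visit
#' begging / feeding records:
#' \itemize{
#'   \item Weights: configured day mean + (day 14 only) a male sex offset
#'     and a testosterone-female offset (the treatment-by-sex interaction),
#'     plus brood-of-origin and brood-of-rearing random effects and Gaussian
#'     noise.  Day 2 carries no rearing effect (measured before
#'     cross-fostering).
#'   \item Tarsus: mean + sex and treatment offsets + brood effects + noise.
#'   \item Breath counts: individual intercept and bout slope, with the
#'     per-individual slope deviation (the simulated handling-stress
#'     response) drawn `N(0, breath_slope_sd^2)` and recorded in the truth
#'     table; counts are rounded to non-negative integers.
#'   \item Begging: per rearing brood a Poisson number of visits; at each
#'     visit every nestling begs with log-odds = intercept + treatment
#'     effect + brood effects + a per-nestling intercept; exactly one
#'     nestling per visit is fed.
#' }
#'
#' @param config a [sim_config()] object.
#' @param design a design table from [simulate_design()].
#' @return a list with `individuals` (one row per nestling: weights, tarsus,
#'   `breath_1` .. `breath_4`), `visits` (one row per nestling x visit with
#'   `begged`, `fed`) and `truth` (true breath slope deviations and the
#'   begging coefficients).
#' @export
simulate_phenotypes <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  validate_design(design)
  with_child_seed(config, "phenotypes", {
    N <- nrow(design)
    Ti <- design$treatment == "testosterone"
    Mi <- design$sex == "M"
    origin_levels <- sort(unique(design$brood_origin))
    rearing_levels <- sort(unique(design$brood_rearing))
    io <- match(design$brood_origin, origin_levels)
    ir <- match(design$brood_rearing, rearing_levels)

    brood_eff <- function(sd_o, sd_r, rearing = TRUE) {
      eo <- rnorm(length(origin_levels), 0, sd_o)[io]
      er <- if (rearing) rnorm(length(rearing_levels), 0, sd_r)[ir] else 0
      eo + er
    }

    weights <- sapply(c("d2", "d6", "d8", "d14"), function(day) {
      mu <- config$weight_means[[day]]
      fx <- mu +
        (if (day == "d14") config$weight_sex_d14 * Mi else 0) +
        (if (day == "d14") config$weight_trt_female_d14 * (Ti & !Mi) else 0)
      fx + brood_eff(config$weight_sigma_origin, config$weight_sigma_rearing,
                     rearing = day != "d2") +
        rnorm(N, 0, config$weight_sigma_resid)
    })
    colnames(weights) <- paste0("weight_", c("d2", "d6", "d8", "d14"))

    tarsus <- config$tarsus_mean + config$tarsus_sex * Mi +
      config$tarsus_trt * Ti +
      brood_eff(config$weight_sigma_origin, config$weight_sigma_rearing) +
      rnorm(N, 0, config$tarsus_sigma_resid)

    slope_dev <- rnorm(N, 0, config$breath_slope_sd)
    int_dev <- rnorm(N, 0, config$breath_intercept_sd)
    breath <- sapply(1:4, function(b) {
      mu <- config$breath_intercept + int_dev +
        (config$breath_slope + slope_dev) * (b - 1) +
        rnorm(N, 0, config$breath_sigma_resid)
      pmax(0, round(mu))
    })
    colnames(breath) <- paste0("breath_", 1:4)

    individuals <- data.frame(individual = design$individual, weights,
                              tarsus_d14 = tarsus, breath,
                              stringsAsFactors = FALSE)

    # begging / feeding per parental visit
    u_or <- rnorm(length(origin_levels), 0, config$sigma_origin)
    u_re <- rnorm(length(rearing_levels), 0, config$sigma_rearing)
    u_ind <- rnorm(N, 0, config$begging_sigma_nestling)
    visit_rows <- list()
    for (rb in seq_along(rearing_levels)) {
      members <- which(ir == rb)
      if (!length(members)) next
      nv <- max(1L, rpois(1L, config$visit_rate_mean))
      for (v in seq_len(nv)) {
        eta <- config$begging_intercept + config$begging_trt * Ti[members] +
          u_or[io[members]] + u_re[rb] + u_ind[members]
        begged <- runif(length(members)) < plogis(eta)
        fed <- seq_along(members) == sample.int(length(members), 1L)
        visit_rows[[length(visit_rows) + 1L]] <- data.frame(
          brood = rearing_levels[rb], visit = v,
          individual = design$individual[members],
          begged = begged, fed = fed, stringsAsFactors = FALSE)
      }
    }
    visits <- do.call(rbind, visit_rows)
    rownames(visits) <- NULL

    list(individuals = individuals, visits = visits,
         truth = list(
           breath_slope_dev = setNames(slope_dev, design$individual),
           begging = c(intercept = config$begging_intercept,
                       treatment = config$begging_trt),
           weight_trt_female_d14 = config$weight_trt_female_d14))
  })
}

#' Write / read phenotype tables
#'
#' Per-individual measures and the per-visit begging table are written as
#' two CSV files sharing a stem: `<stem>_individuals.csv` and
#' `<stem>_visits.csv`.
#'
#' @param phenotypes list as returned by [simulate_phenotypes()] (the
#'   `truth` element is not written).
#' @param stem file path stem.
#' @return `read_phenotypes` returns a list with `individuals` and `visits`.
#' @export
write_phenotypes <- function(phenotypes, stem) {
  utils::write.csv(phenotypes$individuals,
                   paste0(stem, "_individuals.csv"), row.names = FALSE)
  utils::write.csv(phenotypes$visits,
                   paste0(stem, "_visits.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(stem) {
  list(individuals = utils::read.csv(paste0(stem, "_individuals.csv"),
                                     stringsAsFactors = FALSE),
       visits = utils::read.csv(paste0(stem, "_visits.csv"),
                                stringsAsFactors = FALSE))
}
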