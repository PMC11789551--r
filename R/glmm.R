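#' Model specification for the mixed models
#'
#' A light container naming the response family, the fixed-effect formula
#' and the random-effect terms.  Random intercepts are given as factor
#' names; a correlated random intercept + slope is given as
#' `list(factor = "individual", slope = "bout")`.
#'
#' @param response one of `"binomial"` (two-column counts), `"bernoulli"`,
#'   `"gaussian"`.
#' @param fixed one-sided formula of fixed effects (intercept always
#'   included).
#' @param random list (or character vector) of random terms.
#' @return a `model_spec` object.
#' @export
model_spec <- function(response = c("binomial", "bernoulli", "gaussian"),
                       fixed = ~ treatment * sex,
                       random = c("brood_origin", "brood_rearing")) {
  response <- match.arg(response)
  if (is.character(random)) random <- as.list(random)
  structure(list(response = response, fixed = fixed, random = random),
            class = "model_spec")
}

# fit_glmm / fit_lmm accept a model_spec in place of `fixed`
unpack_spec <- function(fixed, random) {
  if (inherits(fixed, "model_spec")) list(fixed = fixed$fixed,
                                          random = fixed$random)
  else list(fixed = fixed, random = random)
}

# fixed-effect design matrix with stable factor coding
build_fixed_X <- function(fixed, data) {
  if ("treatment" %in% names(data))
    data$treatment <- factor(data$treatment,
                             levels = c("control", "testosterone"))
  if ("sex" %in% names(data))
    data$sex <- factor(data$sex, levels = c("F", "M"))
  stats::model.matrix(fixed, data)
}

SEPARATION_BOUND <- 15

#' Fit a binomial GLMM by the Laplace approximation
#'
#' Logit-link mixed model for methylated counts out of coverage (or a
#' Bernoulli outcome) with crossed random intercepts.  For each value of
#' the random-effect SDs, the fixed effects and random effects are set to
#' their joint penalized mode by damped iteratively reweighted least
#' squares, and the Laplace-approximate deviance is evaluated there; the
#' SDs are then optimized by a deterministic coarse pre-search followed by
#' Nelder-Mead on the natural SD scale (the deviance surface is flat along
#' the zero-variance boundary, where gradient-based outer optimizers
#' stall).  The whole procedure is deterministic.
#'
#' Fits with any SD estimated below `1e-4` are flagged `singular` but
#' retained.  Fits where any fixed effect exceeds 15 on the logit scale are
#' flagged as (quasi-)complete separation and `converged` is set `FALSE`
#' (these are the model-warning fits the genome-wide scan excludes).
#'
#' @param m numeric vector of methylated counts (or 0/1 outcomes).
#' @param size numeric vector of coverages (all 1 for Bernoulli).
#' @param data `data.frame` with the fixed- and random-effect variables,
#'   one row per observation.
#' @param fixed one-sided fixed-effect formula (default
#'   `~ treatment * sex`), or a [model_spec()] (its `random` terms then
#'   override the `random` argument).
#' @param random character vector of random-intercept factor names.
#' @param sigma_start starting SD for every random term.
#' @param sigma_bounds lower/upper SD bounds for the outer optimizer.
#' @param sigma_fixed optional vector of SDs (one per random term): skip
#'   the outer optimization and evaluate the Laplace fit at these values
#'   (e.g. at the zero boundary, where the fit must reproduce plain
#'   logistic regression).
#' @return an object of class `glmm_fit`: fixed effects `beta` with
#'   `se_beta` and `vcov_beta`, random-effect SDs `sigma`, conditional
#'   modes `u`, `loglik` (Laplace, binomial constant included),
#'   `converged`, `singular`, `reason`, fitted probabilities, and the
#'   ingredients for [pearson_dispersion()] and
#'   [marginal_means_contrasts()].
#' @examples
#' cfg <- sim_config(seed = 7, n_brood_pairs = 8, n_cpgs = 3)
#' d <- simulate_design(cfg)
#' sim <- simulate_methylation(cfg, d)
#' obs <- !is.na(sim$matrix$cov[1, ])
#' fit <- fit_glmm(sim$matrix$meth[1, obs], sim$matrix$cov[1, obs], d[obs, ])
#' fit$beta
#' @export
fit_glmm <- function(m, size, data, fixed = ~ treatment * sex,
                     random = c("brood_origin", "brood_rearing"),
                     sigma_start = 0.5, sigma_bounds = c(1e-6, 20),
                     sigma_fixed = NULL) {
  stopifnot(length(m) == nrow(data), length(size) == nrow(data),
            all(size >= 1), all(m >= 0), all(m <= size))
  sp <- unpack_spec(fixed, random)
  fixed <- sp$fixed
  random <- unlist(sp$random)
  X <- build_fixed_X(fixed, data)
  for (term in c("treatment", "sex")) {
    if (term %in% all.vars(fixed) && length(unique(data[[term]])) < 2)
      stop("fixed factor '", term, "' has fewer than 2 levels in the data")
  }
  K <- length(random)
  if (K > 0) {
    facs <- lapply(random, function(f) factor(data[[f]]))
    G <- vapply(facs, function(f) as.integer(f) - 1L, integer(nrow(data)))
    nlev <- vapply(facs, nlevels, 1L)
    lev <- lapply(facs, levels)
  } else {
    G <- matrix(0L, nrow(data), 0)
    nlev <- integer(0)
    lev <- list()
  }
  eng <- glmm_engine(m, size, X, G, nlev, sigma_start, sigma_bounds,
                     sigma_fixed)

  u <- list()
  if (K > 0 && !is.null(eng$u)) {
    offs <- c(0L, cumsum(nlev))
    for (k in seq_len(K))
      u[[random[[k]]]] <- setNames(eng$u[(offs[k] + 1):offs[k + 1]], lev[[k]])
  }
  structure(list(
    kind = if (all(size == 1)) "bernoulli" else "binomial",
    beta = setNames(eng$beta, colnames(X)),
    se_beta = setNames(eng$se_beta, colnames(X)),
    vcov_beta = eng$vcov_beta,
    sigma = setNames(eng$sigma, unlist(random)),
    u = u,
    loglik = eng$loglik,
    deviance = eng$deviance,
    converged = eng$converged,
    singular = eng$singular,
    reason = eng$reason,
    n_obs = length(m), p_fixed = ncol(X),
    eta = eng$eta,
    fitted_p = plogis(eng$eta),
    m = m, size = size, fixed = fixed,
    response_checksum = c(sum(m), sum(size))),
    class = "glmm_fit")
}

# Deterministic Laplace-GLMM engine on raw matrices: the genome-wide scan
# calls this once per site (twice, full and reduced) so it avoids all
# data.frame / formula overhead.
glmm_engine <- function(m, size, X, G, nlev, sigma_start = 0.5,
                        sigma_bounds = c(1e-6, 20), sigma_fixed = NULL) {
  K <- length(nlev)
  p <- ncol(X)
  state <- new.env(parent = emptyenv())
  state$v <- numeric(p + sum(nlev))
  state$failed <- FALSE
  state$best_dev <- Inf
  state$best_sig <- rep(sigma_start, K)
  fold <- function(par) pmin(pmax(abs(par), sigma_bounds[1]),
                             sigma_bounds[2])
  eval_dev <- function(par) {
    sig <- fold(par)
    res <- pirls_binom(m, size, X, G, nlev, sig, state$v,
                       200L, 1e-8, FALSE)
    if (is.null(res$deviance) || !is.finite(res$deviance)) {
      state$failed <- TRUE
      return(1e10)
    }
    state$v <- res$v
    if (res$deviance < state$best_dev) {
      state$best_dev <- res$deviance
      state$best_sig <- sig
    }
    res$deviance
  }
  if (!is.null(sigma_fixed)) {
    stopifnot(length(sigma_fixed) == K)
    sigma <- fold(sigma_fixed)
    opt_conv <- TRUE
  } else if (K > 0) {
    # The deviance is exactly flat in log sigma near the zero boundary and
    # its sigma-derivative vanishes at zero, so gradient-based outer
    # optimizers stall on the boundary plateaus.  Instead: a deterministic
    # coarse pre-search (diagonal SD values, single-factor axes, the
    # near-zero corner, and the configured start) followed by Nelder-Mead
    # on the natural SD scale, folding negatives by absolute value --
    # simplex moves at finite scale see the real deviance differences and
    # step off the boundary when an interior optimum exists.
    pre <- c(lapply(c(sigma_start, 0.2, 0.05), function(s) rep(s, K)),
             lapply(seq_len(K), function(k) {
               s <- rep(sigma_bounds[1], K); s[k] <- 0.3; s
             }),
             list(rep(sigma_bounds[1], K)))
    for (s in pre) eval_dev(s)
    start <- pmax(state$best_sig, 0.02)   # give the simplex room to move
    opt <- if (K == 1)
      optim(start, eval_dev, method = "Brent",
            lower = sigma_bounds[1], upper = sigma_bounds[2])
    else
      optim(start, eval_dev, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-8))
    # take the best point ever evaluated (optim can end on a worse one)
    eval_dev(opt$par)
    sigma <- state$best_sig
    opt_conv <- opt$convergence == 0
  } else {
    sigma <- numeric(0)
    opt_conv <- TRUE
  }
  fin <- pirls_binom(m, size, X, G, nlev, sigma, state$v, 200L, 1e-8, TRUE)

  reason <- ""
  converged <- opt_conv && isTRUE(fin$conv) && !state$failed
  if (is.null(fin$deviance)) {
    converged <- FALSE
    reason <- fin$reason
    fin$beta <- rep(NA_real_, p)
    fin$eta <- rep(NA_real_, length(m))
    fin$deviance <- NA_real_
    fin$u <- NULL
  } else if (any(abs(fin$beta) > SEPARATION_BOUND)) {
    converged <- FALSE
    reason <- "separation"
  } else if (!converged) {
    reason <- "no_convergence"
  }
  vcov_beta <- fin$vcov_beta
  se_beta <- if (!is.null(vcov_beta)) sqrt(pmax(diag(vcov_beta), 0))
             else rep(NA_real_, p)
  list(beta = as.numeric(fin$beta), se_beta = se_beta,
       vcov_beta = vcov_beta, sigma = as.numeric(sigma),
       u = if (is.null(fin$u)) NULL else as.numeric(fin$u),
       loglik = -fin$deviance / 2 + sum(lchoose(size, m)),
       deviance = fin$deviance, eta = as.numeric(fin$eta),
       converged = converged,
       singular = K > 0 && any(sigma < 1e-4),
       reason = reason)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit>", x$kind, "| n =", x$n_obs,
      "| logLik =", round(x$loglik, 2),
      if (!x$converged) paste0("| NOT CONVERGED (", x$reason, ")") else "",
      if (x$singular) "| singular" else "", "\n")
  print(round(rbind(estimate = x$beta, se = x$se_beta), 4))
  if (length(x$sigma)) {
    cat("random-effect SDs:\n")
    print(round(x$sigma, 4))
  }
  invisible(x)
}
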