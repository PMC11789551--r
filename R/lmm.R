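#' Fit a Gaussian linear mixed model by maximum likelihood
#'
#' ML (not REML) fit of `y = X beta + Z b + e` with independent Gaussian
#' random terms: any number of random intercept factors, plus optionally a
#' correlated random intercept + slope per grouping factor (used for the
#' handling-stress breath-rate model).  The deviance is profiled: for a
#' value of the relative covariance factor (the random-effect Cholesky
#' scaled by the residual SD), `beta`, the spherical modes `u`, and the
#' residual variance have closed forms, so the outer bounded quasi-Newton
#' optimization runs only over the covariance parameters (diagonal entries
#' bounded at zero, so singular fits land exactly on the boundary).
#'
#' @param y numeric response vector.
#' @param data `data.frame` with covariates, one row per observation.
#' @param fixed one-sided fixed-effect formula.
#' @param random list of random terms: a character scalar names a random
#'   intercept factor; `list(factor = "individual", slope = "bout")`
#'   requests a correlated random intercept + slope of `bout` within
#'   `individual`.  `list()` gives ordinary least squares (ML).
#' @return an object of class `lmm_fit`: `beta`, `se_beta`, `vcov_beta`,
#'   `sigma` (named random-effect SDs, plus `residual`), `corr` (named
#'   intercept-slope correlations where applicable), `blups` (per-term
#'   conditional modes on the data scale), `loglik`, `converged`,
#'   `singular`, `degenerate` (residual SD collapsed to zero).
#' @examples
#' cfg <- sim_config(seed = 3, n_brood_pairs = 6)
#' d <- simulate_design(cfg)
#' ph <- simulate_phenotypes(cfg, d)
#' fit <- fit_lmm(ph$individuals$weight_d14, d)
#' fit$beta
#' @export
fit_lmm <- function(y, data, fixed = ~ treatment * sex,
                    random = list("brood_origin", "brood_rearing")) {
  stopifnot(length(y) == nrow(data))
  sp <- unpack_spec(fixed, random)
  fixed <- sp$fixed
  random <- sp$random
  if (is.character(random)) random <- as.list(random)
  X <- build_fixed_X(fixed, data)
  N <- length(y)
  p <- ncol(X)

  # random-term bookkeeping: Zraw columns per term on the data scale,
  # plus a builder mapping theta -> Z Lambda (columns of the scaled design)
  terms <- lapply(random, function(r) {
    if (is.character(r) && length(r) == 1L) {
      f <- factor(data[[r]])
      list(kind = "intercept", name = r, f = f, q = nlevels(f),
           n_theta = 1L, lower = 0, start = 1)
    } else {
      f <- factor(data[[r$factor]])
      list(kind = "intslope", name = r$factor, slope = r$slope, f = f,
           x = data[[r$slope]], q = 2L * nlevels(f),
           n_theta = 3L, lower = c(0, -Inf, 0), start = c(1, 0, 1))
    }
  })
  q_tot <- sum(vapply(terms, `[[`, 1L, "q"))
  n_theta <- vapply(terms, `[[`, 1L, "n_theta")

  build_ZL <- function(theta) {
    if (!length(terms)) return(matrix(0, N, 0))
    pieces <- list()
    pos <- 0L
    for (k in seq_along(terms)) {
      tk <- terms[[k]]
      th <- theta[(pos + 1):(pos + tk$n_theta)]
      pos <- pos + tk$n_theta
      ind <- outer(tk$f, levels(tk$f), "==") * 1
      if (tk$kind == "intercept") {
        pieces[[k]] <- ind * th[1]
      } else {
        Zint <- ind
        Zslo <- ind * tk$x
        # b_int = t1 u1 ; b_slope = t2 u1 + t3 u2
        cols <- matrix(0, N, tk$q)
        cols[, seq(1, tk$q, 2)] <- Zint * th[1] + Zslo * th[2]
        cols[, seq(2, tk$q, 2)] <- Zslo * th[3]
        pieces[[k]] <- cols
      }
    }
    do.call(cbind, pieces)
  }

  yy <- sum(y * y)
  profiled <- function(theta, details = FALSE) {
    L <- build_ZL(theta)
    q <- ncol(L)
    A <- cbind(L, X)
    M <- crossprod(A)
    if (q > 0) diag(M)[1:q] <- diag(M)[1:q, drop = FALSE] + 1
    rhs <- crossprod(A, y)
    R <- tryCatch(chol(M + diag(1e-10, nrow(M))), error = function(e) NULL)
    if (is.null(R)) return(if (details) NULL else 1e10)
    sol <- backsolve(R, forwardsolve(t(R), rhs))
    r2 <- max(yy - sum(rhs * sol), 0)
    s2 <- max(r2 / N, 1e-300)
    ld <- if (q > 0) {
      Ru <- chol(M[1:q, 1:q, drop = FALSE] + diag(1e-10, q))
      2 * sum(log(diag(Ru)))
    } else 0
    dev <- N * log(2 * pi * s2) + N + ld
    if (!details) return(dev)
    Minv <- chol2inv(R)
    list(dev = dev, u = if (q > 0) sol[1:q] else numeric(0),
         beta = sol[(q + 1):(q + p)], s2 = s2, r2 = r2,
         vcov_beta = s2 * Minv[(q + 1):(q + p), (q + 1):(q + p), drop = FALSE],
         L = L)
  }

  if (length(terms)) {
    start <- unlist(lapply(terms, `[[`, "start"))
    lower <- unlist(lapply(terms, `[[`, "lower"))
    opt <- optim(start, profiled, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500))
    theta <- opt$par
    opt_conv <- opt$convergence == 0
  } else {
    theta <- numeric(0)
    opt_conv <- TRUE
  }
  fin <- profiled(theta, details = TRUE)
  if (is.null(fin)) stop("linear mixed model fit failed (singular system)")

  sd_resid <- sqrt(fin$s2)
  # unpack per-term SDs / correlations and data-scale BLUPs b = Lambda u
  sigma <- c(); corr <- c(); blups <- list()
  pos <- 0L; upos <- 0L
  for (tk in terms) {
    th <- theta[(pos + 1):(pos + tk$n_theta)]
    pos <- pos + tk$n_theta
    uk <- fin$u[(upos + 1):(upos + tk$q)]
    upos <- upos + tk$q
    if (tk$kind == "intercept") {
      sigma[tk$name] <- sd_resid * th[1]
      # data-scale conditional mode: b = Lambda u (u solves the penalized LS)
      blups[[tk$name]] <- setNames(th[1] * uk, levels(tk$f))
    } else {
      u1 <- uk[seq(1, tk$q, 2)]; u2 <- uk[seq(2, tk$q, 2)]
      b_int <- th[1] * u1
      b_slo <- th[2] * u1 + th[3] * u2
      sigma[paste0(tk$name, ".intercept")] <- sd_resid * th[1]
      sigma[paste0(tk$name, ".slope")] <- sd_resid * sqrt(th[2]^2 + th[3]^2)
      den <- th[1] * sqrt(th[2]^2 + th[3]^2)
      corr[tk$name] <- if (den > 0) th[1] * th[2] / den else NA_real_
      blups[[paste0(tk$name, ".intercept")]] <- setNames(b_int, levels(tk$f))
      blups[[paste0(tk$name, ".slope")]] <- setNames(b_slo, levels(tk$f))
    }
  }
  sigma["residual"] <- sd_resid
  # relative threshold: catches constant responses despite the ridge- and
  # cancellation-level noise left in the residual sum of squares
  degenerate <- sd_resid < 1e-4 * max(1, sqrt(yy / N))

  structure(list(
    kind = "gaussian",
    beta = setNames(as.numeric(fin$beta), colnames(X)),
    se_beta = setNames(sqrt(pmax(diag(fin$vcov_beta), 0)), colnames(X)),
    vcov_beta = fin$vcov_beta,
    sigma = sigma, corr = corr, theta = theta, blups = blups,
    loglik = -fin$dev / 2, deviance = fin$dev,
    converged = opt_conv, degenerate = degenerate,
    singular = length(theta) > 0 &&
      any(theta[unlist(lapply(terms, function(t)
        if (t$kind == "intercept") TRUE else c(TRUE, FALSE, TRUE)))] < 1e-4),
    reason = if (opt_conv) "" else "no_convergence",
    n_obs = N, p_fixed = p,
    fitted = as.numeric(X %*% fin$beta +
                          (if (ncol(fin$L)) fin$L %*% fin$u else 0)),
    y = y, fixed = fixed,
    response_checksum = c(sum(y), N)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> n =", x$n_obs, "| logLik =", round(x$loglik, 2),
      if (x$degenerate) "| DEGENERATE (residual SD ~ 0)" else "", "\n")
  print(round(rbind(estimate = x$beta, se = x$se_beta), 4))
  cat("SDs:\n"); print(round(x$sigma, 4))
  invisible(x)
}

#' Extract per-individual random-slope deviations (BLUPs)
#'
#' Returns the conditional modes of the random slope from a model fitted
#' with a correlated intercept + slope term -- for the handling-stress
#' pipeline, the individual deviation from the average change in breath
#' rate over the four bouts.  Modes are shrunken towards zero and average
#' approximately zero across individuals; when all trajectories are
#' parallel the slope variance is estimated exactly zero and so are all
#' deviations.
#'
#' @param fit an [fit_lmm()] result containing a random-slope term.
#' @param factor name of the grouping factor (default: the single slope
#'   term present).
#' @return named numeric vector of slope deviations, one per level.
#' @export
random_slope_blups <- function(fit, factor = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  slopes <- grep("\\.slope$", names(fit$blups), value = TRUE)
  if (!length(slopes)) stop("fit has no random-slope term")
  nm <- if (is.null(factor)) slopes[1] else paste0(factor, ".slope")
  if (!nm %in% names(fit$blups)) stop("no random slope for factor ", factor)
  fit$blups[[nm]]
}
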