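# Independent oracles used across the suite.  Each is written from the
# definition it checks, not from the package implementation.

# plain logistic regression for binomial counts by hand-rolled IRLS
irls_logistic <- function(X, m, n, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- n * p * (1 - p)
    z <- eta + (m - n * p) / pmax(w, 1e-12)
    WX <- X * w
    beta_new <- solve(crossprod(X, WX), crossprod(WX, z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  ll <- sum(lchoose(n, m) + m * log(p) + (n - m) * log1p(-p))
  list(beta = drop(beta), loglik = ll)
}

# definitional Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(sort(p)[i:m] * m / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exhaustive shortest-window HDI: try every window of k sorted values
hdi_oracle <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- NULL
  best_w <- Inf
  for (i in seq_len(n - k + 1)) {
    w <- s[i + k - 1] - s[i]
    if (w < best_w) { best_w <- w; best <- c(s[i], s[i + k - 1]) }
  }
  which(x >= best[1] & x <= best[2])
}

# DMS category truth table, enumerated case by case from the definitions
categorize_oracle <- function(sig_f, sig_m, dir_f, dir_m, other_sig) {
  both <- sig_f && sig_m
  neither <- !sig_f && !sig_m
  if (both && dir_f != dir_m) return("antagonistic")
  if (both && dir_f == dir_m) return("concordant")
  if (sig_f) return("female_specific")
  if (sig_m) return("male_specific")
  if (neither && other_sig) return("other")
  "unclassified"
}

# all-pairs region assignment: loops over every gene, collects every
# membership, then applies priority and tie-break rules literally
annotate_oracle <- function(chrom, pos, models) {
  genes <- models$genes
  exons <- models$exons
  cand <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    up <- g$strand == "+"
    tss_lo <- if (up) g$tss - 300 else g$tss - 50
    tss_hi <- if (up) g$tss + 50 else g$tss + 300
    pr_lo <- if (up) g$tss - 2000 else g$tss - 200
    pr_hi <- if (up) g$tss + 200 else g$tss + 2000
    us_lo <- if (up) g$start - 10000 else g$end + 1
    us_hi <- if (up) g$start - 1 else g$end + 10000
    ds_lo <- if (up) g$end + 1 else g$start - 10000
    ds_hi <- if (up) g$end + 10000 else g$start - 1
    add <- function(cls) {
      cand[[length(cand) + 1]] <<- data.frame(
        gene_id = g$gene_id, class = cls, tss = g$tss,
        characterized = g$characterized,
        dist = if (pos < g$start) g$start - pos
               else if (pos > g$end) pos - g$end else 0,
        stringsAsFactors = FALSE)
    }
    if (pos >= tss_lo && pos <= tss_hi) add("TSS")
    if (pos >= pr_lo && pos <= pr_hi) add("promoter")
    if (pos >= g$start && pos <= g$end) add("body")
    if (pos >= us_lo && pos <= us_hi) add("upstream")
    if (pos >= ds_lo && pos <= ds_hi) add("downstream")
  }
  if (!length(cand))
    return(list(region = "intergenic", gene_id = NA_character_))
  cand <- do.call(rbind, cand)
  for (cls in c("TSS", "promoter", "body")) {
    sub <- cand[cand$class == cls, , drop = FALSE]
    if (nrow(sub)) {
      sub <- sub[order(abs(sub$tss - pos)), , drop = FALSE]
      gene <- sub$gene_id[1]
      region <- cls
      if (cls == "body") {
        ex <- exons[exons$gene_id == gene, , drop = FALSE]
        region <- if (any(pos >= ex$start & pos <= ex$end)) "exon" else "intron"
      }
      return(list(region = region, gene_id = gene))
    }
  }
  sub <- cand[cand$class %in% c("upstream", "downstream"), , drop = FALSE]
  sub <- sub[order(!sub$characterized, sub$dist, sub$gene_id), , drop = FALSE]
  list(region = sub$class[1], gene_id = sub$gene_id[1])
}

# joint one-pass filtering oracle: evaluates the coverage mask and both
# site rules together on raw matrices
filter_oracle <- function(meth, cov, trt, min_cov = 10, pct_cap = 99.9,
                          min_per_treatment = 15, mean_lo = 0.05,
                          mean_hi = 0.95) {
  caps <- apply(cov, 2, function(x)
    quantile(x[!is.na(x)], pct_cap / 100, type = 7, names = FALSE))
  for (j in seq_len(ncol(cov))) {
    bad <- !is.na(cov[, j]) & (cov[, j] < min_cov | cov[, j] > caps[j])
    meth[bad, j] <- NA
    cov[bad, j] <- NA
  }
  keep <- logical(nrow(cov))
  for (i in seq_len(nrow(cov))) {
    obs <- !is.na(cov[i, ])
    nc <- sum(obs & trt == "control")
    nt <- sum(obs & trt == "testosterone")
    mu <- mean(meth[i, obs] / cov[i, obs])
    keep[i] <- nc >= min_per_treatment && nt >= min_per_treatment &&
      !is.nan(mu) && mu >= mean_lo && mu <= mean_hi
  }
  list(meth = meth[keep, , drop = FALSE], cov = cov[keep, , drop = FALSE],
       keep = keep)
}
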