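# Independent oracles: each re-derives a quantity by a route disjoint from
# the package implementation it checks.

# Cosinor OLS by explicit normal equations (3x3 solve, no lm).
oracle_cosinor <- function(time_h, y, period = 24) {
  X <- cbind(1, cos(2 * pi * time_h / period), sin(2 * pi * time_h / period))
  A <- t(X) %*% X
  b <- solve(A) %*% (t(X) %*% y)
  resid <- y - X %*% b
  n <- length(y)
  sigma2 <- sum(resid^2) / (n - 3)
  list(mesor = b[1], beta = b[2], gamma = b[3],
       cov3 = sigma2 * solve(A), sigma2 = sigma2)
}

# Upper-tail F probability through the incomplete beta, not pf().
oracle_f_upper <- function(f, d1, d2) {
  stats::pbeta(d2 / (d2 + d1 * f), d2 / 2, d1 / 2)
}

# Benjamini-Hochberg by literal step-up enumeration.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(p[ord][js] * m / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Pooled two-sample t by the textbook formula.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# PERMANOVA pseudo-F recomputed from squared dissimilarities directly.
oracle_pseudo_f <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  a <- length(unique(labels))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Exact permutation p for a two-group design by exhaustive enumeration of
# distinct label assignments (includes the observed one).
oracle_perm_enum_p <- function(d, labels) {
  n <- length(labels)
  g1 <- unique(labels)[1]
  k <- sum(labels == g1)
  f_obs <- oracle_pseudo_f(d, labels)
  sets <- utils::combn(n, k)
  fs <- apply(sets, 2, function(idx) {
    lab <- rep(unique(labels)[2], n)
    lab[idx] <- g1
    oracle_pseudo_f(d, lab)
  })
  mean(fs >= f_obs - 1e-12)
}

# Circular mean of clock times in hours.
circ_mean_h <- function(a, period = 24) {
  th <- 2 * pi * a / period
  (atan2(mean(sin(th)), mean(cos(th))) * period / (2 * pi)) %% period
}

# Shared small fixtures -------------------------------------------------

zt6 <- c(2, 6, 10, 14, 18, 22)

noiseless_cohort <- function(mesor, amplitude, acrophase_h,
                             timepoints = zt6, reps = 2, period = 24) {
  t_h <- rep(timepoints, each = reps)
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(t_h)),
    group = "WT",
    time_h = t_h,
    feature = "f",
    value = mesor + amplitude *
      cos(2 * pi * t_h / period - 2 * pi * acrophase_h / period)
  )
}

demo_community <- function(n_taxa = 5, osc_taxon = NULL, osc_amp = 0,
                           osc_acro = 19) {
  baseline <- (1 / seq_len(n_taxa))^0.7
  baseline <- baseline / sum(baseline)
  amp <- rep(0, n_taxa)
  if (!is.null(osc_taxon)) amp[osc_taxon] <- osc_amp
  phyla <- rep(c("Bacteroidota", "Bacillota", "Pseudomonadota"),
               length.out = n_taxa)
  community_params(
    taxon_id = sprintf("genus_%02d", seq_len(n_taxa)),
    lineage = sprintf("Bacteria;%s;c;o;f;genus_%02d", phyla,
                      seq_len(n_taxa)),
    baseline = baseline, amplitude = amp, acrophase_h = osc_acro
  )
}
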