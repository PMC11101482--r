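# Independent oracles used to verify pipeline computations. Each is a
# deliberately naive implementation (enumeration / direct formula), kept
# separate from the code paths it checks.

# Benjamini-Hochberg step-up by direct inequality: reject all p <= p_(k*)
# where k* is the largest k with p_(k) <= k * alpha / m.
bh_flags_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * alpha / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins.
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive K-medoids optimum: minimum total squared Euclidean cost over
# every possible medoid subset.
pam_cost_oracle <- function(x, k) {
  d2 <- as.matrix(stats::dist(x))^2
  sets <- utils::combn(nrow(x), k)
  min(apply(sets, 2, function(m)
    sum(apply(d2[, m, drop = FALSE], 1, min))))
}

# FR by explicit loop over unordered cluster pairs.
fr_oracle <- function(centroids) {
  k <- nrow(centroids)
  apply(centroids, 2, function(mu) {
    s <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) s <- s + (mu[i] - mu[j])^2
    sqrt(s)
  })
}

# Two-group log-rank statistic by the observed-minus-expected
# hypergeometric sum over distinct event times.
logrank_oracle <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Small deterministic cohort for fast tests.
small_bundle <- function(n = 80, seed = 3, ...) {
  generate_cohort(generator_config(n_patients = n, seed = seed, ...))
}
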