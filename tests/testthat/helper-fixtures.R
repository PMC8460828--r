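# Shared fixture builders. Everything is generated in code; no binary data.

make_expr <- function(n_genes = 20, n_samples = 10, seed = 1,
                      genes = sprintf("G%02d", seq_len(n_genes)),
                      samples = sprintf("S%02d", seq_len(n_samples))) {
  set.seed(seed)
  m <- matrix(round(stats::runif(n_genes * n_samples, 0, 10), 4),
              n_genes, n_samples, dimnames = list(genes, samples))
  expression_matrix(m)
}

make_groups <- function(samples, n_a, label_a = "A", label_b = "B") {
  stats::setNames(rep(c(label_a, label_b),
                      c(n_a, length(samples) - n_a)), samples)
}

# Brute-force two-sided Fisher p by direct hypergeometric enumeration:
# sum the point probabilities of every table with the observed margins
# whose probability is <= the observed one (1e-7 relative tolerance).
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Min-over-tail BH definition: q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive running-sum ssGSEA for one sample, evaluated term by term.
oracle_ssgsea_sample <- function(values, set_genes, alpha) {
  genes <- names(values)
  r <- rank(values, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  es <- 0; cin <- 0; cout <- 0
  win <- sum(abs(r[genes %in% set_genes])^alpha)
  nout <- sum(!(genes %in% set_genes))
  for (g in genes[ord]) {
    if (g %in% set_genes) cin <- cin + abs(r[g])^alpha / win
    else cout <- cout + 1 / nout
    es <- es + (cin - cout)
  }
  as.numeric(es)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# the pooled ranks to the first group.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  stat <- apply(idx, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  lo <- mean(stat <= w_obs)
  hi <- mean(stat >= w_obs)
  min(1, 2 * min(lo, hi))
}
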