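# Shared fixtures, built in code at test time.

# a small, fast study: 1/5 of the default feature counts
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_meth_features = 400, n_expr_features = 400,
    n_diff_meth = 40, n_diff_expr = 24,
    trait_signal_features = 8, n_overlap_genes = 2,
    n_genes = 40, vocab_size = 60,
    abstracts_per_gene_range = c(3, 6),
    seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-steppable Benjamini-Hochberg oracle: q_(i) = min_{j>=i} p_(j) m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exhaustive two-sided Fisher oracle: enumerate every table with the same
# margins and sum point probabilities (from binomial coefficients) not
# exceeding the observed one
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  pt <- function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }
  probs <- vapply(support, pt, numeric(1))
  obs <- pt(a)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
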