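# Shared fixtures and independent oracles. All fixtures are generated in
# code; the oracles are deliberately naive (loops, enumeration) so they
# stay independent of the implementation they check.

tiny_reference <- function(seed = 1, n_types = 3, n_cells_per_type = 40,
                           n_genes = 60, n_markers_per_type = 5,
                           fold_change = 8) {
  make_reference(n_types = n_types, n_cells_per_type = n_cells_per_type,
                 n_genes = n_genes, n_markers_per_type = n_markers_per_type,
                 fold_change = fold_change, seed = seed)
}

# raw counts -> lognorm count_matrix
as_lognorm <- function(m, target_sum = 1e4) {
  log1p_transform(normalize_total(m, target_sum))
}

# Plain-loop KLD: mean over rows of sum_k Y log(Y/(S+eps)), 0 log 0 = 0.
loop_kld <- function(Y, S, eps = 1e-8) {
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    acc <- 0
    for (k in seq_len(ncol(Y))) {
      if (Y[i, k] > 0) acc <- acc + Y[i, k] * log(Y[i, k] / (S[i, k] + eps))
    }
    tot <- tot + acc
  }
  tot / nrow(Y)
}

loop_adv_gen <- function(dp, dr, eps = 1e-8) {
  dp <- pmin(pmax(dp, eps), 1 - eps)
  dr <- pmin(pmax(dr, eps), 1 - eps)
  acc <- 0
  for (i in seq_along(dp)) acc <- acc - log(dp[i])
  acc <- acc / length(dp)
  acc2 <- 0
  for (i in seq_along(dr)) acc2 <- acc2 - log(1 - dr[i])
  acc + acc2 / length(dr)
}

# Exact one-sided rank-sum p-value by enumeration of all group assignments
# of the pooled sample (valid with ties; n choose n1 must be small).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stat <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(stat >= obs)
}

# Brute-force AUC: pairwise concordance with half credit for ties.
brute_force_auc <- function(scores, positives) {
  pos <- scores[positives]
  neg <- scores[!positives]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  acc / (length(pos) * length(neg))
}

# Region priors with one type restricted to the "inside" region.
restricted_priors <- function(n_types = 5) {
  types <- sprintf("type_%d", seq_len(n_types))
  inside <- stats::setNames(c(0.4, rep(0.6 / (n_types - 1), n_types - 1)),
                            types)
  outside <- stats::setNames(c(0, rep(1 / (n_types - 1), n_types - 1)),
                             types)
  list(inside = inside, outside = outside)
}
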