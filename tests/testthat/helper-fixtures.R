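# Small in-code fixtures and independent oracles shared across tests.

# genes x cells matrix with named rows, flavor as requested
toy_matrix <- function(values, gene_ids, cell_ids = NULL,
                       flavor = "log2_tpm10") {
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  expr_matrix(values, flavor = flavor)
}

# Exhaustive permutation oracle for the rank-sum test (midranks; the
# two-sided P is the permutation mass at least as far from the null mean).
ranksum_perm_oracle <- function(x, y, alternative) {
  pool <- c(x, y)
  n <- length(pool)
  nx <- length(x)
  r <- rank(pool)
  w <- sum(r[seq_len(nx)])
  e <- nx * (n + 1) / 2
  ws <- apply(utils::combn(n, nx), 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  switch(alternative,
         greater = mean(ws >= w - eps),
         less = mean(ws <= w + eps),
         two_sided = mean(abs(ws - e) >= abs(w - e) - eps))
}

# Direct binomial upper-tail summation
binom_tail_oracle <- function(k, n, p0) {
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# Brute-force AUROC pair counting: fraction of (responder, non-responder)
# pairs where the responder has the higher predictor (+0.5 per tie).
auroc_pair_oracle <- function(pred_resp, pred_non) {
  tot <- 0
  for (a in pred_resp) {
    for (b in pred_non) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pred_resp) * length(pred_non))
}
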