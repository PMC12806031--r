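# Independent brute-force oracles used across the suite.

# Step-up BH by its textbook definition: adjusted p for the gene ranked k
# (ascending) is min over j >= k of p_(j) * m / j, clipped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    vals <- numeric(0)
    for (j in k:m) {
      vals <- c(vals, p[ord[j]] * m / j)
    }
    adj[ord[k]] <- min(1, vals)
  }
  adj
}

# ssGSEA by naive enumeration: walk the descending-expression ranking and
# accumulate the in-set weighted ECDF minus the out-of-set ECDF.
brute_ssgsea <- function(x, gene_set, exponent = 0) {
  genes <- names(sort(x, decreasing = TRUE))
  n_out <- sum(!genes %in% gene_set)
  w_total <- 0
  for (g in genes) {
    if (g %in% gene_set) w_total <- w_total + abs(x[g])^exponent
  }
  score <- 0
  w_seen <- 0
  out_seen <- 0
  for (g in genes) {
    if (g %in% gene_set) {
      w_seen <- w_seen + abs(x[g])^exponent
    } else {
      out_seen <- out_seen + 1
    }
    score <- score + (w_seen / w_total - out_seen / n_out)
  }
  unname(score)
}

# Analytic optimum of the two-sink balanced allocation QP:
# max w1 v1 + w2 v2 - lambda (v1^2 + v2^2), v1 + v2 = V, 0 <= vi <= Bi.
two_sink_closed_form <- function(w1, w2, lambda, V, B1, B2) {
  lo <- max(0, V - B2)
  hi <- min(B1, V)
  v1 <- min(max(V / 2 + (w1 - w2) / (4 * lambda), lo), hi)
  c(v1, V - v1)
}

# A tiny two-group log2 expression matrix with named genes/samples.
tiny_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}
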