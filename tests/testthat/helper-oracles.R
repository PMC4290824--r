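# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (direct summation / closed forms) and
# never share code with the implementation they check.

# CDF of the k-th smallest of n uniforms at u, via the binomial sum
# P(U_(k) <= u) = sum_{i=k}^{n} C(n,i) u^i (1-u)^(n-i).
oracle_order_stat_cdf <- function(u, k, n) {
  i <- k:n
  sum(choose(n, i) * u^i * (1 - u)^(n - i))
}

# Upper/lower NB tail by brute-force PMF summation.
oracle_nb_tail <- function(mu, var, threshold, direction,
                           x_max = 10000L) {
  size <- mu^2 / (var - mu)
  prob <- mu / var
  if (direction == "greater") {
    xs <- seq.int(floor(threshold) + 1, x_max)
    sum(dnbinom(xs, size = size, prob = prob))
  } else {
    hi <- ceiling(threshold) - 1
    if (hi < 0) 0 else sum(dnbinom(0:hi, size = size, prob = prob))
  }
}

# Step-up Benjamini-Hochberg written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# A tiny hand-built screen table: `rows` is a list of count vectors.
make_table <- function(rows, genes = NULL, samples = NULL) {
  counts <- do.call(rbind, rows)
  m <- nrow(counts)
  make_ids <- function(prefix, n) sprintf("%s%d", prefix, seq_len(n))
  count_table(counts,
              sgrna_ids = make_ids("sg", m),
              gene_ids = genes %||% make_ids("gene", m),
              sample_names = samples %||% make_ids("s", ncol(counts)))
}

# Standard design for simulator output.
sim_design <- function(n_control = 2, n_treatment = 2) {
  design_spec(sprintf("control_%d", seq_len(n_control)),
              sprintf("treatment_%d", seq_len(n_treatment)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
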