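#' Configuration for alpha-RRA aggregation
#'
#' @param p_threshold Significance cut applied to the per-item p-values
#'   (NB p-values for sgRNAs, permutation p-values for genes at the
#'   pathway level) when deciding which items are "good". Default 0.05.
#' @param alpha_percent Top fraction of the ranked list an item must fall
#'   in to be "good". Default `NULL`: use the realized fraction of items
#'   passing `p_threshold`, which makes the two criteria coincide.
#' @param num_permutations Number of null permutations per gene-size
#'   stratum. Default `NULL`: 100 times the number of groups (genes or
#'   pathways) being tested.
#' @param seed Integer RNG seed making the permutation null reproducible.
#' @return An object of class `alpha_config`.
#' @export
alpha_config <- function(p_threshold = 0.05, alpha_percent = NULL,
                         num_permutations = NULL, seed = 1L) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop("alpha_config: p_threshold must be in (0, 1]", call. = FALSE)
  if (!is.null(alpha_percent) &&
      (alpha_percent < 0 || alpha_percent > 1))
    stop("alpha_config: alpha_percent must be in [0, 1]", call. = FALSE)
  if (!is.null(num_permutations) && num_permutations < 1)
    stop("alpha_config: num_permutations must be >= 1", call. = FALSE)
  structure(list(p_threshold = p_threshold, alpha_percent = alpha_percent,
                 num_permutations = num_permutations,
                 seed = as.integer(seed)),
            class = "alpha_config")
}

#' Beta order-statistic p-values of rank percentiles
#'
#' Under the null that a gene's sgRNAs are exchangeable with all others,
#' their rank percentiles are order statistics of n uniforms, and the
#' k-th smallest follows Beta(k, n + 1 - k).  `p_k` is the probability
#' that the k-th smallest of n uniforms is at most `u[k]` - small when
#' the gene's sgRNAs sit unusually close to the top of the list.
#'
#' @param u Numeric vector of percentiles in (0, 1], sorted ascending.
#' @return Vector `p` with `p[k] = P(Beta(k, n + 1 - k) <= u[k])`.
#' @export
beta_order_pvalues <- function(u) {
  n <- length(u)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(u))
    stop("beta_order_pvalues: percentiles must be sorted ascending",
         call. = FALSE)
  if (any(u <= 0 | u > 1))
    stop("beta_order_pvalues: percentiles must lie in (0, 1]",
         call. = FALSE)
  k <- seq_len(n)
  stats::pbeta(u, k, n + 1 - k)
}

#' Flag the "good" items of a ranked list
#'
#' The alpha modification of RRA: an item counts toward a group's score
#' only if its directional p-value is below `p_threshold` *and* it falls
#' within the top `alpha_percent` fraction of the ranked list.  With the
#' default `alpha_percent` (the realized fraction passing the threshold)
#' the two criteria select the same prefix.  Because the list is ranked
#' by that same p-value, the good set is always a rank prefix.
#'
#' @param p Item p-values, in rank order (ascending).
#' @param cfg An [alpha_config].
#' @return Logical vector, `TRUE` for good items, in rank order.
#' @export
alpha_select <- function(p, cfg = alpha_config()) {
  m <- length(p)
  pass <- p < cfg$p_threshold
  alpha <- cfg$alpha_percent %||% (sum(pass) / m)
  pass & seq_len(m) <= floor(alpha * m + 1e-9)
}

#' The rho score of a group of ranked items
#'
#' The significance score of alpha-RRA: the minimum of the first `j`
#' beta order-statistic p-values, where `j` is the number of good items
#' in the group (always the `j` smallest percentiles, since goodness is
#' a rank prefix).  A group with no good item scores rho = 1.  Items
#' beyond the good prefix never influence the score, which is what lets
#' the method ignore inert sgRNAs concentrated mid-list.
#'
#' @param u Sorted ascending percentiles of the group's items.
#' @param j Number of good items, `0 <= j <= length(u)`.
#' @return The rho score in (0, 1].
#' @export
rho_score <- function(u, j) {
  if (j > length(u))
    stop("rho_score: j exceeds the number of items", call. = FALSE)
  if (j == 0L) return(1)
  min(beta_order_pvalues(u)[seq_len(j)])
}

# Vectorized rho for a matrix of rank draws: one row per permutation,
# n columns of ranks in 1..m; good items are exactly ranks <= n_good.
# Returns one null rho per row.
rho_from_rank_matrix <- function(ranks, m, n_good) {
  n <- ncol(ranks)
  sorted <- matrix(ranks[order(row(ranks), ranks)],
                   ncol = n, byrow = TRUE)
  j <- rowSums(sorted <= n_good)
  cummin_p <- matrix(NA_real_, nrow(ranks), n)
  acc <- rep(Inf, nrow(ranks))
  for (k in seq_len(n)) {
    acc <- pmin(acc, stats::pbeta(sorted[, k] / m, k, n + 1 - k))
    cummin_p[, k] <- acc
  }
  rho <- rep(1, nrow(ranks))
  hasj <- j > 0
  rho[hasj] <- cummin_p[cbind(which(hasj), j[hasj])]
  rho
}

#' Null rho samples by permutation
#'
#' Emulates random reassignment of sgRNAs to genes: for each group size
#' `n`, ranks are repeatedly drawn without replacement from `1..m`,
#' goodness is inherited from the drawn positions (an item is good iff
#' its rank lies in the good prefix), and the resulting rho scores form
#' the size-stratified null.  Stratifying by size with a shared pool per
#' size is distribution-identical to permuting gene labels directly and
#' reuses every draw across all genes of that size.
#'
#' @param sizes Integer vector of distinct group sizes to stratify on.
#' @param m Total number of ranked items (M sgRNAs, or n_g genes).
#' @param n_good Number of good items (the good rank prefix length).
#' @param num_permutations Null draws per stratum.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Named list mapping each size to its vector of null rho values.
#' @export
permutation_null <- function(sizes, m, n_good, num_permutations,
                             seed = 1L) {
  sizes <- sort(unique(as.integer(sizes)))
  b <- as.integer(num_permutations)
  withr::with_seed(seed, {
    out <- lapply(sizes, function(n) {
      if (n >= m) {
        # degenerate: the draw is the whole list, rho is constant
        return(rep(rho_score(seq_len(m) / m, min(n_good, m)), b))
      }
      draws <- matrix(0L, b, n)
      for (i in seq_len(b)) draws[i, ] <- sample.int(m, n)
      rho_from_rank_matrix(draws, m, n_good)
    })
  })
  names(out) <- as.character(sizes)
  out
}

#' Empirical permutation p-values from a size-stratified null
#'
#' @param rho Observed rho score per group.
#' @param n Group size per group (matched against the null strata).
#' @param null Size-stratified null from [permutation_null()].
#' @return Empirical p-values `(#{null <= rho} + 1) / (B + 1)`, the
#'   add-one estimator that keeps permutation p-values strictly positive.
#' @export
gene_pvalues <- function(rho, n, null) {
  key <- as.character(n)
  missing <- setdiff(unique(key), names(null))
  if (length(missing))
    stop("permutation p-values: no null stratum for group size(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(seq_along(rho), function(i) {
    pool <- null[[key[i]]]
    (sum(pool <= rho[i]) + 1) / (length(pool) + 1)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false discovery rate control with monotonicity
#' enforcement, applied across genes (or pathways) to the permutation
#' p-values.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Shared alpha-RRA driver for genes (items = sgRNAs) and pathways
# (items = genes).  `item_rank` is each member item's 1..m rank for the
# tested direction, `group` the group label per member.  `p_by_rank` is
# the directional p-value of the FULL ranked list in rank order (length
# m): the good prefix is a property of the whole list, independent of
# group membership.
rra_aggregate <- function(group, item_rank, p_by_rank, m, cfg,
                          n_groups_for_default = length(unique(group))) {
  stopifnot(length(group) == length(item_rank), length(p_by_rank) == m)
  good <- alpha_select(p_by_rank, cfg)
  n_good <- sum(good)           # good set is a rank prefix
  groups <- split(item_rank, group)
  n <- lengths(groups)
  rho <- vapply(groups, function(r) {
    u <- sort(r) / m
    rho_score(u, sum(sort(r) <= n_good))
  }, numeric(1))
  b <- cfg$num_permutations %||% (100L * n_groups_for_default)
  null <- permutation_null(unique(n), m, n_good, b, seed = cfg$seed)
  perm_p <- gene_pvalues(rho, n, null)
  j <- vapply(groups, function(r) sum(r <= n_good), integer(1))
  res <- data.frame(group = names(groups), n = as.integer(n), j = j,
                    rho = rho, perm_p = perm_p, fdr = bh_fdr(perm_p),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$rank <- order(order(res$perm_p, res$rho, res$group))
  res[order(res$rank), , drop = FALSE]
}

#' Gene-level alpha-RRA test
#'
#' Aggregates the ranked sgRNA list into per-gene selection scores: each
#' gene's sgRNA rank percentiles are scored with beta order statistics
#' restricted to the alpha-selected ("good") prefix, significance is
#' assessed by permutation (sgRNAs randomly reassigned to genes, gene
#' sizes preserved), and q-values are computed across genes by
#' Benjamini-Hochberg.  Run once per direction; both directions can be
#' computed from one [sgrna_test()] result.
#'
#' @param sgrna_results An `sgrna_results` data frame.
#' @param cfg An [alpha_config].
#' @param direction `"neg"` (depletion) or `"pos"` (enrichment).
#' @return A data frame of class `gene_results`, ranked most significant
#'   first, with columns `gene`, `n` (sgRNAs targeting the gene), `j`
#'   (good sgRNAs), `rho`, `perm_p`, `fdr`, `rank`.
#' @export
gene_test <- function(sgrna_results, cfg = alpha_config(),
                      direction = c("neg", "pos")) {
  direction <- match.arg(direction)
  m <- nrow(sgrna_results)
  rank_col <- if (direction == "neg") "rank_neg" else "rank_pos"
  p_col <- if (direction == "neg") "p_low" else "p_high"
  p_by_rank <- sgrna_results[[p_col]][order(sgrna_results[[rank_col]])]
  res <- rra_aggregate(sgrna_results$gene, sgrna_results[[rank_col]],
                       p_by_rank, m, cfg)
  names(res)[names(res) == "group"] <- "gene"
  attr(res, "direction") <- direction
  class(res) <- c("gene_results", "data.frame")
  res
}
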