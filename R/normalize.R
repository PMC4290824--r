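#' Median-ratio size factors
#'
#' Computes one scaling factor per sample by the median-ratio method: each
#' sample's factor is the median, over sgRNAs, of the ratio of that
#' sgRNA's count to its geometric mean across samples,
#' \deqn{s_j = \mathrm{median}_i\; x_{ij} / \hat x_i, \qquad
#'       \hat x_i = \Big(\prod_{k=1}^N x_{ik}\Big)^{1/N}.}
#' sgRNAs with a zero count in any sample have \eqn{\hat x_i = 0} and are
#' excluded from the median (a single zero annihilates the geometric
#' mean); they are still normalized by the resulting factors.
#'
#' @param table A [count_table] of raw counts.
#' @return An object of class `size_factors`: list with `factors` (named
#'   positive numeric, one per sample), `geometric_means` (one per sgRNA)
#'   and `n_used` (number of sgRNAs entering the median).
#' @seealso [normalize_counts()], [total_count_normalize()]
#' @export
compute_size_factors <- function(table) {
  x <- table$counts
  # geometric mean via mean of logs; any zero count forces it to zero
  gm <- exp(rowMeans(log(x)))
  gm[apply(x == 0, 1L, any)] <- 0
  use <- gm > 0
  if (!any(use))
    stop("size factors: no sgRNA has positive counts in every sample; ",
         "median-ratio normalization is undefined - consider ",
         "total_count_normalize()", call. = FALSE)
  ratios <- x[use, , drop = FALSE] / gm[use]
  s <- apply(ratios, 2L, stats::median)
  names(s) <- table$sample_names
  structure(list(factors = s,
                 geometric_means = stats::setNames(gm, table$sgrna_ids),
                 n_used = sum(use)),
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors (", x$n_used, " sgRNAs used):\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Normalize a count table by per-sample size factors
#'
#' Each count is divided by its sample's size factor and rounded
#' half-away-from-zero back to an integer, so the result is again a valid
#' count table.
#'
#' @param table A [count_table] of raw counts.
#' @param sf Size factors from [compute_size_factors()] on the same table;
#'   computed if missing.
#' @return A normalized [count_table].
#' @export
normalize_counts <- function(table, sf = compute_size_factors(table)) {
  adj <- round_half_away(sweep(table$counts, 2L, sf$factors, "/"))
  count_table(adj, table$sgrna_ids, table$gene_ids, table$sample_names)
}

#' Total-count normalization
#'
#' Scales every sample to the mean library size (sum of counts), then
#' rounds half-away-from-zero.  A simpler alternative to the median-ratio
#' method for libraries where few sgRNAs have all-positive counts.
#'
#' @param table A [count_table] of raw counts.
#' @return A normalized [count_table].
#' @export
total_count_normalize <- function(table) {
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("total-count normalization: sample(s) with zero total reads: ",
         paste(table$sample_names[totals == 0], collapse = ", "),
         call. = FALSE)
  s <- totals / mean(totals)
  adj <- round_half_away(sweep(table$counts, 2L, s, "/"))
  count_table(adj, table$sgrna_ids, table$gene_ids, table$sample_names)
}
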