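#' One-sided negative binomial tail probability
#'
#' Exact tail probability of the gamma-extended negative binomial with
#' the given method-of-moments parameters: the probability that a count
#' drawn from NB(\eqn{\mu}, \eqn{\sigma^2}) is strictly greater (or
#' strictly less) than `threshold`.  Non-integral thresholds are handled
#' literally: `x > t` means integer counts \eqn{x \ge \lfloor t \rfloor + 1},
#' `x < t` means \eqn{x \le \lceil t \rceil - 1}.
#'
#' @param params One-row data frame (or list) from [nb_params()], fields
#'   `r`, `p`, `mean`, `var`; `r` and `p` are vectorized.
#' @param threshold Count threshold (typically the other condition's mean
#'   \eqn{\mu_{iB}}); vectorized.
#' @param direction `"greater"` for the upper tail, `"less"` for the
#'   lower tail.
#' @return Tail probabilities in `(0, 1]` (floored at `1e-300`).
#' @export
nb_tail <- function(params, threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  size <- params$r
  prob <- 1 - params$p          # stats::pnbinom success probability
  p <- if (direction == "greater") {
    stats::pnbinom(floor(threshold), size = size, prob = prob,
                   lower.tail = FALSE)
  } else {
    q <- ceiling(threshold) - 1
    ifelse(q < 0, 0, stats::pnbinom(q, size = size, prob = prob))
  }
  pmax(p, P_FLOOR)
}

#' Per-sgRNA negative binomial test between two conditions
#'
#' For each sgRNA the control mean \eqn{\mu_{iA}} is taken as the null NB
#' mean, its variance \eqn{\sigma^2_{iA}} is predicted from the fitted
#' mean-variance model, and two one-sided tail probabilities are computed
#' against the treatment mean \eqn{\mu_{iB}}:
#' `p_high` = P(X > \eqn{\mu_{iB}}) tests positive selection (enrichment),
#' `p_low` = P(X < \eqn{\mu_{iB}}) tests negative selection (depletion).
#'
#' Control means of zero are replaced by a pseudo-mean of 0.5 normalized
#' counts before variance prediction (the NB is undefined at mean zero).
#' When the predicted variance does not exceed the mean it is inflated to
#' \eqn{\mu(1 + 10^{-2})}, the minimal overdispersion the NB
#' parameterization requires.  sgRNAs with zero counts in every sample
#' carry no evidence in either direction; they are assigned p-values of 1
#' and rank after all other sgRNAs.
#'
#' @param table A normalized [count_table].
#' @param design A [design_spec] naming control and treatment samples.
#' @param model A `mean_var_model`, fitted on the control replicates (or
#'   on all samples when the controls are unreplicated).
#' @return A data frame of class `sgrna_results` with columns `sgrna`,
#'   `gene`, `control_mean`, `treat_mean`, `adj_var`, `p_low`, `p_high`,
#'   `rank_neg`, `rank_pos`; row order follows the input table.
#' @export
sgrna_test <- function(table, design, model) {
  missing <- setdiff(c(design$control, design$treatment),
                     table$sample_names)
  if (length(missing))
    stop("sgRNA test: design sample(s) not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mu_a <- rowMeans(table$counts[, design$control, drop = FALSE])
  mu_b <- rowMeans(table$counts[, design$treatment, drop = FALSE])

  mu_null <- ifelse(mu_a == 0, 0.5, mu_a)
  var_null <- predict_variance(model, mu_null)
  var_null <- ifelse(var_null <= mu_null, mu_null * (1 + VAR_EPSILON),
                     var_null)
  params <- nb_params(mu_null, var_null)

  p_high <- nb_tail(params, mu_b, "greater")
  p_low <- nb_tail(params, mu_b, "less")
  p_high[table$all_zero] <- 1
  p_low[table$all_zero] <- 1

  res <- data.frame(sgrna = table$sgrna_ids, gene = table$gene_ids,
                    control_mean = mu_a, treat_mean = mu_b,
                    adj_var = var_null, p_low = p_low, p_high = p_high,
                    all_zero = table$all_zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$rank_neg <- order(rank_sgrnas(res, "neg"))
  res$rank_pos <- order(rank_sgrnas(res, "pos"))
  class(res) <- c("sgrna_results", "data.frame")
  res
}

#' Order sgRNAs by directional significance
#'
#' Returns the permutation that sorts sgRNAs ascending by the chosen
#' direction's p-value (`p_low` for negative selection, `p_high` for
#' positive).  Ties are broken by larger absolute mean difference
#' \eqn{|\mu_{iB} - \mu_{iA}|}, then by sgRNA id, so the order is total
#' and reproducible.  sgRNAs flagged all-zero always sort last: dropping
#' them would silently change every percentile \eqn{u_i = r_i / M}, so
#' they are kept in `M` but never compete for top ranks.
#'
#' @param results An `sgrna_results` data frame.
#' @param direction `"neg"` or `"pos"`.
#' @return Integer vector of row indices, most significant first.
#' @export
rank_sgrnas <- function(results, direction = c("neg", "pos")) {
  direction <- match.arg(direction)
  p <- if (direction == "neg") results$p_low else results$p_high
  all_zero <- results$all_zero %||% rep(FALSE, nrow(results))
  order(all_zero, p, -abs(results$treat_mean - results$control_mean),
        results$sgrna)
}
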