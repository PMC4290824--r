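#' Pathway-level alpha-RRA test
#'
#' Applies the same rank aggregation used for genes one level up: genes
#' play the role of sgRNAs, with percentiles taken from the gene ranking
#' of [gene_test()] and "good" genes defined by permutation p-value below
#' `cfg$p_threshold` within the top alpha fraction.  Genes in the
#' database that were not screened are dropped from each set; pathways
#' with no screened gene are excluded with a warning.  The default
#' permutation count is 100 times the number of testable pathways.
#'
#' @param gene_results A ranked `gene_results` data frame for one
#'   direction.
#' @param db A [read_gmt()] `pathway_db`.
#' @param cfg An [alpha_config].
#' @return A data frame of class `pathway_results` with columns
#'   `pathway`, `n` (screened genes in the set), `j` (good genes), `rho`,
#'   `perm_p`, `fdr`, `rank`, most significant first.
#' @export
pathway_test <- function(gene_results, db, cfg = alpha_config()) {
  n_g <- nrow(gene_results)
  gene_rank <- stats::setNames(gene_results$rank, gene_results$gene)
  sets <- lapply(db$pathways, function(g) intersect(g, gene_results$gene))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with no screened gene excluded: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "", call. = FALSE)
    sets <- sets[!empty]
  }
  if (!length(sets))
    stop("pathway test: no pathway shares a gene with the screen",
         call. = FALSE)
  membership <- data.frame(
    pathway = rep(names(sets), lengths(sets)),
    rank = gene_rank[unlist(sets, use.names = FALSE)],
    row.names = NULL, stringsAsFactors = FALSE)
  # p per gene in rank order: the gene ranking's own permutation p-values
  p_by_rank <- gene_results$perm_p[order(gene_results$rank)]
  res <- rra_aggregate(membership$pathway, membership$rank,
                       p_by_rank, n_g, cfg,
                       n_groups_for_default = length(sets))
  names(res)[names(res) == "group"] <- "pathway"
  attr(res, "direction") <- attr(gene_results, "direction")
  class(res) <- c("pathway_results", "data.frame")
  res
}
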