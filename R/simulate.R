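#' Configuration for the synthetic screen simulator
#'
#' The simulator generates count tables with the statistical structure
#' the analysis assumes: per-sgRNA baseline abundances drawn log-normal
#' (wide, as in real lentiviral libraries), counts drawn from a negative
#' binomial whose variance follows the power law
#' \eqn{\sigma^2 = \mu + k\mu^b}, and a chosen fraction of genes under
#' negative or positive selection with a constant fold change applied to
#' every treatment replicate.
#'
#' Defaults emulate a compact knockout screen: 500 genes with 4 sgRNAs
#' each, two replicates per condition, baseline abundance centered at
#' about 300 reads per sgRNA with a log-sd of 1 (roughly a 7-fold
#' interquartile spread), overdispersion `k = 0.2`, `b = 1.5`, no
#' selection, and 4-fold effects for selected genes when fractions are
#' positive.
#'
#' @param n_genes Number of genes.
#' @param sgrnas_per_gene sgRNAs targeting each gene.
#' @param n_control,n_treatment Replicates per condition.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-sgRNA baseline mean abundance (in reads).
#' @param k,b Parameters of the mean-variance law used for sampling;
#'   `k = 0` gives Poisson counts.
#' @param fraction_neg,fraction_pos Fractions of genes under negative /
#'   positive selection (sum at most 1).
#' @param effect_size Fold change magnitude for selected genes (> 0);
#'   negatively selected genes are depleted by this factor, positively
#'   selected genes enriched by it.
#' @param efficiency_sd Optional per-sgRNA jitter: log-normal sd applied
#'   multiplicatively to each sgRNA's log fold change, modeling unequal
#'   knockout efficiencies. Default 0 (all sgRNAs fully effective).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, sgrnas_per_gene = 4L,
                       n_control = 2L, n_treatment = 2L,
                       baseline_meanlog = log(300), baseline_sdlog = 1,
                       k = 0.2, b = 1.5,
                       fraction_neg = 0, fraction_pos = 0,
                       effect_size = 4, efficiency_sd = 0, seed = 1L) {
  if (fraction_neg < 0 || fraction_pos < 0 ||
      fraction_neg + fraction_pos > 1)
    stop("sim_config: selected fractions must be in [0, 1] and sum to ",
         "at most 1", call. = FALSE)
  if (effect_size <= 0)
    stop("sim_config: effect_size must be positive", call. = FALSE)
  if (k < 0 || b < 0)
    stop("sim_config: k and b must be non-negative", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 k = k, b = b,
                 fraction_neg = fraction_neg,
                 fraction_pos = fraction_pos,
                 effect_size = effect_size,
                 efficiency_sd = efficiency_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draw with mean mu and variance mu + k*mu^b; Poisson when the law
# gives no overdispersion.
rcounts <- function(n, mu, k, b) {
  v <- mu + k * mu^b
  over <- v > mu & mu > 0
  out <- numeric(n)
  out[!over] <- stats::rpois(sum(!over), mu[!over])
  if (any(over)) {
    size <- mu[over]^2 / (v[over] - mu[over])
    out[over] <- stats::rnbinom(sum(over), size = size, mu = mu[over])
  }
  out
}

#' Simulate a pooled CRISPR knockout screen
#'
#' @param cfg A [sim_config].
#' @return A list with `table` (a [count_table]) and `truth` (a data
#'   frame with columns `gene`, `label` in `{"neg", "pos", "null"}` and
#'   `fold_change`, the ground truth for recovery evaluation).
#' @export
simulate_screen <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, {
    genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    n_neg <- round(cfg$fraction_neg * cfg$n_genes)
    n_pos <- round(cfg$fraction_pos * cfg$n_genes)
    label <- rep("null", cfg$n_genes)
    picked <- sample.int(cfg$n_genes, n_neg + n_pos)
    label[picked[seq_len(n_neg)]] <- "neg"
    label[picked[seq_len(n_pos) + n_neg]] <- "pos"
    fold <- ifelse(label == "neg", 1 / cfg$effect_size,
                   ifelse(label == "pos", cfg$effect_size, 1))

    m <- cfg$n_genes * cfg$sgrnas_per_gene
    gene_of <- rep(genes, each = cfg$sgrnas_per_gene)
    sgrna <- paste0(gene_of, "_sg", seq_len(cfg$sgrnas_per_gene))
    mu0 <- stats::rlnorm(m, cfg$baseline_meanlog, cfg$baseline_sdlog)
    lfc <- rep(log(fold), each = cfg$sgrnas_per_gene)
    if (cfg$efficiency_sd > 0)
      lfc <- lfc * stats::rlnorm(m, 0, cfg$efficiency_sd)
    mu1 <- mu0 * exp(lfc)

    counts <- matrix(0, m, cfg$n_control + cfg$n_treatment)
    for (j in seq_len(cfg$n_control))
      counts[, j] <- rcounts(m, mu0, cfg$k, cfg$b)
    for (j in seq_len(cfg$n_treatment))
      counts[, cfg$n_control + j] <- rcounts(m, mu1, cfg$k, cfg$b)
    samples <- c(sprintf("control_%d", seq_len(cfg$n_control)),
                 sprintf("treatment_%d", seq_len(cfg$n_treatment)))

    list(table = count_table(counts, sgrna, gene_of, samples),
         truth = data.frame(gene = genes, label = label,
                            fold_change = fold,
                            row.names = NULL, stringsAsFactors = FALSE))
  })
}

#' Build a synthetic pathway database over simulated genes
#'
#' Creates one gene set holding all truly selected genes of the given
#' direction ("spiked" pathway) plus null pathways of the same size drawn
#' from the unselected genes, for pathway-level recovery tests.
#'
#' @param truth Truth table from [simulate_screen()].
#' @param direction `"neg"` or `"pos"`: which selected genes form the
#'   spiked set.
#' @param n_pathways Total number of pathways including the spiked one.
#' @param seed Integer RNG seed for the null sets.
#' @return A `pathway_db`; the spiked set is named `"spiked_pathway"`.
#' @export
simulate_pathway_db <- function(truth, direction = c("neg", "pos"),
                                n_pathways = 50L, seed = 1L) {
  direction <- match.arg(direction)
  spiked <- truth$gene[truth$label == direction]
  if (!length(spiked))
    stop("simulate_pathway_db: truth table has no '", direction,
         "' genes", call. = FALSE)
  nulls <- truth$gene[truth$label == "null"]
  size <- length(spiked)
  withr::with_seed(seed, {
    sets <- c(list(spiked_pathway = spiked),
              stats::setNames(
                lapply(seq_len(n_pathways - 1L),
                       function(i) sample(nulls, min(size, length(nulls)))),
                sprintf("null_pathway_%02d", seq_len(n_pathways - 1L))))
  })
  structure(list(pathways = sets,
                 descriptions = stats::setNames(
                   rep("synthetic", length(sets)), names(sets))),
            class = "pathway_db")
}

#' Fraction of true hits recovered in the top of a gene ranking
#'
#' @param gene_results A ranked `gene_results` data frame.
#' @param truth Truth table from [simulate_screen()].
#' @param top_k Ranking depth to search.
#' @param direction Which truth label counts as a hit (defaults to the
#'   direction the gene test was run in).
#' @return Fraction (0..1) of truly selected genes ranked within
#'   `top_k`.
#' @export
evaluate_recovery <- function(gene_results, truth, top_k,
                              direction = attr(gene_results, "direction")) {
  hits <- truth$gene[truth$label == direction]
  if (!length(hits)) return(NA_real_)
  top <- gene_results$gene[gene_results$rank <= top_k]
  mean(hits %in% top)
}
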