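#' Merge the two directional gene (or pathway) tests into one summary
#'
#' Produces the wide per-gene summary table written by [run_screen()]:
#' one row per gene with the negative- and positive-selection statistics
#' side by side, ordered by the negative-selection rank.
#'
#' @param neg,pos `gene_results` (or `pathway_results`) data frames for
#'   the two directions, over the same genes.
#' @return A data frame with columns `gene` (or `pathway`), `n`,
#'   `j_neg`, `j_pos`, `rho_neg`, `rho_pos`, `p_neg`, `p_pos`,
#'   `fdr_neg`, `fdr_pos`, `rank_neg`, `rank_pos`.
#' @export
summarize_screen <- function(neg, pos) {
  key <- intersect(c("gene", "pathway"), colnames(neg))[1]
  stopifnot(setequal(neg[[key]], pos[[key]]))
  pos <- pos[match(neg[[key]], pos[[key]]), , drop = FALSE]
  out <- data.frame(neg[[key]], neg$n, neg$j, pos$j, neg$rho, pos$rho,
                    neg$perm_p, pos$perm_p, neg$fdr, pos$fdr,
                    neg$rank, pos$rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  colnames(out) <- c(key, "n", "j_neg", "j_pos", "rho_neg", "rho_pos",
                     "p_neg", "p_pos", "fdr_neg", "fdr_pos",
                     "rank_neg", "rank_pos")
  out[order(out$rank_neg), , drop = FALSE]
}

#' Run the full screen analysis end to end
#'
#' Wires the pipeline together: median-ratio (or total-count)
#' normalization, mean-variance model fit on the control replicates
#' (pooling all samples when the controls are unreplicated), the
#' per-sgRNA negative binomial test, gene-level alpha-RRA in one or both
#' directions, and optionally pathway-level alpha-RRA.  Writes
#' `sgrna_summary.txt`, `gene_summary.txt`, a `model.txt` sidecar with
#' the fitted (k, b), optionally `pathway_summary.txt`, and a
#' `run_log.txt` recording size factors, model parameters, good-sgRNA
#' counts and the seed, so every run is reproducible from its log.
#'
#' @param table A [count_table] of raw counts, or a path to a count
#'   file.
#' @param design A [design_spec].
#' @param cfg An [alpha_config] (carries p-threshold, permutations,
#'   seed).
#' @param gmt Optional path to a GMT file, or a `pathway_db`, enabling
#'   the pathway test.
#' @param norm_method `"median"` (median-ratio) or `"total"`
#'   (total-count).
#' @param direction `"both"`, `"neg"` or `"pos"`.
#' @param output_dir Directory for the output files; `NULL` suppresses
#'   writing and just returns the results.
#' @return Invisibly, a list with elements `sgrna`, `gene_neg`,
#'   `gene_pos`, `gene_summary`, `pathway_summary` (when `gmt` given),
#'   `size_factors` and `model` (entries `NULL` when not computed).
#' @export
run_screen <- function(table, design, cfg = alpha_config(), gmt = NULL,
                       norm_method = c("median", "total"),
                       direction = c("both", "neg", "pos"),
                       output_dir = NULL) {
  norm_method <- match.arg(norm_method)
  direction <- match.arg(direction)
  if (is.character(table)) table <- read_count_table(table)
  if (is.character(gmt)) gmt <- read_gmt(gmt)

  sf <- NULL
  norm <- if (norm_method == "median") {
    sf <- compute_size_factors(table)
    normalize_counts(table, sf)
  } else {
    total_count_normalize(table)
  }

  model_samples <- if (length(design$control) >= 2) design$control
                   else c(design$control, design$treatment)
  model <- tryCatch(
    fit_mean_variance(sample_moments(norm, model_samples)),
    error = function(e) {
      warning("mean-variance fit failed (", conditionMessage(e),
              "); using Poisson model", call. = FALSE)
      poisson_model()
    })

  sg <- sgrna_test(norm, design, model)
  gene_neg <- gene_pos <- NULL
  if (direction %in% c("both", "neg"))
    gene_neg <- gene_test(sg, cfg, "neg")
  if (direction %in% c("both", "pos"))
    gene_pos <- gene_test(sg, cfg, "pos")
  gene_summary <- if (!is.null(gene_neg) && !is.null(gene_pos))
    summarize_screen(gene_neg, gene_pos) else NULL

  pathway_summary <- path_neg <- path_pos <- NULL
  if (!is.null(gmt)) {
    if (!is.null(gene_neg)) path_neg <- pathway_test(gene_neg, gmt, cfg)
    if (!is.null(gene_pos)) path_pos <- pathway_test(gene_pos, gmt, cfg)
    pathway_summary <- if (!is.null(path_neg) && !is.null(path_pos))
      summarize_screen(path_neg, path_pos) else NULL
  }

  res <- list(sgrna = sg, gene_neg = gene_neg, gene_pos = gene_pos,
              gene_summary = gene_summary,
              pathway_neg = path_neg, pathway_pos = path_pos,
              pathway_summary = pathway_summary,
              size_factors = sf, model = model)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(output_dir, f)
    write_results(sg[, setdiff(colnames(sg), "all_zero")],
                  out("sgrna_summary.txt"))
    single <- gene_neg %||% gene_pos
    write_results(gene_summary %||% single, out("gene_summary.txt"))
    if (!is.null(pathway_summary %||% path_neg %||% path_pos))
      write_results(pathway_summary %||% path_neg %||% path_pos,
                    out("pathway_summary.txt"))
    utils::write.table(
      data.frame(k = model$k, b = model$b, n_points = model$n_points,
                 r2 = model$r2),
      out("model.txt"), sep = "\t", quote = FALSE, row.names = FALSE)
    n_good <- function(g) if (is.null(g)) NA else sum(g$j > 0)
    log_lines <- c(
      paste0("samples: ", paste(table$sample_names, collapse = ", ")),
      paste0("design: control={",
             paste(design$control, collapse = ","), "} treatment={",
             paste(design$treatment, collapse = ","), "}"),
      paste0("norm_method: ", norm_method),
      if (!is.null(sf))
        paste0("size_factors: ",
               paste(sprintf("%s=%.6g", names(sf$factors), sf$factors),
                     collapse = ", ")),
      sprintf("model: k=%.6g b=%.6g n_points=%d", model$k, model$b,
              model$n_points),
      sprintf("p_threshold: %g", cfg$p_threshold),
      sprintf("genes_with_good_sgrnas: neg=%s pos=%s",
              n_good(gene_neg), n_good(gene_pos)),
      sprintf("seed: %d", cfg$seed))
    writeLines(log_lines, out("run_log.txt"))
  }
  invisible(res)
}

#' Run only the pathway-level test
#'
#' Convenience wrapper for re-running the pathway aggregation on an
#' existing gene ranking (for example with a different gene-set
#' database) without repeating the sgRNA and gene tests.
#'
#' @param gene_results A ranked `gene_results` data frame.
#' @param gmt Path to a GMT file or a `pathway_db`.
#' @param cfg An [alpha_config].
#' @param output_path Optional file to write the pathway summary to.
#' @return The `pathway_results` data frame, invisibly when written.
#' @export
run_pathway <- function(gene_results, gmt, cfg = alpha_config(),
                        output_path = NULL) {
  if (is.character(gmt)) gmt <- read_gmt(gmt)
  res <- pathway_test(gene_results, gmt, cfg)
  if (!is.null(output_path)) {
    write_results(res, output_path)
    return(invisible(res))
  }
  res
}
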