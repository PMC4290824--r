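#' Construct and validate an sgRNA read-count table
#'
#' A `count_table` holds the raw (or normalized) read counts of a pooled
#' CRISPR/Cas9 knockout screen: one row per sgRNA, one column per sample,
#' together with the sgRNA-to-gene mapping.  All downstream steps
#' (normalization, the negative binomial sgRNA test, and rank aggregation)
#' consume this container.
#'
#' @param counts Non-negative integer matrix, rows = sgRNAs, columns =
#'   samples.
#' @param sgrna_ids Character vector of unique sgRNA identifiers, one per
#'   row of `counts`.
#' @param gene_ids Character vector giving the gene targeted by each sgRNA
#'   (same length as `sgrna_ids`).
#' @param sample_names Character vector of unique sample labels, one per
#'   column of `counts`.
#'
#' @return An object of class `count_table`: a list with elements `counts`
#'   (dimnamed integer matrix), `sgrna_ids`, `gene_ids`, `sample_names`,
#'   and `all_zero` (logical flag marking sgRNAs with zero counts in every
#'   sample; these are retained but handled specially downstream).
#' @export
count_table <- function(counts, sgrna_ids, gene_ids, sample_names) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != length(sgrna_ids))
    stop("count table: ", length(sgrna_ids), " sgRNA ids for ",
         nrow(counts), " count rows", call. = FALSE)
  if (length(gene_ids) != length(sgrna_ids))
    stop("count table: gene_ids must have one entry per sgRNA", call. = FALSE)
  if (ncol(counts) != length(sample_names))
    stop("count table: ", length(sample_names), " sample names for ",
         ncol(counts), " count columns", call. = FALSE)
  if (ncol(counts) < 1)
    stop("count table: at least one sample column is required", call. = FALSE)
  dup <- sgrna_ids[duplicated(sgrna_ids)]
  if (length(dup))
    stop("count table: duplicated sgRNA id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- sample_names[duplicated(sample_names)]
  if (length(dup))
    stop("count table: duplicated sample name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("count table: negative or non-numeric count at row ", bad[1, 1],
         " (", sgrna_ids[bad[1, 1]], "), column ", bad[1, 2],
         " (", sample_names[bad[1, 2]], ")", call. = FALSE)
  bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("count table: non-integer count at row ", bad[1, 1],
         " (", sgrna_ids[bad[1, 1]], "), column ", bad[1, 2],
         " (", sample_names[bad[1, 2]], ")", call. = FALSE)
  counts <- round(counts)
  dimnames(counts) <- list(sgrna_ids, sample_names)
  structure(
    list(counts = counts,
         sgrna_ids = as.character(sgrna_ids),
         gene_ids = as.character(gene_ids),
         sample_names = as.character(sample_names),
         all_zero = rowSums(counts) == 0),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "sgRNAs,",
      length(unique(x$gene_ids)), "genes,",
      ncol(x$counts), "samples\n")
  cat("samples:", paste(x$sample_names, collapse = ", "), "\n")
  if (any(x$all_zero))
    cat(sum(x$all_zero), "sgRNA(s) with zero counts in all samples\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read an sgRNA count table from a tab-delimited file
#'
#' Expects the conventional screen count layout: a mandatory header line,
#' first column sgRNA id, second column gene id, remaining columns integer
#' read counts (one per sample).
#'
#' @param path Path to a tab-delimited count file.
#' @return A validated [count_table].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path))
    stop("count file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 3)
    stop("count file ", path, ": needs sgRNA, gene and at least one ",
         "sample column", call. = FALSE)
  samples <- colnames(df)[-(1:2)]
  counts <- suppressWarnings(
    vapply(df[-(1:2)], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) counts <- matrix(counts, nrow = 1L)
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    stop("count file ", path, ": non-numeric count at data row ",
         bad[1, 1], ", column '", samples[bad[1, 2]], "'", call. = FALSE)
  }
  count_table(counts, df[[1]], df[[2]], samples)
}

#' Write a count table to a tab-delimited file
#'
#' Inverse of [read_count_table()]; `read_count_table(write_count_table(x))`
#' reproduces `x` field for field.
#'
#' @param table A [count_table].
#' @param path Output file path.
#' @param id_columns Header names used for the two identifier columns.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, id_columns = c("sgRNA", "gene")) {
  df <- data.frame(table$sgrna_ids, table$gene_ids,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_columns, table$sample_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Specify the control/treatment design of a screen comparison
#'
#' @param control Character vector of control (condition A) sample names.
#' @param treatment Character vector of treatment (condition B) sample
#'   names.
#' @param table Optional [count_table]; when given, membership of all
#'   samples is checked.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(control, treatment, table = NULL) {
  control <- as.character(control)
  treatment <- as.character(treatment)
  if (!length(control) || !length(treatment))
    stop("design: control and treatment must each name at least one sample",
         call. = FALSE)
  overlap <- intersect(control, treatment)
  if (length(overlap))
    stop("design: sample(s) in both conditions: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  if (!is.null(table)) {
    missing <- setdiff(c(control, treatment), table$sample_names)
    if (length(missing))
      stop("design: sample(s) not in count table: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(control = control, treatment = treatment),
            class = "design_spec")
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format used by MSigDB (and by
#' KEGG / REACTOME exports): each line holds a set name, a description, and
#' one or more member gene symbols.
#'
#' @param path Path to a GMT file.
#' @param case_fold If `TRUE`, gene symbols are upper-cased on input so
#'   that later matching against screen gene ids is case-insensitive.
#'   Defaults to `FALSE`: silent case-folding can mask annotation
#'   mismatches, so it is opt-in.
#' @return An object of class `pathway_db`: a list with `pathways` (named
#'   list of unique gene-symbol character vectors) and `descriptions`.
#' @export
read_gmt <- function(path, case_fold = FALSE) {
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT file ", path, ": line ", which(nf < 3)[1],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop("GMT file ", path, ": duplicated pathway name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  genes <- lapply(fields, function(f) {
    g <- unique(f[-(1:2)])
    if (case_fold) g <- unique(toupper(g))
    g
  })
  names(genes) <- names_
  desc <- vapply(fields, `[[`, character(1), 2L)
  names(desc) <- names_
  structure(list(pathways = genes, descriptions = desc),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("pathway_db:", length(x$pathways), "gene sets, median size",
      stats::median(lengths(x$pathways)), "\n")
  invisible(x)
}

#' Write a result table to a tab-delimited file
#'
#' Serializes sgRNA-, gene- or pathway-level result data frames with a
#' deterministic column order, rows ordered by rank, and floats printed
#' with enough significant digits to round-trip.
#'
#' @param results A data frame as returned by [sgrna_test()],
#'   [gene_test()], [pathway_test()] or [summarize_screen()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  rank_col <- intersect(c("rank", "rank_neg"), colnames(df))
  if (length(rank_col) && nrow(df))
    df <- df[order(df[[rank_col[1]]]), , drop = FALSE]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.8g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
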