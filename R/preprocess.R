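#' Filter lowly expressed exons and single-exon genes
#'
#' Removes exons whose overall average count across all samples is not above
#' \code{min_avg}, then drops genes left with fewer than \code{min_exons}
#' exons. Genes that had a single exon before any filtering are removed
#' outright: for them the exon-based and gene-based strategies coincide, so
#' they carry no information about the comparison. The inequality on the
#' average is strict (a mean of exactly \code{min_avg} is removed).
#'
#' @param table an \code{\link{exon_count_table}}.
#' @param min_avg minimum overall mean count an exon must exceed (default 1).
#' @param min_exons minimum number of surviving exons a gene needs to be
#'   retained (default 2).
#' @return The filtered \code{ExonCountTable}. A summary of removals is
#'   attached as attribute \code{"filter_report"} and reported via
#'   \code{message()}. An empty result triggers a warning, not an error.
#' @export
filter_exons <- function(table, min_avg = 1, min_exons = 2) {
  single <- names(which(base::table(factor(table$gene_id)) == 1L))
  keep_gene <- !(table$gene_id %in% single)
  expressed <- rowMeans(table$counts) > min_avg
  keep <- keep_gene & expressed
  n_per_gene <- base::table(factor(table$gene_id)[keep])
  ok_genes <- names(n_per_gene)[n_per_gene >= min_exons]
  keep <- keep & table$gene_id %in% ok_genes
  report <- c(exons_low = sum(!expressed & keep_gene),
              single_exon_genes = length(single),
              genes_too_few_exons =
                length(setdiff(unique(table$gene_id[keep_gene]), ok_genes)),
              exons_kept = sum(keep))
  message(sprintf(
    "filter_exons: kept %d exons; removed %d low-count exons, %d single-exon genes, %d genes with < %d surviving exons",
    report["exons_kept"], report["exons_low"], report["single_exon_genes"],
    report["genes_too_few_exons"], min_exons))
  if (!any(keep)) {
    warning("filtering removed all exons")
    out <- table
    out$counts <- table$counts[0, , drop = FALSE]
    out$gene_id <- character(0)
    class(out) <- "ExonCountTable"
  } else {
    out <- subset_exons(table, keep)
  }
  attr(out, "filter_report") <- report
  out
}

#' Sum exon counts to gene level
#'
#' Produces the input of the conventional gene-based strategy: one row per
#' gene holding, for each sample, the total read count over the gene's
#' exons. The result is returned as an \code{ExonCountTable} whose "exons"
#' are the genes themselves, so the identical testing code path applies to
#' both strategies.
#'
#' @param table an \code{\link{exon_count_table}}.
#' @return An \code{ExonCountTable} with one row per gene
#'   (\code{exon_id == gene_id}). Empty input yields an empty table.
#' @export
sum_gene_counts <- function(table) {
  if (nrow(table$counts) == 0L) {
    out <- table
    return(out)
  }
  g <- factor(table$gene_id, levels = unique(table$gene_id))
  summed <- rowsum(table$counts, group = g, reorder = FALSE)
  exon_count_table(summed, gene_id = rownames(summed), samples = table$samples)
}

#' Library sizes and TMM scaling factors
#'
#' Computes the trimmed-mean-of-M-values scaling factor for each sample
#' (30\% trim on log-ratios, 5\% on average log-abundance, precision
#' weights, reference chosen by upper-quartile proximity to the mean) via
#' \code{edgeR::calcNormFactors}, the canonical implementation. Factors are
#' rescaled to geometric mean 1; sequencing depth itself is absorbed by the
#' library size, not the factor.
#'
#' @param counts count matrix (features x samples) or an
#'   \code{ExonCountTable}.
#' @return A list of class \code{"NormalizationState"} with per-sample
#'   \code{library_size}, \code{tmm_factor} and \code{effective_library_size
#'   = library_size * tmm_factor}.
#' @export
tmm_factors <- function(counts) {
  if (inherits(counts, "ExonCountTable")) counts <- counts$counts
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM", lib.size = lib)
  structure(list(library_size = lib, tmm_factor = f,
                 effective_library_size = lib * f),
            class = "NormalizationState")
}

#' Log2 counts per million with a prior count
#'
#' \code{log2((count + prior) / (effective_library_size + 2 * prior) * 1e6)}.
#' The prior count keeps zeros finite and shrinks low-count fold changes.
#'
#' @param counts count matrix or \code{ExonCountTable}.
#' @param norm a \code{NormalizationState} from \code{\link{tmm_factors}};
#'   computed from \code{counts} when \code{NULL}.
#' @param prior prior count added to every observation (default 0.5).
#' @return Numeric matrix of the same shape as the counts.
#' @export
log_cpm <- function(counts, norm = NULL, prior = 0.5) {
  if (inherits(counts, "ExonCountTable")) counts <- counts$counts
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$effective_library_size
  if (any(eff <= 0)) stop("effective library sizes must be positive")
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}
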