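#' Read per-sample exon count files in the DEXSeq-counting dialect
#'
#' Each file holds one sample as TAB-separated lines
#' \code{"geneID:exonBin<TAB>count"}. Trailing meta-feature rows whose name
#' starts with an underscore (ambiguous, no-feature and similar tallies) are
#' dropped; the number dropped is reported via \code{message()}. All files
#' must share an identical exon universe.
#'
#' @param sample_sheet data frame with columns \code{sample_id},
#'   \code{group} and \code{file_path}.
#' @return An \code{\link{exon_count_table}} with \code{gene_id} parsed from
#'   the part of each feature id before the first colon.
#' @export
read_dexseq_counts <- function(sample_sheet) {
  stopifnot(is.data.frame(sample_sheet),
            all(c("sample_id", "group", "file_path") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (nrow(sample_sheet) == 0L) stop("empty sample sheet")

  read_one <- function(path) {
    d <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
    if (ncol(d) != 2L)
      stop("file ", path, ": expected two TAB-separated columns")
    meta <- startsWith(d[[1]], "_")
    if (any(meta))
      message(sum(meta), " meta-feature row(s) dropped from ", basename(path))
    d <- d[!meta, , drop = FALSE]
    cnt <- suppressWarnings(as.numeric(d[[2]]))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
    if (length(bad))
      stop("file ", path, ", line ", which(!meta)[bad[1]],
           ": count must be a non-negative integer, got '", d[[2]][bad[1]], "'")
    stats::setNames(cnt, d[[1]])
  }

  first <- read_one(sample_sheet$file_path[1])
  universe <- names(first)
  mat <- matrix(0, nrow = length(universe), ncol = nrow(sample_sheet),
                dimnames = list(universe, sample_sheet$sample_id))
  mat[, 1] <- first
  if (nrow(sample_sheet) > 1L) {
    for (j in 2:nrow(sample_sheet)) {
      v <- read_one(sample_sheet$file_path[j])
      if (!setequal(names(v), universe))
        stop("exon universe mismatch: file ", sample_sheet$file_path[j],
             " does not contain the same exons as ", sample_sheet$file_path[1])
      mat[, j] <- v[universe]
    }
  }
  gene_id <- sub(":.*$", "", universe)
  exon_count_table(mat, gene_id,
                   samples = data.frame(sample_id = sample_sheet$sample_id,
                                        group = sample_sheet$group,
                                        stringsAsFactors = FALSE))
}

#' Read an exon count matrix from a TSV file
#'
#' Expects header columns \code{gene_id}, \code{exon_id}, then one column
#' per sample. Group labels can be attached from a sample sheet; otherwise
#' they are left \code{NA} and must be set before testing.
#'
#' @param path path to a TAB-separated file.
#' @param sample_sheet optional data frame with columns \code{sample_id} and
#'   \code{group} covering all sample columns of the matrix.
#' @return An \code{\link{exon_count_table}}.
#' @export
read_count_matrix <- function(path, sample_sheet = NULL) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE, quote = "")
  if (!all(c("gene_id", "exon_id") %in% names(d)))
    stop("header must contain 'gene_id' and 'exon_id'")
  if (nrow(d) == 0L) stop("no exons: data section of ", path, " is empty")
  sample_cols <- setdiff(names(d), c("gene_id", "exon_id"))
  if (length(sample_cols) == 0L) stop("no sample columns in ", path)
  if (anyDuplicated(d$exon_id))
    stop("duplicate exon_id in ", path, ": ",
         paste(unique(d$exon_id[duplicated(d$exon_id)]), collapse = ", "))
  mat <- as.matrix(d[, sample_cols, drop = FALSE])
  rownames(mat) <- d$exon_id
  grp <- rep(NA_character_, length(sample_cols))
  if (!is.null(sample_sheet)) {
    idx <- match(sample_cols, sample_sheet$sample_id)
    if (any(is.na(idx)))
      stop("sample sheet is missing samples: ",
           paste(sample_cols[is.na(idx)], collapse = ", "))
    grp <- as.character(sample_sheet$group[idx])
  }
  exon_count_table(mat, as.character(d$gene_id),
                   samples = data.frame(sample_id = sample_cols, group = grp,
                                        stringsAsFactors = FALSE))
}

#' Write an exon count table as a TSV matrix
#'
#' Inverse of \code{\link{read_count_matrix}}: columns \code{gene_id},
#' \code{exon_id}, then the samples.
#'
#' @param x an \code{ExonCountTable}.
#' @param path output path.
#' @export
write_count_matrix <- function(x, path) {
  d <- data.frame(gene_id = x$gene_id, exon_id = rownames(x$counts),
                  x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-exon test results produced by an external method
#'
#' The aggregation step is test-agnostic: any method that yields a per-exon
#' log2 fold change and two-sided p-value can feed it. The file must have
#' header columns \code{exon_id}, \code{log2fc} and \code{pvalue}, and may
#' carry an optional \code{gene_id} column; without one, gene assignments
#' are resolved against \code{table}.
#'
#' @param path path to a TAB-separated results file.
#' @param table optional \code{ExonCountTable} used to resolve gene ids.
#' @return A data frame with columns \code{exon_id}, \code{gene_id}
#'   (possibly \code{NA} when unresolvable), \code{x} (log2 fold change) and
#'   \code{p}. A p-value of exactly 0 is accepted here and clamped later by
#'   \code{\link{signed_log_p}}; its presence is reported via
#'   \code{message()}.
#' @export
read_external_exon_results <- function(path, table = NULL) {
  d <- utils::read.delim(path, header = TRUE, quote = "")
  if (!all(c("exon_id", "log2fc", "pvalue") %in% names(d)))
    stop("header must contain 'exon_id', 'log2fc' and 'pvalue'")
  if (anyDuplicated(d$exon_id)) stop("duplicate exon_id in ", path)
  if (any(is.na(d$pvalue) | d$pvalue < 0 | d$pvalue > 1))
    stop("p-values must lie in [0, 1]")
  if (any(d$pvalue == 0))
    message(sum(d$pvalue == 0), " p-value(s) equal to 0 in ", basename(path),
            "; they will be clamped before log transformation")
  gene <- if ("gene_id" %in% names(d)) as.character(d$gene_id)
          else rep(NA_character_, nrow(d))
  if (!is.null(table)) {
    idx <- match(d$exon_id, rownames(table$counts))
    gene[!is.na(idx)] <- table$gene_id[idx[!is.na(idx)]]
  }
  if (all(is.na(gene))) {
    # fall back on the geneID:exonBin convention
    colon <- grepl(":", d$exon_id)
    gene[colon] <- sub(":.*$", "", d$exon_id[colon])
  }
  data.frame(exon_id = as.character(d$exon_id), gene_id = gene,
             x = as.numeric(d$log2fc), p = as.numeric(d$pvalue),
             stringsAsFactors = FALSE)
}

#' Write ranked gene-level results to a TSV file
#'
#' Rows are sorted ascending by \code{final_score}, ties broken by
#' lexicographic \code{gene_id}, so that re-running an identical
#' configuration yields a byte-identical file.
#'
#' @param scores a gene score data frame from \code{\link{score_genes}} (or
#'   the gene-based analogue from \code{\link{run_gene_strategy}}).
#' @param path output path.
#' @export
write_gene_results <- function(scores, path) {
  cols <- c("gene_id", "n_exons", "median_log2fc", "score_m", "median_p",
            "null_p", "fdr", "final_score", "called")
  out <- as.data.frame(scores)
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  out <- out[, cols]
  ord <- order(out$final_score, out$gene_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach exon coordinates from a flattened GFF annotation
#'
#' Optionally decorates result tables with 1-based inclusive genomic
#' coordinates taken from a flattened exonic-part annotation (the GFF
#' produced by flattening a gene model for exon counting). Features of type
#' \code{exonic_part} are matched to exon ids via their
#' \code{gene_id}/\code{exonic_part_number} attributes joined as
#' \code{"gene:part"}. Coordinates never alter counts or statistics.
#'
#' @param results data frame with an \code{exon_id} column.
#' @param gff_path path to the flattened GFF file.
#' @return \code{results} with added columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{NA} for unmatched exons).
#' @export
attach_exon_coordinates <- function(results, gff_path) {
  g <- utils::read.delim(gff_path, header = FALSE, comment.char = "#",
                         quote = "", stringsAsFactors = FALSE)
  if (ncol(g) < 9L) stop("not a GFF file: ", gff_path)
  g <- g[g[[3]] == "exonic_part", , drop = FALSE]
  attr_field <- function(s, key) {
    hit <- regexpr(paste0(key, "[ =]+\"?[^\";]+"), s)
    out <- rep(NA_character_, length(s))
    out[hit > 0] <- gsub(paste0("^", key, "[ =]+\"?"), "",
                         regmatches(s, hit))
    out
  }
  gene <- attr_field(g[[9]], "gene_id")
  part <- attr_field(g[[9]], "exonic_part_number")
  key <- paste0(gene, ":", part)
  idx <- match(results$exon_id, key)
  results$chrom <- g[[1]][idx]
  results$start <- as.integer(g[[4]][idx])
  results$end <- as.integer(g[[5]][idx])
  results$strand <- g[[7]][idx]
  results
}
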