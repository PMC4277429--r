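#' Construct an exon count table
#'
#' The central container of the package: a matrix of non-negative integer
#' read counts with one row per exon bin and one column per sample, a gene
#' assignment for every exon, and per-sample group labels. Exon identifiers
#' follow the flattened-annotation counting convention
#' (\code{"geneID:exonBin"}), but any unique string is accepted as long as a
#' gene assignment is supplied.
#'
#' @param counts numeric matrix of non-negative integers, exons x samples.
#'   Row names are taken as exon identifiers; column names as sample
#'   identifiers.
#' @param gene_id character vector, one gene identifier per row of
#'   \code{counts}.
#' @param samples data frame with columns \code{sample_id} and \code{group},
#'   one row per column of \code{counts}. \code{group} may be \code{NA} when
#'   the table is not yet attached to a two-group design.
#'
#' @return An object of class \code{"ExonCountTable"}: a list with elements
#'   \code{counts}, \code{gene_id} and \code{samples}.
#' @export
#' @examples
#' cts <- matrix(c(5L, 7L, 3L, 4L), 2, 2,
#'               dimnames = list(c("G1:E001", "G1:E002"), c("s1", "s2")))
#' tab <- exon_count_table(cts, gene_id = c("G1", "G1"),
#'                         samples = data.frame(sample_id = c("s1", "s2"),
#'                                              group = c("A", "B")))
#' n_exons(tab)
exon_count_table <- function(counts, gene_id, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("'counts' must have exon ids as row names")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  storage.mode(counts) <- "double"
  obj <- structure(
    list(counts = counts,
         gene_id = as.character(gene_id),
         samples = as.data.frame(samples)),
    class = "ExonCountTable")
  validate_exon_count_table(obj)
}

validate_exon_count_table <- function(x) {
  counts <- x$counts
  if (nrow(counts) == 0L) stop("no exons: count table is empty")
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate exon_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (length(x$gene_id) != nrow(counts))
    stop("gene_id must have one entry per exon")
  s <- x$samples
  if (!all(c("sample_id", "group") %in% names(s)))
    stop("samples must have columns 'sample_id' and 'group'")
  if (nrow(s) != ncol(counts))
    stop("samples must have one row per count column")
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in samples")
  if (!identical(as.character(s$sample_id), colnames(counts)))
    stop("samples$sample_id must match count column names in order")
  x
}

#' @rdname exon_count_table
#' @param x an \code{ExonCountTable}.
#' @export
n_exons <- function(x) nrow(x$counts)

#' @rdname exon_count_table
#' @export
n_genes <- function(x) length(unique(x$gene_id))

#' @export
print.ExonCountTable <- function(x, ...) {
  cat(sprintf("ExonCountTable: %d exons, %d genes, %d samples\n",
              n_exons(x), n_genes(x), ncol(x$counts)))
  grp <- x$samples$group
  if (!all(is.na(grp)))
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(grp)), table(grp)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExonCountTable <- function(x) dim(x$counts)

#' Subset an exon count table by exon
#'
#' @param x an \code{ExonCountTable}.
#' @param i logical or integer index over exons (rows).
#' @return An \code{ExonCountTable} restricted to the selected exons.
#' @keywords internal
#' @export
subset_exons <- function(x, i) {
  exon_count_table(x$counts[i, , drop = FALSE], x$gene_id[i], x$samples)
}

#' Two-group factor from the sample sheet of a table
#'
#' Returns the group labels as a two-level factor (levels in order of first
#' appearance), erroring when the design is not a two-group comparison.
#'
#' @param x an \code{ExonCountTable}.
#' @return A factor of length \code{ncol(x$counts)} with exactly two levels.
#' @export
table_groups <- function(x) {
  grp <- as.character(x$samples$group)
  if (any(is.na(grp))) stop("every sample must have a group label")
  lev <- unique(grp)
  if (length(lev) != 2L)
    stop("exactly two groups are required for testing, found: ",
         paste(lev, collapse = ", "))
  factor(grp, levels = lev)
}
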