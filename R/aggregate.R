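#' Signed log-transformed p-value of one exon
#'
#' \code{s = sgn(x) * (-ln p)}: the building block of the gene score. The
#' log transformation sends the least significant p-value (p = 1) to zero,
#' so uninformative exons contribute nothing. P-values are clamped to
#' \code{[1e-300, 1]} before the log; a zero fold change contributes a zero
#' score (\code{sgn(0) = 0}).
#'
#' @param p p-value(s) in [0, 1].
#' @param x log2 fold change(s), same length.
#' @return Signed log-p score(s).
#' @export
#' @examples
#' signed_log_p(exp(-3), -1)  # -3
#' signed_log_p(1, 2.3)       # 0
signed_log_p <- function(p, x) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  n_clamped <- sum(p < 1e-300, na.rm = TRUE)
  if (n_clamped > 0)
    message(n_clamped, " p-value(s) clamped to 1e-300 before log transform")
  p <- pmin(pmax(p, 1e-300), 1)
  sign(x) * (-log(p))
}

#' Gene-level median of signed log-p scores
#'
#' The gene score m: the median over the per-exon signed log-p values (for
#' even n, the mean of the two central order statistics). Any other mean
#' descriptor can replace the median; the arithmetic mean is built in.
#'
#' @param s signed log-p scores of one gene's exons (length >= 2; single
#'   exon genes are removed upstream).
#' @param aggregator \code{"median"} (default) or \code{"mean"}.
#' @return The aggregated score m.
#' @export
gene_median_score <- function(s, aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  if (length(s) < 2L)
    stop("gene score needs >= 2 exons (single-exon genes are filtered out)")
  if (aggregator == "median") stats::median(s) else mean(s)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (\code{stats::p.adjust}, method "BH"):
#' monotone, capped at 1.
#'
#' @param pvals p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Score genes from per-exon test results
#'
#' The exon-based strategy's aggregation step. Per gene with n tested
#' exons: the signed log-p scores are aggregated to m; the magnitude is
#' back-transformed to a p-value scale as \code{median_p = exp(-|m|)}; the
#' gene fold change is the median of the exon fold changes; \code{null_p}
#' is the tail probability of |m| under the uniform-p symmetric-sign null
#' for n exons; \code{fdr} is the Benjamini-Hochberg adjustment of the
#' null p-values across genes; and \code{final_score = max(median_p, fdr)}
#' (the max rule) is used to rank, ensuring the median p-value is below
#' the FDR level whenever a gene is ranked as significant.
#'
#' @param exon_results data frame with columns \code{gene_id}, \code{x}
#'   (log2 fold change) and \code{p} (as produced by
#'   \code{\link{test_features}} or \code{\link{read_external_exon_results}}).
#'   Every gene must have at least two exons.
#' @param aggregator passed to \code{\link{gene_median_score}}.
#' @param mc_reps,mc_seed even-n null table parameters (see
#'   \code{\link{null_tail}}).
#' @return A data frame of class \code{"gene_scores"}, one row per gene,
#'   ranked ascending by \code{final_score} (ties by \code{gene_id}):
#'   columns \code{gene_id}, \code{n_exons}, \code{median_log2fc},
#'   \code{score_m}, \code{median_p}, \code{raw_median_p} (plain median of
#'   the exon p-values, a diagnostic), \code{null_p}, \code{fdr},
#'   \code{final_score}, \code{called} (initialized \code{FALSE}; see
#'   \code{\link{call_genes}}).
#' @export
score_genes <- function(exon_results, aggregator = "median",
                        mc_reps = 2e6, mc_seed = 285713L) {
  stopifnot(all(c("gene_id", "x", "p") %in% names(exon_results)))
  if (any(is.na(exon_results$gene_id)))
    stop("every exon must resolve to a gene")
  g <- factor(exon_results$gene_id, levels = unique(exon_results$gene_id))
  n_ex <- as.integer(base::table(g)[levels(g)])
  if (any(n_ex < 2L))
    stop("gene(s) with a single tested exon: ",
         paste(utils::head(levels(g)[n_ex < 2L], 5), collapse = ", "),
         " (filter them out before scoring)")
  s <- signed_log_p(exon_results$p, exon_results$x)
  m <- as.numeric(tapply(s, g, gene_median_score, aggregator = aggregator))
  median_fc <- as.numeric(tapply(exon_results$x, g, stats::median))
  raw_median_p <- as.numeric(tapply(exon_results$p, g, stats::median))
  null_p <- numeric(length(m))
  for (nn in unique(n_ex)) {
    idx <- n_ex == nn
    null_p[idx] <- null_tail(nn, abs(m[idx]), mc_reps = mc_reps,
                             mc_seed = mc_seed)
  }
  out <- data.frame(gene_id = levels(g), n_exons = n_ex,
                    median_log2fc = median_fc, score_m = m,
                    median_p = exp(-abs(m)), raw_median_p = raw_median_p,
                    null_p = null_p, fdr = bh_adjust(null_p),
                    stringsAsFactors = FALSE)
  out$final_score <- pmax(out$median_p, out$fdr)
  out$called <- FALSE
  out <- out[order(out$final_score, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' The calling criteria: FDR below \code{fdr_max}, absolute fold change of
#' at least \code{min_abs_fc} (on the linear scale, i.e.
#' \code{|median_log2fc| >= log2(min_abs_fc)}), at least \code{min_exons}
#' exons, and — for the exon-based strategy — a median p-value below
#' \code{median_p_max}. Gene-based result tables (which carry no median
#' p-value) skip that criterion.
#'
#' @param scores a \code{gene_scores} data frame (or the gene-based
#'   analogue with columns \code{fdr}, \code{median_log2fc},
#'   \code{n_exons}).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_abs_fc minimum absolute linear fold change (default 1.5).
#' @param min_exons minimum number of exons (default 5).
#' @param median_p_max median p-value threshold for the exon-based
#'   strategy (default 0.05).
#' @return \code{scores} with the \code{called} column set.
#' @export
call_genes <- function(scores, fdr_max = 0.05, min_abs_fc = 1.5,
                       min_exons = 5, median_p_max = 0.05) {
  called <- scores$fdr < fdr_max &
    abs(scores$median_log2fc) >= log2(min_abs_fc) &
    scores$n_exons >= min_exons
  if ("median_p" %in% names(scores) && !all(is.na(scores$median_p)))
    called <- called & scores$median_p < median_p_max
  scores$called <- called
  scores
}
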