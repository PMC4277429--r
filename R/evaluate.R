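#' Build a gold standard from validation fold changes
#'
#' Implements the qRT-PCR-style gold-standard construction: a gene enters
#' the standard only if it is called present in at least
#' \code{min_present} of \code{n_replicates} replicate measurements in at
#' least one group; among those, genes with \code{|log2fc| > pos_cutoff}
#' are positives and genes with \code{|log2fc| < neg_cutoff} are
#' negatives. Genes between the cutoffs remain unlabeled.
#'
#' @param validation_table data frame with columns \code{gene_id},
#'   \code{log2fc}, \code{present_g1}, \code{present_g2} (counts of
#'   present calls per group).
#' @param pos_cutoff positive threshold on \code{|log2fc|}.
#' @param neg_cutoff negative threshold (default 0.2); must be below
#'   \code{pos_cutoff}.
#' @param min_present,n_replicates present-call rule (default 3 of 4).
#' @return A list of class \code{"GoldStandard"} with disjoint
#'   \code{positives} and \code{negatives} gene sets and the cutoffs.
#' @export
build_gold_standard <- function(validation_table, pos_cutoff,
                                neg_cutoff = 0.2, min_present = 3,
                                n_replicates = 4) {
  stopifnot(all(c("gene_id", "log2fc", "present_g1", "present_g2") %in%
                  names(validation_table)))
  if (pos_cutoff <= neg_cutoff)
    stop("pos_cutoff must exceed neg_cutoff")
  ok <- validation_table$present_g1 >= min_present |
        validation_table$present_g2 >= min_present
  v <- validation_table[ok, , drop = FALSE]
  structure(list(
    positives = v$gene_id[abs(v$log2fc) > pos_cutoff],
    negatives = v$gene_id[abs(v$log2fc) < neg_cutoff],
    pos_cutoff = pos_cutoff, neg_cutoff = neg_cutoff),
    class = "GoldStandard")
}

#' Standardized partial AUC at fixed specificity
#'
#' Trapezoidal partial area under the ROC curve over false-positive rates
#' in \code{[0, 1 - specificity]}, divided by \code{1 - specificity} when
#' standardized so a perfect ranking scores 1.0 (and exchangeable random
#' scores average \code{(1 - specificity)/2}). Smaller scores rank as more
#' significant; tied scores step diagonally.
#'
#' @param scores per-gene significance scores, ascending = significant.
#' @param labels logical (or 0/1): \code{TRUE} for gold-standard
#'   positives, \code{FALSE} for negatives. Unlabeled genes must be
#'   excluded beforehand.
#' @param specificity lower bound on specificity (default 0.8).
#' @param standardized divide by the maximal attainable area (default
#'   \code{TRUE}).
#' @return The (standardized) partial AUC.
#' @export
pauc <- function(scores, labels, specificity = 0.8, standardized = TRUE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(labels)),
            specificity > 0, specificity < 1)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("both classes must be present in the gold standard")
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)  # one ROC vertex per tie group
  fpr <- c(0, cumsum(!l)[last] / nn)
  tpr <- c(0, cumsum(l)[last] / np)
  fmax <- 1 - specificity
  inside <- which(fpr <= fmax)
  xs <- fpr[inside]; ys <- tpr[inside]
  j <- max(inside)
  if (j < length(fpr) && fpr[j] < fmax) {
    frac <- (fmax - fpr[j]) / (fpr[j + 1] - fpr[j])
    xs <- c(xs, fmax)
    ys <- c(ys, tpr[j] + frac * (tpr[j + 1] - tpr[j]))
  }
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  if (standardized) area / fmax else area
}

#' Empirical FDR of a detection list against a gold standard
#'
#' Detections with an analysis fold change below \code{prefilter_lfc} in
#' absolute value are removed first; among the remaining detections that
#' intersect the gold standard, the empirical FDR is the fraction that
#' are gold-standard negatives. When no detection intersects the
#' standard the value is undefined and \code{NA} is returned.
#'
#' @param detections data frame with columns \code{gene_id} and
#'   \code{log2fc} (the analysis fold change, not the validation one).
#' @param gold a \code{\link{build_gold_standard}} object (or any list
#'   with \code{positives} and \code{negatives}).
#' @param prefilter_lfc absolute log fold-change prefilter (default 0.2).
#' @return Empirical FDR in [0, 1], or \code{NA}.
#' @export
empirical_fdr <- function(detections, gold, prefilter_lfc = 0.2) {
  d <- detections[abs(detections$log2fc) >= prefilter_lfc, , drop = FALSE]
  n_neg <- sum(d$gene_id %in% gold$negatives)
  n_pos <- sum(d$gene_id %in% gold$positives)
  if (n_neg + n_pos == 0L) return(NA_real_)
  n_neg / (n_neg + n_pos)
}

#' Random-selection baseline for the empirical FDR
#'
#' For each requested list size, genes are drawn at random from the
#' scored universe, compared against the gold standard (no fold-change
#' prefilter: random picks carry no direction), and the empirical FDR is
#' averaged over the randomizations.
#'
#' @param detection_sizes integer vector of result-list sizes.
#' @param gold a \code{GoldStandard}.
#' @param universe character vector of selectable gene ids (all scored
#'   genes).
#' @param reps randomizations per size (default 100).
#' @param seed RNG seed; the global RNG state is preserved.
#' @return Numeric vector of mean empirical FDRs, one per size
#'   (\code{NA} for size 0 or when no draw intersects the standard).
#' @export
random_baseline <- function(detection_sizes, gold, universe, reps = 100,
                            seed = 1L) {
  if (any(detection_sizes > length(universe)))
    stop("detection size exceeds the gene universe")
  with_local_seed(seed, {
    vapply(detection_sizes, function(sz) {
      if (sz == 0L) return(NA_real_)
      vals <- vapply(seq_len(reps), function(i) {
        picked <- sample(universe, sz)
        n_neg <- sum(picked %in% gold$negatives)
        n_pos <- sum(picked %in% gold$positives)
        if (n_neg + n_pos == 0L) NA_real_ else n_neg / (n_neg + n_pos)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  })
}

#' Genes where the two strategies disagree
#'
#' Reports genes with more than \code{min_exons} exons for which one
#' strategy is significant (p below \code{p_thresh} and absolute linear
#' fold change above \code{fc_thresh}) while the other strategy either
#' shows a fold change in the opposite direction or a p-value differing
#' by more than \code{p_gap}. The gene-based p is compared against the
#' exon-based final score on the probability scale. The report carries
#' the median and standard deviation of the exon-level fold changes.
#'
#' @param exon_scores a \code{gene_scores} data frame (exon-based
#'   strategy).
#' @param gene_results gene-based result data frame with columns
#'   \code{gene_id}, \code{log2fc}, \code{p}.
#' @param exon_results the per-exon test results (for the fold-change
#'   spread).
#' @param min_exons genes must have strictly more exons than this
#'   (default 3).
#' @param fc_thresh linear fold-change threshold (default 2).
#' @param p_thresh significance threshold (default 0.05).
#' @param p_gap p-value difference threshold (default 0.1).
#' @return Data frame of discrepant genes with per-strategy fold changes
#'   and p-values, exon fold-change median and sd, sorted by gene id.
#' @export
discrepancy_report <- function(exon_scores, gene_results, exon_results,
                               min_exons = 3, fc_thresh = 2,
                               p_thresh = 0.05, p_gap = 0.1) {
  common <- intersect(exon_scores$gene_id, gene_results$gene_id)
  e <- exon_scores[match(common, exon_scores$gene_id), , drop = FALSE]
  g <- gene_results[match(common, gene_results$gene_id), , drop = FALSE]
  lfc_thresh <- log2(fc_thresh)
  sig_e <- e$final_score < p_thresh & abs(e$median_log2fc) > lfc_thresh
  sig_g <- g$p < p_thresh & abs(g$log2fc) > lfc_thresh
  opposite <- e$median_log2fc * g$log2fc < 0
  gap <- abs(g$p - e$final_score) > p_gap
  hit <- e$n_exons > min_exons & (sig_e | sig_g) & (opposite | gap)
  spread <- tapply(exon_results$x, exon_results$gene_id, stats::sd)
  out <- data.frame(gene_id = common,
                    n_exons = e$n_exons,
                    exon_median_log2fc = e$median_log2fc,
                    exon_log2fc_sd = as.numeric(spread[common]),
                    exon_final_score = e$final_score,
                    gene_log2fc = g$log2fc,
                    gene_p = g$p,
                    stringsAsFactors = FALSE)[hit, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
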