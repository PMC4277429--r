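#' Per-feature two-group fit on log-CPM values
#'
#' Ordinary least squares for the two-group design, computed feature-wise:
#' the effect is the difference of group means (second group minus first)
#' and the residual variance is pooled within groups.
#'
#' @param logcpm numeric matrix, features x samples.
#' @param groups two-level factor (or coercible) over the samples; the
#'   effect is \code{level2 - level1}.
#' @return A data frame with one row per feature: \code{x} (log2 fold
#'   change), \code{s2} (pooled residual variance), \code{df_resid}
#'   (\code{n - 2}) and \code{avg_expr} (mean log-CPM).
#' @export
fit_two_group <- function(logcpm, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (ncol(logcpm) != length(groups))
    stop("length of 'groups' must match the number of samples")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  df_resid <- n1 + n2 - 2L
  if (df_resid < 1L)
    stop("insufficient replication: residual degrees of freedom would be ",
         df_resid)
  m1 <- rowMeans(logcpm[, i1, drop = FALSE])
  m2 <- rowMeans(logcpm[, i2, drop = FALSE])
  rss <- rowSums((logcpm[, i1, drop = FALSE] - m1)^2) +
         rowSums((logcpm[, i2, drop = FALSE] - m2)^2)
  data.frame(x = m2 - m1, s2 = rss / df_resid, df_resid = df_resid,
             avg_expr = rowMeans(logcpm), row.names = rownames(logcpm))
}

#' Empirical-Bayes prior for residual variances
#'
#' Fits a scaled inverse chi-square prior to the observed residual
#' variances by moment matching on the log scale, the standard machinery
#' behind moderated t-statistics (delegated to \code{limma::fitFDist}).
#' When the empirical spread of the log variances does not exceed the
#' theoretical chi-square spread, the prior degrees of freedom are
#' infinite and all variances shrink to a common value.
#'
#' @param s2 numeric vector of residual variances (at least two positive
#'   values unless all are equal).
#' @param df_resid residual degrees of freedom of the fits (scalar).
#' @return A list of class \code{"ShrinkagePrior"} with \code{d0} (prior
#'   degrees of freedom, possibly \code{Inf}) and \code{s0_sq} (prior
#'   variance).
#' @export
estimate_prior <- function(s2, df_resid) {
  s2 <- as.numeric(s2)
  if (length(s2) < 1L) stop("no variances supplied")
  if (length(unique(s2)) == 1L)
    return(structure(list(d0 = Inf, s0_sq = s2[1]), class = "ShrinkagePrior"))
  if (sum(s2 > 0) < 2L)
    stop("need at least two positive variances to fit a prior")
  fit <- limma::fitFDist(s2, df1 = df_resid)
  d0 <- fit$df2
  s0 <- fit$scale
  if (!is.finite(d0) || d0 <= 0) d0 <- Inf
  if (!is.finite(s0) || s0 <= 0)
    stop("prior variance estimate is not positive")
  structure(list(d0 = d0, s0_sq = s0), class = "ShrinkagePrior")
}

#' Moderated two-sided p-values
#'
#' Squeezes each residual variance toward the prior,
#' \code{s2_post = (d0 * s0_sq + df * s2) / (d0 + df)}, forms the moderated
#' t-statistic for the group difference and refers it to a t-distribution
#' on \code{d0 + df} degrees of freedom (the normal tail when \code{d0} is
#' infinite).
#'
#' @param x log2 fold changes.
#' @param s2 residual variances.
#' @param df_resid residual degrees of freedom (scalar).
#' @param prior a \code{ShrinkagePrior} from \code{\link{estimate_prior}}.
#' @param n1,n2 group sizes.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @export
moderated_p <- function(x, s2, df_resid, prior, n1, n2) {
  d0 <- prior$d0
  s2_post <- if (is.finite(d0))
    (d0 * prior$s0_sq + df_resid * s2) / (d0 + df_resid)
  else rep(prior$s0_sq, length(s2))
  tstat <- x / sqrt(s2_post * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df = d0 + df_resid)
}

#' Test every feature of a count table for a two-group difference
#'
#' The full built-in test: TMM normalization, log-CPM transformation,
#' feature-wise two-group fit, variance shrinkage and moderated p-values.
#' The same code path serves exon-level tables (exon-based strategy) and
#' gene-level summed tables (gene-based strategy).
#'
#' @param table a filtered \code{\link{exon_count_table}} with two-group
#'   labels.
#' @param norm optional \code{NormalizationState}; computed when
#'   \code{NULL}.
#' @param groups optional two-level factor overriding the table's group
#'   labels.
#' @param prior_count prior count for \code{\link{log_cpm}}.
#' @return A data frame with columns \code{exon_id}, \code{gene_id},
#'   \code{x}, \code{p}, \code{avg_expr}, \code{s2}, \code{df_resid}, plus
#'   the shrinkage prior as attribute \code{"prior"}.
#' @export
test_features <- function(table, norm = NULL, groups = NULL,
                          prior_count = 0.5) {
  if (is.null(groups)) groups <- table_groups(table)
  groups <- droplevels(as.factor(groups))
  lc <- log_cpm(table, norm = norm, prior = prior_count)
  fit <- fit_two_group(lc, groups)
  prior <- estimate_prior(fit$s2, fit$df_resid[1])
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  p <- moderated_p(fit$x, fit$s2, fit$df_resid[1], prior, n1, n2)
  out <- data.frame(exon_id = rownames(table$counts),
                    gene_id = table$gene_id,
                    x = fit$x, p = p, avg_expr = fit$avg_expr,
                    s2 = fit$s2, df_resid = fit$df_resid,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  out
}
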