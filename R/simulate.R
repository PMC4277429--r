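#' Configuration for the exon-count simulator
#'
#' Defines a two-group experiment of negative-binomial exon counts with
#' gene-level differential expression, optional deviant (outlier) exons,
#' and log-normal library-size variation. The defaults describe a bulk
#' RNA-seq experiment of moderate depth: gene totals log-normal around a
#' few hundred reads, exon usage spread by a Dirichlet with concentration
#' 5 (uneven but rarely degenerate), dispersion 0.1 (biological
#' replicates), and DE effects of about two-fold with symmetric direction.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range \code{c(min, max)}; exon numbers are
#'   drawn uniformly from it.
#' @param n_per_group samples per group (>= 2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene total mean count.
#' @param exon_usage_conc Dirichlet concentration spreading a gene's
#'   expression over its exons (larger = more even usage).
#' @param dispersion negative-binomial dispersion phi in
#'   \code{var = mu + phi * mu^2}.
#' @param de_fraction fraction of genes differentially expressed.
#' @param effect_mean,effect_sd absolute log2 fold change of DE genes is
#'   \code{N(effect_mean, effect_sd^2)}; the sign is a fair coin.
#' @param outlier_exon_prob probability that an exon of a DE gene carries
#'   an independent deviant effect instead of the gene effect.
#' @param outlier_mean,outlier_sd deviant-exon absolute log2 fold change is
#'   \code{N(outlier_mean, outlier_sd^2)}, directed opposite to the gene
#'   effect (emulating an alternative-splicing event).
#' @param libsize_sdlog log-normal sd of the per-sample library-size
#'   factor.
#' @param seed RNG seed.
#' @return A list of class \code{"SimConfig"}.
#' @export
sim_config <- function(n_genes = 2000L, exons_per_gene = c(2L, 15L),
                       n_per_group = 5L,
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       exon_usage_conc = 5, dispersion = 0.1,
                       de_fraction = 0.1,
                       effect_mean = 1, effect_sd = 0.25,
                       outlier_exon_prob = 0,
                       outlier_mean = 2, outlier_sd = 0.5,
                       libsize_sdlog = 0.15, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_per_group = as.integer(n_per_group),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              exon_usage_conc = exon_usage_conc,
              dispersion = dispersion,
              de_fraction = de_fraction,
              effect_mean = effect_mean, effect_sd = effect_sd,
              outlier_exon_prob = outlier_exon_prob,
              outlier_mean = outlier_mean, outlier_sd = outlier_sd,
              libsize_sdlog = libsize_sdlog,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, length(cfg$exons_per_gene) == 2,
            cfg$exons_per_gene[1] >= 1,
            cfg$exons_per_gene[2] >= cfg$exons_per_gene[1],
            cfg$n_per_group >= 2, cfg$dispersion > 0,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$outlier_exon_prob >= 0, cfg$outlier_exon_prob <= 1,
            cfg$exon_usage_conc > 0)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a two-group exon-count experiment with known truth
#'
#' Exon means are \code{libsize_s * gene_mean * usage_fraction *
#' 2^(effect)} with the effect applied to the second group only; counts
#' are negative binomial with \code{var = mu + phi mu^2}. The run is fully
#' reproducible from the seed in the configuration, and the caller's RNG
#' state is preserved.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with \code{table} (an \code{\link{exon_count_table}},
#'   groups "A" and "B") and \code{truth}: \code{genes} (gene_id, is_de,
#'   gene_log2fc) and \code{exons} (exon_id, gene_id, exon_log2fc,
#'   is_outlier).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_local_seed(config$seed, {
    ng <- config$n_genes
    ex_range <- seq(config$exons_per_gene[1], config$exons_per_gene[2])
    n_ex <- if (length(ex_range) == 1L) rep(ex_range, ng)
            else sample(ex_range, ng, replace = TRUE)
    gene_ids <- sprintf("G%05d", seq_len(ng))
    gene_mean <- stats::rlnorm(ng, config$baseline_meanlog,
                               config$baseline_sdlog)
    is_de <- stats::runif(ng) < config$de_fraction
    gene_lfc <- ifelse(is_de,
                       sample(c(-1, 1), ng, replace = TRUE) *
                         stats::rnorm(ng, config$effect_mean,
                                      config$effect_sd),
                       0)
    n_s <- 2L * config$n_per_group
    group <- rep(c("A", "B"), each = config$n_per_group)
    sample_ids <- sprintf("s%02d_%s", seq_len(n_s), group)
    lib <- stats::rlnorm(n_s, 0, config$libsize_sdlog)

    total_exons <- sum(n_ex)
    gene_of <- rep(seq_len(ng), n_ex)
    # Dirichlet usage per gene via normalized gammas; degenerate draws
    # (all mass on one exon of a multi-exon gene) are resampled
    n_ex_of <- rep(n_ex, n_ex)
    usage <- stats::rgamma(total_exons, shape = config$exon_usage_conc)
    usage_sum <- stats::ave(usage, gene_of, FUN = sum)
    bad <- usage_sum == 0 | (usage / usage_sum >= 1 & n_ex_of > 1)
    while (any(bad)) {
      usage[bad] <- stats::rgamma(sum(bad), shape = config$exon_usage_conc)
      usage_sum <- stats::ave(usage, gene_of, FUN = sum)
      bad <- usage_sum == 0 | (usage / usage_sum >= 1 & n_ex_of > 1)
    }
    usage <- usage / usage_sum

    exon_lfc <- gene_lfc[gene_of]
    is_outlier <- is_de[gene_of] &
      stats::runif(total_exons) < config$outlier_exon_prob
    n_out <- sum(is_outlier)
    if (n_out > 0)
      exon_lfc[is_outlier] <- -sign(exon_lfc[is_outlier]) *
        abs(stats::rnorm(n_out, config$outlier_mean, config$outlier_sd))

    exon_in_gene <- sequence(n_ex)
    exon_ids <- sprintf("%s:E%03d", gene_ids[gene_of], exon_in_gene)
    base_mean <- gene_mean[gene_of] * usage
    effect <- outer(exon_lfc, as.numeric(group == "B"))  # exons x samples
    mu <- (base_mean %o% lib) * 2^effect
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$dispersion),
                     nrow = total_exons,
                     dimnames = list(exon_ids, sample_ids))
    table <- exon_count_table(counts, gene_ids[gene_of],
                              samples = data.frame(sample_id = sample_ids,
                                                   group = group,
                                                   stringsAsFactors = FALSE))
    truth <- list(
      genes = data.frame(gene_id = gene_ids, is_de = is_de,
                         gene_log2fc = gene_lfc, n_exons = n_ex,
                         stringsAsFactors = FALSE),
      exons = data.frame(exon_id = exon_ids, gene_id = gene_ids[gene_of],
                         exon_log2fc = exon_lfc, is_outlier = is_outlier,
                         stringsAsFactors = FALSE))
    list(table = table, truth = truth, config = config)
  })
}

#' One outlier-exon gene among null genes
#'
#' Constructs the scenario in which the two strategies disagree: a single
#' gene whose exons change moderately and concordantly between groups,
#' except for one highly expressed exon with a strong change in the
#' opposite direction. Because that exon carries half of the gene's reads,
#' it dominates the summed count and pulls the gene-level fold change back
#' toward zero, while the per-exon median is untouched. The gene is
#' embedded among null genes so that normalization, variance shrinkage and
#' FDR adjustment all operate realistically.
#'
#' @param n_exons exons of the target gene (>= 2).
#' @param concordant_lfc log2 fold change shared by the concordant exons.
#' @param outlier_lfc log2 fold change of the deviant exon.
#' @param n_per_group samples per group.
#' @param n_null_genes null genes surrounding the target (>= 200 so the
#'   FDR machinery has something to work on).
#' @param outlier_weight fraction of the gene's expression carried by the
#'   deviant exon. The default (\code{NULL}) picks the weight at which the
#'   deviant exon cancels the concordant signal in the summed counts,
#'   \code{w = (2^c - 1) / (2^c - 2^o)} — the masking regime in which the
#'   gene-level fold change collapses to zero; when no weight in (0, 1)
#'   achieves cancellation (e.g. no deviant effect), 0.5 is used.
#' @param gene_mean expected total count of the target gene per sample.
#' @param dispersion negative-binomial dispersion; the default 0.01 is the
#'   technical-replicate regime of lane-replicated benchmark designs, which
#'   this seven-versus-seven scenario mirrors.
#' @param seed RNG seed.
#' @return As \code{\link{simulate_experiment}}; the target gene is
#'   \code{"TARGET"}.
#' @export
make_outlier_gene_case <- function(n_exons = 8L, concordant_lfc = 1.0,
                                   outlier_lfc = -4.0, n_per_group = 7L,
                                   n_null_genes = 200L,
                                   outlier_weight = NULL,
                                   gene_mean = 2000, dispersion = 0.01,
                                   seed = 1L) {
  if (is.null(outlier_weight)) {
    w <- (2^concordant_lfc - 1) / (2^concordant_lfc - 2^outlier_lfc)
    outlier_weight <- if (is.finite(w) && w > 0 && w < 1) w else 0.5
  }
  stopifnot(n_exons >= 2L, n_null_genes >= 1L,
            outlier_weight > 0, outlier_weight < 1)
  bg_cfg <- sim_config(n_genes = n_null_genes, n_per_group = n_per_group,
                       de_fraction = 0, dispersion = dispersion,
                       seed = seed)
  bg <- simulate_experiment(bg_cfg)
  with_local_seed(seed + 1000003L, {
    group <- as.character(bg$table$samples$group)
    n_s <- length(group)
    usage <- c(rep((1 - outlier_weight) / (n_exons - 1), n_exons - 1),
               outlier_weight)
    exon_lfc <- c(rep(concordant_lfc, n_exons - 1), outlier_lfc)
    effect <- outer(exon_lfc, as.numeric(group == "B"))
    mu <- (gene_mean * usage) %o% rep(1, n_s) * 2^effect
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow = n_exons)
    rownames(counts) <- sprintf("TARGET:E%03d", seq_len(n_exons))
    colnames(counts) <- colnames(bg$table$counts)
    table <- exon_count_table(rbind(counts, bg$table$counts),
                              c(rep("TARGET", n_exons), bg$table$gene_id),
                              bg$table$samples)
    truth <- list(
      genes = rbind(data.frame(gene_id = "TARGET", is_de = TRUE,
                               gene_log2fc = concordant_lfc,
                               n_exons = n_exons, stringsAsFactors = FALSE),
                    bg$truth$genes),
      exons = rbind(data.frame(exon_id = rownames(counts),
                               gene_id = "TARGET",
                               exon_log2fc = exon_lfc,
                               is_outlier = c(rep(FALSE, n_exons - 1), TRUE),
                               stringsAsFactors = FALSE),
                    bg$truth$exons))
    list(table = table, truth = truth)
  })
}
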