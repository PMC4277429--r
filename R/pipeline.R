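#' Run the exon-based strategy
#'
#' Filter exons, normalize, test every exon, aggregate to gene scores and
#' apply the calling criteria. \code{table} is the raw (unfiltered) count
#' table; filtering parameters follow the package defaults.
#'
#' @param table an \code{\link{exon_count_table}} with group labels.
#' @param min_avg,min_exons filtering thresholds, see
#'   \code{\link{filter_exons}}.
#' @param prior_count prior count for the log-CPM transform.
#' @param aggregator \code{"median"} or \code{"mean"}.
#' @param mc_reps,mc_seed even-n null table parameters.
#' @param criteria named list overriding \code{\link{call_genes}}
#'   defaults.
#' @return A list with \code{scores} (ranked \code{gene_scores}),
#'   \code{exon_results} and the \code{filtered} table.
#' @export
run_exon_strategy <- function(table, min_avg = 1, min_exons = 2,
                              prior_count = 0.5, aggregator = "median",
                              mc_reps = 2e6, mc_seed = 285713L,
                              criteria = list()) {
  ft <- filter_exons(table, min_avg = min_avg, min_exons = min_exons)
  if (nrow(ft$counts) == 0L) stop("no exons survive filtering")
  res <- test_features(ft, prior_count = prior_count)
  scores <- score_genes(res, aggregator = aggregator,
                        mc_reps = mc_reps, mc_seed = mc_seed)
  scores <- do.call(call_genes, c(list(scores = scores), criteria))
  list(scores = scores, exon_results = res, filtered = ft)
}

#' Run the conventional gene-based strategy
#'
#' Sums exon counts per gene and tests the summed counts directly. The
#' gene universe matches the exon-based strategy (genes surviving
#' \code{\link{filter_exons}}), but by default the sums are taken over all
#' exons of each retained gene — the full gene signal, as a gene-level
#' count pipeline would see it. Set \code{sum_filtered_only = TRUE} to sum
#' only the exons that pass the filter.
#'
#' @inheritParams run_exon_strategy
#' @param sum_filtered_only sum post-filter exons instead of all exons of
#'   retained genes.
#' @return A list with \code{results}: a data frame with one row per gene
#'   (\code{gene_id}, \code{n_exons} of tested exons, \code{log2fc},
#'   \code{p}, \code{fdr}, and the alias columns \code{median_log2fc},
#'   \code{final_score}, \code{called} so that
#'   \code{\link{write_gene_results}} and \code{\link{call_genes}} apply
#'   unchanged), ranked ascending by \code{final_score}.
#' @export
run_gene_strategy <- function(table, min_avg = 1, min_exons = 2,
                              prior_count = 0.5, sum_filtered_only = FALSE,
                              criteria = list()) {
  ft <- filter_exons(table, min_avg = min_avg, min_exons = min_exons)
  if (nrow(ft$counts) == 0L) stop("no exons survive filtering")
  keep_genes <- unique(ft$gene_id)
  src <- if (sum_filtered_only) ft
         else subset_exons(table, table$gene_id %in% keep_genes)
  gt <- sum_gene_counts(src)
  res <- test_features(gt, prior_count = prior_count)
  n_tested <- as.integer(base::table(factor(ft$gene_id,
                                            levels = res$gene_id)))
  out <- data.frame(gene_id = res$gene_id, n_exons = n_tested,
                    log2fc = res$x, p = res$p, fdr = bh_adjust(res$p),
                    stringsAsFactors = FALSE)
  out$median_log2fc <- out$log2fc   # alias: shared downstream interface
  out$final_score <- out$fdr
  out$called <- FALSE
  out <- do.call(call_genes, c(list(scores = out), criteria))
  out <- out[order(out$final_score, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  list(results = out, gene_table = gt, filtered = ft)
}

#' Run a configured analysis and write result files
#'
#' The top-level workflow: reads counts (matrix TSV via \code{counts} +
#' \code{samples}, or per-sample files via \code{sample_sheet} with
#' \code{file_path}), runs the requested strategy (\code{"exon"},
#' \code{"gene"} or \code{"both"}) and writes ranked result tables plus a
#' run log recording the package version, seeds and filter tallies.
#' Re-running an identical configuration produces byte-identical result
#' tables.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   \code{counts}, \code{samples} (TSV with sample_id, group),
#'   \code{sample_sheet} (TSV with sample_id, group, file_path),
#'   \code{strategy}, \code{min_avg}, \code{min_exons},
#'   \code{prior_count}, \code{aggregator}, \code{mc_reps},
#'   \code{mc_seed}, \code{criteria} (named list), \code{out_dir}.
#' @return Invisibly, the paths of the files written.
#' @export
cmd_run <- function(config) {
  cfg <- load_run_config(config)
  table <- if (!is.null(cfg$sample_sheet)) {
    ss <- utils::read.delim(cfg$sample_sheet, stringsAsFactors = FALSE)
    read_dexseq_counts(ss)
  } else {
    ss <- utils::read.delim(cfg$samples, stringsAsFactors = FALSE)
    read_count_matrix(cfg$counts, sample_sheet = ss)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- c(sprintf("exondiff %s",
                         as.character(utils::packageVersion("exondiff"))),
                 sprintf("strategy: %s", cfg$strategy),
                 sprintf("min_avg: %g  min_exons: %d", cfg$min_avg,
                         cfg$min_exons),
                 sprintf("null table: mc_reps=%g mc_seed=%d", cfg$mc_reps,
                         cfg$mc_seed))
  if (cfg$strategy %in% c("exon", "both")) {
    ex <- run_exon_strategy(table, min_avg = cfg$min_avg,
                            min_exons = cfg$min_exons,
                            prior_count = cfg$prior_count,
                            aggregator = cfg$aggregator,
                            mc_reps = cfg$mc_reps, mc_seed = cfg$mc_seed,
                            criteria = cfg$criteria)
    p1 <- file.path(cfg$out_dir, "exon_based_results.tsv")
    write_gene_results(ex$scores, p1)
    written <- c(written, p1)
    fr <- attr(ex$filtered, "filter_report")
    log_lines <- c(log_lines,
                   sprintf("filter: %s", paste(names(fr), fr, sep = "=",
                                               collapse = " ")))
  }
  if (cfg$strategy %in% c("gene", "both")) {
    gn <- run_gene_strategy(table, min_avg = cfg$min_avg,
                            min_exons = cfg$min_exons,
                            prior_count = cfg$prior_count,
                            criteria = cfg$criteria)
    p2 <- file.path(cfg$out_dir, "gene_based_results.tsv")
    g <- gn$results
    g$score_m <- NA
    g$median_p <- NA
    g$null_p <- NA
    write_gene_results(g, p2)
    written <- c(written, p2)
  }
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(c(written, log_path))
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(strategy = "both", min_avg = 1, min_exons = 2L,
                   prior_count = 0.5, aggregator = "median",
                   mc_reps = 2e6, mc_seed = 285713L, criteria = list(),
                   out_dir = ".")
  cfg <- utils::modifyList(defaults, config)
  cfg$min_exons <- as.integer(cfg$min_exons)
  cfg$mc_seed <- as.integer(cfg$mc_seed)
  if (!cfg$strategy %in% c("exon", "gene", "both"))
    stop("strategy must be one of exon, gene, both")
  if (is.null(cfg$sample_sheet) && (is.null(cfg$counts) || is.null(cfg$samples)))
    stop("config needs either 'sample_sheet' or both 'counts' and 'samples'")
  cfg
}

#' Simulate an experiment and write counts plus truth files
#'
#' @param config a \code{\link{sim_config}}, a named list of its
#'   arguments, or a path to a YAML file of them.
#' @param out_dir output directory.
#' @return Invisibly, the paths written: the count matrix TSV, the sample
#'   sheet, gene and exon truth TSVs, and the echoed configuration YAML.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  sim <- simulate_experiment(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("counts.tsv", "samples.tsv",
                                "truth_genes.tsv", "truth_exons.tsv",
                                "sim_config.yaml"))
  write_count_matrix(sim$table, paths[1])
  utils::write.table(sim$table$samples, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$genes, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$exons, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(config), paths[5])
  invisible(paths)
}

#' Evaluate both strategies against truth labels or a gold standard
#'
#' Computes the standardized partial AUC (specificity 0.8) of each
#' strategy, an empirical-FDR curve over a grid of FDR cutoffs with the
#' random-selection baseline, and the discrepancy report.
#'
#' @param exon_run result of \code{\link{run_exon_strategy}}.
#' @param gene_run result of \code{\link{run_gene_strategy}}.
#' @param truth the \code{truth$genes} data frame of a simulation (used
#'   as labels), or a \code{GoldStandard}.
#' @param fdr_cutoffs grid of FDR cutoffs for the empirical-FDR curve.
#' @param seed seed for the random baseline.
#' @return A list with \code{pauc} (named vector), \code{fdr_curve}
#'   (data frame) and \code{discrepancies}.
#' @export
cmd_evaluate <- function(exon_run, gene_run, truth,
                         fdr_cutoffs = seq(0.01, 0.2, by = 0.01),
                         seed = 1L) {
  es <- exon_run$scores
  gs <- gene_run$results
  if (inherits(truth, "GoldStandard")) {
    gold <- truth
  } else {
    stopifnot(all(c("gene_id", "is_de") %in% names(truth)))
    gold <- structure(list(positives = truth$gene_id[truth$is_de],
                           negatives = truth$gene_id[!truth$is_de]),
                      class = "GoldStandard")
  }
  labeled <- function(scores_df, score_col) {
    ids <- scores_df$gene_id
    lab <- ifelse(ids %in% gold$positives, TRUE,
                  ifelse(ids %in% gold$negatives, FALSE, NA))
    keep <- !is.na(lab)
    list(scores = scores_df[[score_col]][keep], labels = lab[keep])
  }
  le <- labeled(es, "final_score")
  lg <- labeled(gs, "final_score")
  paucs <- c(exon = pauc(le$scores, le$labels),
             gene = pauc(lg$scores, lg$labels))
  curve <- do.call(rbind, lapply(fdr_cutoffs, function(cut) {
    de <- es[es$final_score < cut, c("gene_id", "median_log2fc")]
    names(de)[2] <- "log2fc"
    dg <- gs[gs$final_score < cut, c("gene_id", "log2fc")]
    data.frame(cutoff = cut,
               exon_fdr = empirical_fdr(de, gold),
               gene_fdr = empirical_fdr(dg, gold),
               exon_n = nrow(de), gene_n = nrow(dg),
               exon_random = random_baseline(nrow(de), gold, es$gene_id,
                                             seed = seed),
               gene_random = random_baseline(nrow(dg), gold, gs$gene_id,
                                             seed = seed))
  }))
  disc <- discrepancy_report(es, gs, exon_run$exon_results)
  list(pauc = paucs, fdr_curve = curve, discrepancies = disc)
}
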