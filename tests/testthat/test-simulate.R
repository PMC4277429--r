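test_that("simulation is reproducible and leaves the caller's RNG alone", {
  cfg <- sim_config(n_genes = 50, n_per_group = 3, seed = 21)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_no_rng_change(simulate_experiment(cfg))
  # different seed, different counts
  d <- simulate_experiment(sim_config(n_genes = 50, n_per_group = 3,
                                      seed = 22))
  expect_false(identical(a$table$counts, d$table$counts))
})

test_that("truth tables align with the count table", {
  sim <- simulate_experiment(sim_config(n_genes = 80, n_per_group = 3,
                                        de_fraction = 0.3, seed = 4))
  expect_identical(sim$truth$exons$exon_id, rownames(sim$table$counts))
  expect_identical(sim$truth$exons$gene_id, sim$table$gene_id)
  expect_setequal(sim$truth$genes$gene_id, unique(sim$table$gene_id))
  # non-DE genes carry zero effects and no outliers
  null_genes <- sim$truth$genes$gene_id[!sim$truth$genes$is_de]
  ex0 <- sim$truth$exons[sim$truth$exons$gene_id %in% null_genes, ]
  expect_true(all(ex0$exon_log2fc == 0))
  expect_false(any(ex0$is_outlier))
})

test_that("counts follow the configured negative-binomial moments", {
  # pin every stochastic layer except the NB draw: constant gene mean,
  # two equal-usage exons, no library spread, no DE
  cfg <- sim_config(n_genes = 500, exons_per_gene = c(2, 2),
                    n_per_group = 50, baseline_meanlog = log(200),
                    baseline_sdlog = 0, exon_usage_conc = 1e9,
                    dispersion = 0.1, de_fraction = 0,
                    libsize_sdlog = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  x <- as.numeric(sim$table$counts)   # 1e5 draws at mu = 100
  expect_equal(mean(x), 100, tolerance = 0.01)
  expect_equal(stats::var(x), 100 + 0.1 * 100^2, tolerance = 0.1)
})

test_that("per-sample totals match the configured scale", {
  cfg <- sim_config(n_genes = 2000, n_per_group = 3, de_fraction = 0,
                    libsize_sdlog = 0, seed = 15)
  sim <- simulate_experiment(cfg)
  expected <- cfg$n_genes * exp(cfg$baseline_meanlog +
                                  cfg$baseline_sdlog^2 / 2)
  expect_equal(mean(colSums(sim$table$counts)) / expected, 1,
               tolerance = 0.1)
})

test_that("exon usage never degenerates onto a single exon", {
  sim <- simulate_experiment(sim_config(n_genes = 200, n_per_group = 2,
                                        exon_usage_conc = 0.05, seed = 2))
  totals <- rowsum(rowSums(sim$table$counts), sim$table$gene_id)
  per_exon <- rowSums(sim$table$counts)
  frac <- per_exon / totals[sim$table$gene_id, 1]
  multi <- sim$truth$genes$n_exons[match(sim$table$gene_id,
                                         sim$truth$genes$gene_id)] > 1
  expect_true(all(frac[multi & totals[sim$table$gene_id, 1] > 0] < 1 + 1e-12))
})

test_that("truth labels round-trip: a perfect scorer attains pAUC 1", {
  sim <- simulate_experiment(sim_config(n_genes = 300, n_per_group = 3,
                                        de_fraction = 0.2, seed = 33))
  tg <- sim$truth$genes
  oracle_scores <- ifelse(tg$is_de, 0, 1)    # ascending = significant
  expect_equal(pauc(oracle_scores, tg$is_de), 1.0)
  det <- data.frame(gene_id = tg$gene_id[tg$is_de],
                    log2fc = tg$gene_log2fc[tg$is_de])
  gold <- structure(list(positives = tg$gene_id[tg$is_de],
                         negatives = tg$gene_id[!tg$is_de]),
                    class = "GoldStandard")
  expect_equal(empirical_fdr(det, gold, prefilter_lfc = 0), 0)
})

test_that("the outlier-gene scenario has the advertised structure", {
  oc <- make_outlier_gene_case(n_exons = 6, n_null_genes = 20, seed = 3)
  tg <- oc$truth$exons[oc$truth$exons$gene_id == "TARGET", ]
  expect_equal(nrow(tg), 6L)
  expect_equal(sum(tg$is_outlier), 1L)
  expect_equal(tg$exon_log2fc[!tg$is_outlier], rep(1, 5))
  expect_equal(tg$exon_log2fc[tg$is_outlier], -4)
  # the deviant exon carries about half of the gene's reads
  tgt <- oc$table$counts[oc$table$gene_id == "TARGET",
                         oc$table$samples$group == "A"]
  w <- rowSums(tgt) / sum(tgt)
  expect_gt(w[tg$is_outlier], 0.4)
  # reproducible
  oc2 <- make_outlier_gene_case(n_exons = 6, n_null_genes = 20, seed = 3)
  expect_identical(oc$table$counts, oc2$table$counts)
})
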