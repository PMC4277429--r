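make_filter_table <- function(means_per_gene, n_samples = 4) {
  # build a table whose per-exon all-sample means are exactly as given
  rows <- list(); genes <- character(0)
  for (g in names(means_per_gene)) {
    m <- means_per_gene[[g]]
    for (i in seq_along(m)) {
      rows[[length(rows) + 1L]] <- rep(m[i], n_samples)
      genes <- c(genes, g)
    }
  }
  # integer counts achieving each target mean: constant rows for integer
  # means, alternating floor/ceiling for half-integer means
  cts <- t(vapply(rows, function(r) {
    m <- r[1]
    if (m == round(m)) rep(m, n_samples)
    else rep(c(floor(m), ceiling(m)), length.out = n_samples)
  }, numeric(n_samples)))
  rownames(cts) <- paste0(genes, ":E", ave(seq_along(genes), genes,
                                           FUN = seq_along))
  colnames(cts) <- paste0("s", seq_len(n_samples))
  exon_count_table(cts, genes,
                   data.frame(sample_id = colnames(cts),
                              group = rep(c("A", "B"),
                                          length.out = n_samples)))
}

test_that("exon filter applies the mean>1 rule and drops depleted genes", {
  tab <- make_filter_table(list(G1 = c(0.5, 1.5, 2),   # exon 1 removed
                                G2 = c(0.5, 1.5),      # one survivor -> gone
                                G3 = c(50)))           # single-exon -> gone
  ft <- suppressMessages(filter_exons(tab))
  expect_equal(sort(rownames(ft$counts)), c("G1:E2", "G1:E3"))
  expect_equal(unique(ft$gene_id), "G1")
  rep_ <- attr(ft, "filter_report")
  expect_equal(unname(rep_["single_exon_genes"]), 1)
})

test_that("a mean of exactly min_avg is removed (strict inequality)", {
  cts <- matrix(c(1, 1, 1, 1,    # mean exactly 1 -> out
                  2, 2, 2, 2,
                  3, 3, 3, 3), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("G1:E", 1:3), paste0("s", 1:4)))
  tab <- exon_count_table(cts, rep("G1", 3),
                          data.frame(sample_id = paste0("s", 1:4),
                                     group = c("A", "A", "B", "B")))
  ft <- suppressMessages(filter_exons(tab))
  expect_equal(rownames(ft$counts), c("G1:E2", "G1:E3"))
})

test_that("exon filtering is idempotent", {
  tab <- make_tiny_table()
  f1 <- suppressMessages(filter_exons(tab))
  f2 <- suppressMessages(filter_exons(f1))
  expect_identical(f1$counts, f2$counts)
  expect_identical(f1$gene_id, f2$gene_id)
})

test_that("filtering everything warns instead of erroring", {
  cts <- matrix(0L, 2, 2, dimnames = list(c("G1:E1", "G1:E2"),
                                          c("s1", "s2")))
  tab <- exon_count_table(cts, c("G1", "G1"),
                          data.frame(sample_id = c("s1", "s2"),
                                     group = c("A", "B")))
  expect_warning(suppressMessages(filter_exons(tab)), "all exons")
})

test_that("gene sums add exon counts and preserve totals", {
  tab <- make_tiny_table()
  gt <- sum_gene_counts(tab)
  expect_equal(nrow(gt$counts), 3L)
  expect_equal(unname(gt$counts["G1", ]),
               unname(tab$counts["G1:E001", ] + tab$counts["G1:E002", ]))
  # single remaining exon: gene row equals exon row
  expect_equal(unname(gt$counts["G3", ]), unname(tab$counts["G3:E001", ]))
  # per-sample totals preserved
  expect_equal(colSums(gt$counts), colSums(tab$counts))
})

test_that("TMM factors: symmetry, depth invariance, geometric mean one", {
  set.seed(7)
  base <- matrix(rpois(400, 50), 100, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  same <- base[, c(1, 1, 1, 1)]
  expect_equal(unname(tmm_factors(same)$tmm_factor), rep(1, 4))

  doubled <- cbind(s1 = base[, 1], s2 = base[, 1] * 2L)
  f <- tmm_factors(doubled)
  expect_equal(unname(f$tmm_factor), c(1, 1))
  expect_equal(unname(f$effective_library_size),
               unname(f$library_size))

  f4 <- tmm_factors(base)$tmm_factor
  expect_lt(abs(exp(mean(log(f4))) - 1), 1e-12)

  zero <- base; zero[, 2] <- 0L
  expect_error(tmm_factors(zero), "zero total count")
})

test_that("a composition-biased sample gets a factor below one", {
  set.seed(11)
  base <- rpois(200, 50)
  biased <- base
  biased[1] <- sum(base)   # one feature takes ~50% of that sample's reads
  counts <- cbind(s1 = base, s2 = base, s3 = biased)
  f <- tmm_factors(counts)$tmm_factor
  expect_lt(f[3], 1)
  expect_lt(f[3], min(f[1:2]))
})

test_that("TMM factors agree with a direct trimmed-mean oracle", {
  set.seed(23)
  for (i in 1:5) {
    counts <- matrix(rnbinom(300 * 4, mu = 80, size = 5), 300, 4,
                     dimnames = list(NULL, paste0("s", 1:4)))
    counts <- counts + 1L  # keep features shared so the pair sets match
    expect_equal(unname(tmm_factors(counts)$tmm_factor),
                 unname(tmm_oracle(counts)), tolerance = 1e-8)
  }
})

test_that("log-CPM follows its defining formula", {
  cts <- matrix(c(0, 1000), 1, 2, dimnames = list("G1:E1", c("s1", "s2")))
  norm <- structure(list(library_size = c(1e6, 1e7),
                         tmm_factor = c(1, 1),
                         effective_library_size = c(1e6, 1e7)),
                    class = "NormalizationState")
  lc <- log_cpm(cts, norm)
  expect_equal(lc[1, 1], log2(0.5 / 1000001 * 1e6), tolerance = 1e-12)
  # doubling a count against a large library adds ~1
  cts2 <- matrix(c(1000, 2000), 1, 2,
                 dimnames = list("G1:E1", c("s1", "s2")))
  norm2 <- structure(list(library_size = c(1e7, 1e7),
                          tmm_factor = c(1, 1),
                          effective_library_size = c(1e7, 1e7)),
                     class = "NormalizationState")
  lc2 <- log_cpm(cts2, norm2)
  expect_equal(lc2[1, 2] - lc2[1, 1], 1, tolerance = 1e-3)
  # equal counts at equal effective sizes give equal values
  expect_equal(log_cpm(matrix(c(7, 7), 1, 2,
                              dimnames = list("e", c("a", "b"))),
                       norm2)[1, ] |> unname() |> diff(), 0)
})
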