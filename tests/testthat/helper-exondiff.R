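# Fixture builders and independent oracles shared across test files.

# Small exon count table built in code: 3 genes (2/3/1 exons), 4 samples.
make_tiny_table <- function() {
  cts <- matrix(c(
    10, 12,  9, 11,
    20, 18, 22, 19,
     5,  6,  4,  7,
    50, 55, 48, 52,
     0,  1,  0,  2,
   100, 90, 95, 98),
    nrow = 6, byrow = TRUE,
    dimnames = list(c("G1:E001", "G1:E002", "G2:E001", "G2:E002",
                      "G2:E003", "G3:E001"),
                    c("s1", "s2", "s3", "s4")))
  exon_count_table(cts, gene_id = c("G1", "G1", "G2", "G2", "G2", "G3"),
                   samples = data.frame(sample_id = paste0("s", 1:4),
                                        group = c("A", "A", "B", "B")))
}

write_dexseq_file <- function(counts, path, meta = c("_ambiguous" = 3)) {
  lines <- c(paste(names(counts), counts, sep = "\t"),
             paste(names(meta), meta, sep = "\t"))
  writeLines(lines, path)
  path
}

# Brute-force Benjamini-Hochberg step-up: walk p-values from largest to
# smallest, adj_i = min over j >= rank(i) of n/j * p_(j), capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- 1
  for (i in seq_along(o)) {
    rank_i <- n - i + 1
    running <- min(running, n / rank_i * p[o[i]])
    adj[o[i]] <- running
  }
  adj
}

# Direct implementation of the doubly trimmed precision-weighted TMM
# factor of one sample against a reference (30% trim on M, 5% on A),
# written independently of edgeR.
tmm_oracle_pair <- function(obs, ref) {
  libo <- sum(obs); libr <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / libo) / (r / libr))
  A <- (log2(o / libo) + log2(r / libr)) / 2
  # delta-method variance of each log-ratio; precision weight is 1/v
  v <- (libo - o) / (libo * o) + (libr - r) / (libr * r)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- 2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  if (!is.finite(f)) f <- 1
  f
}

tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)),
              function(j) tmm_oracle_pair(counts[, j], counts[, ref]),
              numeric(1))
  f / exp(mean(log(f)))
}

# Monte Carlo estimate of P(|median of n standard Laplace| >= t) by
# simulating medians directly (independent of the analytic binomial
# identity under test).
mc_null_tail <- function(n, t, reps, seed) {
  draws <- exondiff:::with_local_seed(seed, laplace_median_draws(n, reps))
  vapply(t, function(tt) mean(abs(draws) >= tt), numeric(1))
}

expect_no_rng_change <- function(expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  before <- get(".Random.seed", envir = globalenv())
  force(expr)
  after <- get(".Random.seed", envir = globalenv())
  expect_identical(before, after)
}
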