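---
title: "The exon-based strategy: model, null distribution and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The exon-based strategy: model, null distribution and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The common way to call differentially expressed (DE) genes from RNA-seq is
to sum the reads falling into each gene and test the summed counts. A
gene's summary count, however, is dominated by its most highly expressed
exons. When one exon behaves differently from the rest — an alternative
splicing event, an unannotated overlapping feature, a mapping artifact —
the summed-count fold change is pulled toward that exon, and a moderate
but systematic change across the remaining exons can vanish entirely from
the gene-level view.

`exondiff` inverts the order of operations: test *each exon* for a
two-group difference first, then aggregate the per-exon results into one
gene-level score. Because the aggregate is a median, a single deviant exon
cannot move it, and because every exon contributes a measurement, moderate
changes shared across many exons gain power that a single summary count
does not have.

## The gene score

Let exon $i$ of a gene have estimated log2 fold change $x_i$ and two-sided
p-value $p_i$ from any per-exon test. Each exon contributes a signed
log-transformed p-value

$$ s_i = \operatorname{sgn}(x_i)\,(-\ln p_i), $$

and the gene score is the median over its $n$ tested exons,

$$ m = \operatorname{median}(s_1, \dots, s_n). $$

The log transformation sends the least significant p-value ($p = 1$) to
zero, so uninformative exons contribute nothing; the sign carries the
direction of the change, so exons changing in opposite directions cancel
instead of reinforcing. The magnitude is reported back on the p-value
scale as `median_p` $= e^{-|m|}$. Any other mean descriptor can replace
the median (`aggregator = "mean"`), at the price of the median's
robustness.

## Calibration against the uniform null

Under no differential expression, $p_i \sim \mathrm{Uniform}(0,1)$ and the
sign of $x_i$ is a fair coin independent of $p_i$ (both hold for a
two-sided test of a symmetric statistic). Then $s_i = \pm(-\ln U)$ is a
standard Laplace variable, and the null distribution of $m$ is that of a
median of $n$ i.i.d. Laplace draws. `null_tail(n, t)` returns
$P(|m| \ge t)$:

* **Odd $n$** — exact. The median exceeds $t$ iff at least $(n+1)/2$ of
  the draws do, each with probability $q = e^{-t}/2$, so by symmetry
  $$P(|m| \ge t) = 2 \sum_{k \ge (n+1)/2} \binom{n}{k} q^k (1-q)^{n-k}.$$
* **Even $n$** — the median is the mean of the two central order
  statistics and the closed form is inconvenient; the tail is read from a
  cached Monte Carlo table (default $2 \times 10^6$ draws, fixed seed
  285713, recorded in the table object). The estimator is the empirical
  survival function with a $(k+1)/(\text{reps}+1)$ correction, which is
  monotone by construction and keeps the p-value in $(0, 1]$; tables are
  cached per session and can be saved/reloaded bit-exactly
  (`save_null_table`, `load_null_table`).

The per-gene null p-value is `null_p` $=$ `null_tail(n, |m|)`. Natural
logarithms are used in $s_i$ precisely so that the null contribution of
each exon is *standard* Laplace, which is what makes the odd-$n$ closed
form available; `median_p` is base-free because it back-transforms with
the same logarithm.

Across genes, `null_p` is adjusted by the Benjamini–Hochberg step-up
(`fdr`), and the ranking statistic is the **max rule**

$$ \text{final\_score} = \max(\text{median\_p},\ \text{fdr}), $$

which guarantees that a gene ranked significant at level $\alpha$ also has
a median p-value below $\alpha$ — a gene can be extremely *consistent*
(tiny `null_p` because all eight exons agree) while the shared effect
itself is weak; the max rule keeps such genes from outranking genes with
both consistent and strong signals.

## Filtering

Before testing, exons whose overall mean count across all samples is not
strictly above 1 are removed; genes left with fewer than two such exons
are dropped, and genes that had only one exon to begin with are dropped
outright (for them, the two strategies coincide by construction). The
"overall average" is read as the pooled mean over all samples — not the
mean of group means; with balanced designs the two differ only slightly,
and both thresholds are arguments of `filter_exons()`.

The gene-based comparison sums, by default, *all* exons of the retained
genes, not only those passing the exon filter: the summed-count pipeline
it emulates never sees an exon filter. `run_gene_strategy(...,
sum_filtered_only = TRUE)` switches to post-filter sums.

## The built-in per-exon test

The aggregation is test-agnostic — any per-exon table of $(x_i, p_i)$ can
be supplied via `read_external_exon_results()` + `score_genes()`. The
built-in test is a moderated t on log-CPM values:

1. TMM scaling factors (`edgeR::calcNormFactors`; 30% trim on M-values,
   5% on A-values, precision-weighted, factors rescaled to geometric
   mean 1) define effective library sizes.
2. $\log_2\!\big((\text{count} + 0.5) / (\text{eff. lib.} + 1) \times
   10^6\big)$ with a prior count of 0.5 keeps zeros finite.
3. A feature-wise two-group fit gives the group-mean difference and
   pooled residual variance on $n_1 + n_2 - 2$ degrees of freedom.
4. Residual variances are shrunk toward a scaled inverse-chi-square prior
   fitted by moment matching on the log scale (`limma::fitFDist`); the
   moderated t is referred to $d_0 + d_\text{resid}$ degrees of freedom
   (normal when $d_0 = \infty$).

No mean–variance precision weights are applied (a voom-style extension
would slot into step 3); consequently p-values for very low counts lean
conservative. The identical code path runs on exon-level and on summed
gene-level tables, so strategy comparisons never confound the test with
the aggregation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_avg` | 1 (counts) | exon kept if pooled mean count strictly above this |
| `min_exons` | 2 | minimum surviving exons per gene |
| `prior_count` | 0.5 (counts) | log-CPM offset |
| `aggregator` | `"median"` | per-gene mean descriptor over $s_i$ |
| `mc_reps`, `mc_seed` | 2e6, 285713 | even-$n$ null table |
| `fdr_max` | 0.05 | calling: FDR threshold |
| `min_abs_fc` | 1.5 (linear) | calling: $|{\rm median\ log2FC}| \ge \log_2 1.5$ |
| `min_exons` (calling) | 5 | calling: minimum exon support |
| `median_p_max` | 0.05 | calling, exon-based only |

P-values are clamped to $[10^{-300}, 1]$ before the log transform (the
clamp, not the test, bounds attainable scores at $\approx 690$);
$\operatorname{sgn}(0) = 0$, so a zero fold change contributes a zero
score. Result tables are ranked ascending by `final_score` with ties
broken lexicographically by gene id, making identical runs byte-identical.

## What the simulator emulates — and what it does not

`simulate_experiment()` draws gene totals from a log-normal
(median 200 counts, $\sigma_{\log} = 1$), spreads them over 2–15 exons by
a Dirichlet with concentration 5 (uneven usage, never degenerate),
applies a gene-level effect $\pm N(1, 0.25^2)$ in log2 to a configurable
fraction of genes, optionally replaces individual exon effects of DE
genes with opposite-sign deviant effects $N(2, 0.5^2)$ (the
alternative-splicing surrogate), multiplies by log-normal library-size
factors ($\sigma_{\log} = 0.15$), and draws negative-binomial counts with
$\mathrm{var} = \mu + \phi \mu^2$, $\phi = 0.1$ — biological-replicate
dispersion. These defaults were fixed once as a realistic bulk RNA-seq
regime of moderate depth.

`make_outlier_gene_case()` constructs the masking scenario directly: one
gene with moderate concordant exon changes and a single strongly deviant,
highly expressed exon, embedded among null genes. Two defaults differ
from the general simulator, both because the scenario mirrors a
lane-replicated benchmark design: dispersion 0.01 (technical, not
biological, replication across seven lanes per group) and a deviant-exon
expression weight chosen so that the deviant exon *cancels* the
concordant signal in the summed counts,
$w = (2^c - 1)/(2^c - 2^o) \approx 0.52$ at the defaults — the regime in
which the gene-based fold change collapses toward zero and the summary
test reports the gene as unchanged while every concordant exon moves. An
explicit `outlier_weight` overrides the cancellation default.

The simulator does **not** model read-level effects (positional bias, GC,
mappability), transcript structure (deviant exons are independent draws,
not coherent isoform switches), correlated exon noise within a gene, or
population structure in the heterogeneous-cohort regime (approximate that
by raising `dispersion` and `libsize_sdlog`). Passing tests on simulated
data therefore demonstrate the statistical machinery — calibration,
robustness, ranking — under the model's assumptions, not performance on
any particular real dataset.

## Evaluation toolkit

* `pauc()` — trapezoidal partial area under the ROC over false-positive
  rates $[0, 1-\text{specificity}]$ (default specificity 0.8),
  standardized by $1-\text{specificity}$ so a perfect ranking scores 1;
  tied scores step diagonally; genes outside the gold standard are
  excluded by the caller. With $n$ finite negatives the null expectation
  is $\sum_{j \le 0.2 n} j / (0.2\, n (n+1)) \to 0.1$.
* `build_gold_standard()` — validation-based positives
  ($|{\log_2 \mathrm{FC}}|$ above a cutoff) and negatives (below 0.2)
  among genes present in at least 3 of 4 replicate measurements in at
  least one group.
* `empirical_fdr()` — among detections intersecting the standard, the
  fraction that are negatives, after removing detections with
  $|{\log_2 \mathrm{FC}}| < 0.2$; `random_baseline()` averages the same
  quantity over random result lists of equal size.
* `discrepancy_report()` — genes (more than 3 exons) significant with
  large fold change under one strategy while the other shows an
  opposite-direction fold change or a p-value differing by more than
  0.1. Fold-change thresholds are linear-scale throughout ("fold change
  above 2" means $|{\log_2 \mathrm{FC}}| > 1$).

## Numerical and design choices

* **Null sign model.** Signs are independent fair coins under the null,
  independent of the p-value magnitudes — the symmetric-null reading of
  "taking the directions into account". A directional imbalance under
  the null (e.g. composition effects surviving normalization) would make
  the null anti-conservative; TMM normalization is applied first to
  remove exactly such shifts.
* **BH on `null_p`, not on `median_p`.** `null_p` is the quantity that is
  uniform under the null, hence the valid input to a step-up procedure;
  `median_p` re-enters through the max rule.
* **Even-$n$ Monte Carlo instead of grid interpolation.** The empirical
  survival function of the sorted draw table is monotone, exact with
  respect to its own sample, and reloads bit-identically; a smoothed grid
  would add an approximation layer without accuracy gain at $2\times10^6$
  draws.
* **Degenerate inputs.** Single-exon genes are rejected by the scorer
  (the upstream filter removes them); an all-zero sample fails
  normalization with a named error; `p = 0` in external results is
  accepted at read time, reported, and clamped at transform time.
* **Problem sizes in the test-suite.** Calibration runs use 2000 genes at
  5 vs 5 across three seeds; the masking scenario 25 seeds of 201 genes
  at 7 vs 7; the ranking comparison 10 seeds of 3000 genes — sizes at
  which the binomial/KS tolerances used by the tests are decisive for
  the claims being checked.

## Known limitations

* Exon-level tests within a gene are treated as independent under the
  null; shared reads across overlapping exon bins or strong within-gene
  count correlation would make the null optimistic. The counting dialect
  (disjoint exon bins) minimizes, but does not eliminate, this.
* The built-in moderated t is one member of the family of tests the
  strategy can host; it claims calibration, not superiority — substitute
  any per-exon test through the plugin table when a negative-binomial
  exact or GLM test is preferred.
* Differential exon *usage* (isoform switching without gene-level
  change) is expressly not the target: a usage switch with no net change
  scores near zero by sign cancellation, by design.

## A minimal session

```{r, eval = FALSE}
library(exondiff)

sim <- simulate_experiment(sim_config(n_genes = 500, n_per_group = 5,
                                      de_fraction = 0.1,
                                      outlier_exon_prob = 0.3, seed = 1))
ex <- run_exon_strategy(sim$table)
gn <- run_gene_strategy(sim$table)
head(ex$scores)

ev <- cmd_evaluate(ex, gn, sim$truth$genes)
ev$pauc
```
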