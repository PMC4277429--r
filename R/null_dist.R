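# Null model: under no differential expression each exon contributes
# S = sgn * (-ln U) with U ~ Uniform(0,1) and an independent fair sign,
# i.e. S is standard Laplace. The gene score m is the median of n such
# draws; null_tail(n, t) = P(|median(S_1..S_n)| >= t).

.null_cache <- new.env(parent = emptyenv())

#' Evaluate the seed-preserving RNG block
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Draw medians of n standard Laplace variables
#'
#' Vectorized sampler used for the even-n null table and available as a
#' Monte Carlo cross-check of the analytic odd-n tail. Rows are sorted with
#' a radix trick instead of per-row \code{median()} calls so tens of
#' millions of draws stay fast.
#'
#' @param n number of Laplace draws per median.
#' @param reps number of medians.
#' @param chunk rows per internal block (memory control).
#' @return Numeric vector of \code{reps} medians.
#' @export
laplace_median_draws <- function(n, reps, chunk = 5e5L) {
  n <- as.integer(n)
  reps <- as.integer(reps)
  out <- numeric(reps)
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    m <- matrix(sample(c(-1, 1), k * n, replace = TRUE) * stats::rexp(k * n),
                nrow = k)
    o <- order(row(m), m, method = "radix")
    sm <- matrix(m[o], nrow = k, byrow = TRUE)
    med <- if (n %% 2L == 1L) sm[, (n + 1L) %/% 2L]
           else (sm[, n %/% 2L] + sm[, n %/% 2L + 1L]) / 2
    out[(done + 1L):(done + k)] <- med
    done <- done + k
  }
  out
}

#' Monte Carlo null table for a given number of exons
#'
#' Sorted absolute medians of \code{reps} simulated genes with \code{n}
#' exons under the uniform-p, symmetric-sign null. Tables are cached in
#' memory per session, keyed by \code{(n, reps, seed)}, and can be saved
#' and reloaded bit-exactly.
#'
#' @param n number of exons.
#' @param reps Monte Carlo repetitions (default 2e6).
#' @param seed RNG seed for the table; the global RNG state is left
#'   untouched.
#' @return A list of class \code{"NullTable"} with the sorted absolute
#'   medians (\code{abs_m}) and the generating parameters.
#' @export
null_table <- function(n, reps = 2e6, seed = 285713L) {
  key <- sprintf("n%d_r%d_s%d", as.integer(n), as.integer(reps),
                 as.integer(seed))
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  draws <- with_local_seed(seed, laplace_median_draws(n, reps))
  tab <- structure(list(n = as.integer(n), reps = as.integer(reps),
                        seed = as.integer(seed),
                        abs_m = sort(abs(draws))),
                   class = "NullTable")
  .null_cache[[key]] <- tab
  tab
}

#' @rdname null_table
#' @param tab a \code{NullTable}.
#' @param path file path for the cache (RDS).
#' @export
save_null_table <- function(tab, path) {
  saveRDS(tab, path)
  invisible(path)
}

#' @rdname null_table
#' @export
load_null_table <- function(path) {
  tab <- readRDS(path)
  stopifnot(inherits(tab, "NullTable"))
  key <- sprintf("n%d_r%d_s%d", tab$n, tab$reps, tab$seed)
  .null_cache[[key]] <- tab
  tab
}

#' Tail probability of the absolute median score under the null
#'
#' For odd \code{n} the tail is exact: the median exceeds \code{t} iff at
#' least \code{(n+1)/2} of the \code{n} Laplace draws do, each with
#' probability \code{q = exp(-t)/2}, so by symmetry
#' \code{tail = 2 * P(Binomial(n, q) >= (n+1)/2)}. For even \code{n} the
#' median is the mean of the two central order statistics and the tail is
#' read from a cached Monte Carlo table (empirical survival with a
#' \code{(k+1)/(reps+1)} estimator, keeping the result in (0, 1]).
#'
#' @param n number of exons (scalar integer >= 1).
#' @param t non-negative threshold(s) on the absolute median score.
#' @param mc_reps,mc_seed Monte Carlo table parameters for even \code{n}.
#' @return Tail probabilities in (0, 1], same length as \code{t}.
#' @export
#' @examples
#' null_tail(1, 2)       # exp(-2)
#' null_tail(3, 1)       # 2 * (3 q^2 (1-q) + q^3), q = exp(-1)/2
null_tail <- function(n, t, mc_reps = 2e6, mc_seed = 285713L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (any(t < 0)) stop("t must be non-negative")
  if (n %% 2L == 1L) {
    q <- exp(-t) / 2
    k <- (n - 1L) %/% 2L  # tail = P(X >= k+1) = P(X > k)
    pmin(1, 2 * stats::pbinom(k, size = n, prob = q, lower.tail = FALSE))
  } else {
    tab <- null_table(n, reps = mc_reps, seed = mc_seed)
    # number of |M| draws >= t via position in the sorted table
    n_ge <- tab$reps - findInterval(t, tab$abs_m, left.open = TRUE)
    ifelse(t == 0, 1, (n_ge + 1) / (tab$reps + 1))
  }
}

#' Null p-value of an observed gene score
#'
#' @param m observed signed median score(s).
#' @param n number of exons of the gene (scalar).
#' @param ... passed to \code{\link{null_tail}}.
#' @return \code{null_tail(n, abs(m))}.
#' @export
gene_null_pvalue <- function(m, n, ...) null_tail(n, abs(m), ...)
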