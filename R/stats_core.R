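#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' Computes the two-sided Fisher exact p-value by conditioning on the table
#' margins: the p-value is the sum of hypergeometric probabilities of every
#' table with the same margins whose probability does not exceed that of the
#' observed table (the convention used by [stats::fisher.test()]).
#'
#' This is the workhorse test of both pipelines: the aggregate
#' observed-vs-expected fitness tables of the interaction screen and the
#' pooled junction-count tables of the differential-usage analysis.
#'
#' @param a,b,c,d Non-negative integer counts. The table is
#'   `rbind(c(a, b), c(c, d))`: rows are the two conditions, columns the two
#'   outcomes.
#' @return A single p-value in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)   # 1: identical proportions
#' fisher_exact_two_sided(2, 8, 8, 2)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency table entries must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) {
    stop("all-zero contingency table: Fisher's exact test is undefined")
  }
  r1 <- a + b   # row 1 margin
  c1 <- a + c   # column 1 margin
  lo <- max(0L, r1 - (n - c1))
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
  logp_obs <- stats::dhyper(a, c1, n - c1, r1, log = TRUE)
  # relative tolerance guards against ties broken by floating-point noise
  keep <- logp <= logp_obs + log(1 + 1e-7)
  min(1, sum(exp(logp[keep])))
}

#' Bonferroni multiple-testing adjustment
#'
#' Family-wise error control by multiplying each raw p-value by the number of
#' tests and capping at one. The interaction screen uses an adjusted
#' threshold of 0.01 over the tested double mutants; the splicing pipeline
#' uses 0.05 over the tested junction pairs.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of tests in the family; defaults to `length(p)`.
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    stop("'m' must be a positive integer")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, p * m)
}

#' Upper-tail hypergeometric test for set overlap
#'
#' Probability of observing at least `overlap` shared elements between two
#' sets of sizes `n_a` and `n_b` drawn without replacement from a common
#' universe, i.e. `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, n_a, n_b)`. Used to score the overlap of
#' differentially spliced junction sets between genotypes.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param overlap Observed intersection size.
#' @param universe Size of the common universe both sets are drawn from.
#' @return Upper-tail p-value.
#' @export
hypergeometric_overlap_test <- function(n_a, n_b, overlap, universe) {
  args <- c(n_a, n_b, overlap, universe)
  if (any(is.na(args)) || any(args < 0) || any(args != round(args))) {
    stop("all arguments must be non-negative integers")
  }
  if (n_a > universe || n_b > universe) {
    stop("set sizes cannot exceed the universe size")
  }
  if (overlap > min(n_a, n_b)) {
    stop("overlap cannot exceed the smaller set size")
  }
  stats::phyper(overlap - 1, n_a, universe - n_a, n_b, lower.tail = FALSE)
}

#' Multi-restart K-means clustering
#'
#' Runs Lloyd's K-means `runs` times from seeded random initialisations and
#' keeps the labelling of the restart with the smallest within-cluster sum of
#' squares (ties keep the first restart encountered). Restart sub-seeds are
#' drawn once from `seed`, so results are reproducible and the best inertia
#' is non-increasing in `runs` for a fixed seed.
#'
#' Initial centres are sampled from the distinct rows of `x`, so duplicated
#' rows cannot abort a restart. No internal rescaling is applied: callers
#' pass already-transformed matrices (log2 fold over mean, or relative
#' junction usage in `[0, 1]`).
#'
#' @param x Numeric matrix, items in rows, features in columns. No missing
#'   values.
#' @param k Number of clusters; must not exceed the number of distinct rows.
#' @param runs Number of random restarts (default 1000).
#' @param seed Integer seed for the restart sequence.
#' @return A list with `labels` (integer cluster index per row, named by
#'   rownames), `inertia` (best within-cluster sum of squares), `centers`,
#'   and `run_inertias` (per-restart inertia, for diagnostics).
#' @export
kmeans_cluster <- function(x, k, runs = 1000, seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("'x' must not contain missing values")
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (runs < 1 || runs != round(runs)) stop("'runs' must be a positive integer")
  if (k > nrow(x)) {
    stop("'k' (", k, ") exceeds the number of items (", nrow(x), ")")
  }
  ux <- unique(x)
  if (k > nrow(ux)) {
    stop("'k' (", k, ") exceeds the number of distinct rows (", nrow(ux), ")")
  }
  rng <- local({
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max, runs)
  })
  best <- NULL
  run_inertias <- numeric(runs)
  for (i in seq_len(runs)) {
    set.seed(rng[i])
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
    run_inertias[i] <- km$tot.withinss
    if (is.null(best) || km$tot.withinss < best$tot.withinss) {
      best <- km
    }
  }
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(x)
  list(
    labels = labels,
    inertia = best$tot.withinss,
    centers = best$centers,
    run_inertias = run_inertias
  )
}
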