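#' Log2 fold change over the row mean
#'
#' Heatmap transform for expression matrices: each entry becomes
#' `log2((x + pseudocount) / (rowmean + pseudocount))`, so a gene's values
#' are centred on its own mean expression and a constant gene maps to zero.
#' The transform is invariant to rescaling the whole matrix (at pseudocount
#' zero) and the linear ratios in each row average to one.
#'
#' @param x Numeric matrix of non-negative normalised counts, genes in
#'   rows, samples in columns.
#' @param pseudocount Positive offset guarding against zero counts
#'   (default 1).
#' @return Matrix of the same shape.
#' @export
log2_fold_over_mean <- function(x, pseudocount = 1) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty matrix")
  if (any(x < 0)) stop("counts must be non-negative")
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  rm <- rowMeans(x)
  log2((x + pseudocount) / (rm + pseudocount))
}

#' Direction-of-change bias among differentially expressed genes
#'
#' Counts significant genes with positive versus negative log2 fold change
#' (mutant over wild type). Genes with exactly zero fold change are excluded
#' from the fraction and reported separately.
#'
#' @param de Data frame with columns `gene`, `log2fc`, `significant`
#'   (logical).
#' @return A list with `n_up`, `n_down`, `n_zero`, `fraction_up`.
#' @export
direction_bias <- function(de) {
  required <- c("gene", "log2fc", "significant")
  if (!all(required %in% names(de))) {
    stop("DE table needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(de$gene)) stop("gene ids must be unique")
  sig <- de[de$significant, , drop = FALSE]
  if (nrow(sig) == 0) stop("no significant genes in the DE table")
  n_up <- sum(sig$log2fc > 0)
  n_down <- sum(sig$log2fc < 0)
  n_zero <- sum(sig$log2fc == 0)
  list(
    n_up = n_up, n_down = n_down, n_zero = n_zero,
    fraction_up = if (n_up + n_down > 0) n_up / (n_up + n_down) else NA_real_
  )
}

#' Overlap of two gene sets with hypergeometric significance
#'
#' Venn-style decomposition of two gene sets plus the upper-tail
#' hypergeometric probability of an intersection at least as large, given
#' the universe both sets were drawn from.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Size of the common universe (total testable genes or
#'   junctions).
#' @return A list with `n_a`, `n_b`, `a_only`, `b_only`, `overlap`,
#'   `fraction_of_a` (overlap / |A|), and `p` from
#'   [hypergeometric_overlap_test()].
#' @export
overlap_sets <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe || length(set_b) > universe) {
    stop("set sizes cannot exceed the universe size")
  }
  ov <- length(intersect(set_a, set_b))
  list(
    n_a = length(set_a), n_b = length(set_b),
    a_only = length(set_a) - ov, b_only = length(set_b) - ov,
    overlap = ov,
    fraction_of_a = if (length(set_a) > 0) ov / length(set_a) else NA_real_,
    p = hypergeometric_overlap_test(length(set_a), length(set_b), ov, universe)
  )
}

#' Cluster an expression matrix for heatmap display
#'
#' Applies [log2_fold_over_mean()] and orders genes by K-means cluster, the
#' same clustering procedure used for junction-usage heatmaps.
#'
#' @param x Non-negative count matrix, genes in rows.
#' @param k,runs,seed Clustering parameters (defaults 10 clusters, 1000
#'   restarts).
#' @param pseudocount Offset for the log transform.
#' @return A list with `matrix` (transformed values, rows ordered by
#'   cluster), `labels`, `inertia`.
#' @export
expression_heatmap_matrix <- function(x, k = 10, runs = 1000, seed = 1,
                                      pseudocount = 1) {
  lf <- log2_fold_over_mean(x, pseudocount)
  cl <- kmeans_cluster(lf, k = k, runs = runs, seed = seed)
  o <- order(cl$labels)
  list(matrix = lf[o, , drop = FALSE], labels = cl$labels[o],
       inertia = cl$inertia)
}
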