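#' Configuration for the interaction screen
#'
#' Bundles the significance thresholds of the three-criterion interaction
#' calling procedure: the minimum absolute synthetic effect, the
#' family-wise alpha applied after Bonferroni correction, and the null
#' expectation for the mutant fraction on a competition plate.
#'
#' @param epsilon_threshold Minimum `|epsilon|` for an interaction call
#'   (default 0.20).
#' @param alpha Bonferroni-adjusted significance threshold (default 0.01).
#' @param null_fraction Expected mutant fraction under equal fitness
#'   (default 0.5: equal numbers of mutant and wild-type founders).
#' @return A list of class `sgi_config`.
#' @export
sgi_config <- function(epsilon_threshold = 0.20, alpha = 0.01,
                       null_fraction = 0.5) {
  if (epsilon_threshold <= 0) stop("'epsilon_threshold' must be positive")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (null_fraction <= 0 || null_fraction >= 1) {
    stop("'null_fraction' must be in (0, 1)")
  }
  structure(
    list(
      epsilon_threshold = epsilon_threshold,
      alpha = alpha,
      null_fraction = null_fraction
    ),
    class = "sgi_config"
  )
}

#' Relative fitness from a competition plate
#'
#' The mutant fraction among all worms counted on the plate, divided by the
#' fraction expected if the mutant had wild-type fitness (50% when equal
#' numbers of mutant and wild-type founders are seeded). A plate on which
#' 40% of worms are mutant therefore gives `0.40 / 0.50 = 0.8`.
#'
#' @param mutant_count Number of mutant (marker-positive) worms counted.
#' @param total_count Total worms counted; must be positive.
#' @param null_fraction Expected mutant fraction under no fitness defect.
#' @return Relative fitness `F`, in `[0, 1/null_fraction]`. Vectorised.
#' @examples
#' relative_fitness(60, 150)  # 0.8
#' @export
relative_fitness <- function(mutant_count, total_count, null_fraction = 0.5) {
  if (any(is.na(mutant_count)) || any(is.na(total_count))) {
    stop("counts must not be missing")
  }
  if (any(total_count <= 0)) stop("'total_count' must be positive")
  if (any(mutant_count < 0) || any(mutant_count > total_count)) {
    stop("'mutant_count' must lie in [0, total_count]")
  }
  (mutant_count / total_count) / null_fraction
}

#' Expected double-mutant fitness under the multiplicative null
#'
#' Under the multiplicative null model a non-interacting double mutant's
#' fitness is the product of its single-mutant fitness values.
#'
#' @param f1,f2 Single-mutant relative fitness values (non-negative).
#' @return `f1 * f2`. Vectorised.
#' @export
expected_double_fitness <- function(f1, f2) {
  if (any(is.na(f1)) || any(is.na(f2)) || any(f1 < 0) || any(f2 < 0)) {
    stop("fitness values must be non-negative")
  }
  f1 * f2
}

#' Synthetic fitness effect
#'
#' The synthetic effect epsilon is the difference between a double mutant's
#' observed fitness and its multiplicative-null expectation. Negative values
#' are aggravating (worse than expected), positive values alleviating.
#'
#' @param f_obs Observed double-mutant relative fitness.
#' @param f_exp Expected fitness from [expected_double_fitness()].
#' @return `f_obs - f_exp`. Vectorised.
#' @export
synthetic_effect <- function(f_obs, f_exp) {
  if (any(is.na(f_obs)) || any(is.na(f_exp)) ||
      any(f_obs < 0) || any(f_exp < 0)) {
    stop("fitness values must be non-negative")
  }
  f_obs - f_exp
}

#' Validate a plate-count table
#'
#' Checks the `genotype_id, replicate_id, mutant_count, total_count` schema,
#' the count invariants, and warns about plates below the 150-worm counting
#' rule (such plates are retained).
#'
#' @param plates Data frame of plate observations.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_plates <- function(plates) {
  required <- c("genotype_id", "replicate_id", "mutant_count", "total_count")
  missing_cols <- setdiff(required, names(plates))
  if (length(missing_cols) > 0) {
    stop("plate table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(plates) == 0) stop("plate table is empty")
  if (any(plates$total_count <= 0)) stop("'total_count' must be positive")
  if (any(plates$mutant_count < 0) ||
      any(plates$mutant_count > plates$total_count)) {
    stop("'mutant_count' must lie in [0, total_count]")
  }
  n_small <- sum(plates$total_count < 150)
  if (n_small > 0) {
    warning(n_small, " plate(s) have fewer than 150 worms counted; ",
            "retained, but below the recommended counting depth")
  }
  plates
}

#' Fitness estimate for one genotype
#'
#' Pools mutant and total counts over all biological replicates of one
#' genotype and converts the pooled fraction to relative fitness. Replicate-
#' level fitness values are kept for the replication criterion of
#' [call_interaction()].
#'
#' @param plates Plate observations for a single genotype.
#' @param null_fraction Expected mutant fraction under no fitness defect.
#' @return A list with `genotype_id`, `F` (pooled), `per_replicate_F`,
#'   `pooled_mutant`, `pooled_total`, `n_replicates`.
#' @export
fitness_estimate <- function(plates, null_fraction = 0.5) {
  if (nrow(plates) == 0) stop("no plates supplied")
  gid <- unique(plates$genotype_id)
  if (length(gid) != 1) {
    stop("fitness_estimate() expects plates for exactly one genotype, got: ",
         paste(gid, collapse = ", "))
  }
  pooled_mut <- sum(plates$mutant_count)
  pooled_tot <- sum(plates$total_count)
  list(
    genotype_id = gid,
    F = relative_fitness(pooled_mut, pooled_tot, null_fraction),
    per_replicate_F = relative_fitness(plates$mutant_count,
                                       plates$total_count, null_fraction),
    pooled_mutant = pooled_mut,
    pooled_total = pooled_tot,
    n_replicates = nrow(plates)
  )
}

#' Fitness estimates for every genotype in a plate table
#'
#' @param plates Plate observations for any number of genotypes.
#' @param null_fraction Expected mutant fraction under no fitness defect.
#' @return Data frame with one row per genotype: `genotype_id`,
#'   `n_replicates`, `pooled_mutant`, `pooled_total`, `F`.
#' @export
estimate_fitness <- function(plates, null_fraction = 0.5) {
  validate_plates(plates)
  parts <- split(plates, plates$genotype_id)
  rows <- lapply(parts, function(p) {
    est <- fitness_estimate(p, null_fraction)
    data.frame(
      genotype_id = est$genotype_id,
      n_replicates = est$n_replicates,
      pooled_mutant = est$pooled_mutant,
      pooled_total = est$pooled_total,
      F = est$F,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All unordered gene pairs
#'
#' Enumerates the double mutants of an all-against-all screen: every
#' unordered pair of distinct genes, `n(n-1)/2` in total (13 genes give 78).
#'
#' @param genes Character vector of distinct gene labels.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
enumerate_pairs <- function(genes) {
  if (anyDuplicated(genes)) stop("gene labels must be distinct")
  if (length(genes) < 2) stop("need at least two genes")
  idx <- utils::combn(length(genes), 2)
  data.frame(
    gene_a = genes[idx[1, ]],
    gene_b = genes[idx[2, ]],
    stringsAsFactors = FALSE
  )
}

#' Call one genetic interaction with the three-criterion procedure
#'
#' Pools the double mutant's replicate plates, computes observed fitness,
#' the multiplicative-null expectation from the two single-mutant estimates,
#' and the synthetic effect epsilon, then applies three criteria:
#' `|epsilon|` at least `epsilon_threshold`; replication (at least two
#' biological replicates whose individual epsilon agrees in sign with the
#' pooled value); and a Fisher exact test of the pooled observed counts
#' against the null-expectation counts, Bonferroni-corrected over `m_tests`,
#' below `alpha`. Only pairs passing all three are significant.
#'
#' A double mutant with zero pooled mutant worms is recorded as synthetic
#' lethal: it bypasses the Fisher test (`p_raw`, `p_adj` are `NA`) and is
#' significant whenever its `|epsilon|` (which equals `F_exp`) clears the
#' threshold.
#'
#' @param plates_double Plate observations for the double mutant.
#' @param fit_a,fit_b Single-mutant estimates from [fitness_estimate()].
#' @param m_tests Bonferroni family size; in a screen this is the number of
#'   double mutants tested.
#' @param config An [sgi_config()].
#' @return One-row data frame: `gene_a`, `gene_b`, `F_obs`, `F_exp`,
#'   `epsilon`, `p_raw`, `p_adj`, `n_replicates`, `significant`, `category`
#'   (`none`, `aggravating`, `alleviating`, `lethal`).
#' @export
call_interaction <- function(plates_double, fit_a, fit_b, m_tests,
                             config = sgi_config()) {
  if (nrow(plates_double) == 0) stop("no plates for the double mutant")
  if (m_tests < 1 || m_tests != round(m_tests)) {
    stop("'m_tests' must be a positive integer")
  }
  nf <- config$null_fraction
  dbl <- fitness_estimate(plates_double, nf)
  f_exp <- expected_double_fitness(fit_a$F, fit_b$F)
  eps <- synthetic_effect(dbl$F, f_exp)

  if (dbl$pooled_mutant == 0 && f_exp > 0) {
    # synthetic lethality: no viable double homozygotes despite viable singles
    significant <- abs(eps) >= config$epsilon_threshold
    return(data.frame(
      gene_a = fit_a$genotype_id, gene_b = fit_b$genotype_id,
      F_obs = 0, F_exp = f_exp, epsilon = eps,
      p_raw = NA_real_, p_adj = NA_real_,
      n_replicates = dbl$n_replicates,
      significant = significant,
      category = "lethal",
      stringsAsFactors = FALSE
    ))
  }

  # expected-count table under the multiplicative null, rounded to integers
  exp_mut <- min(dbl$pooled_total, max(0, round(dbl$pooled_total * f_exp * nf)))
  p_raw <- fisher_exact_two_sided(
    dbl$pooled_mutant, dbl$pooled_total - dbl$pooled_mutant,
    exp_mut, dbl$pooled_total - exp_mut
  )
  p_adj <- bonferroni_adjust(p_raw, m_tests)

  eps_rep <- synthetic_effect(dbl$per_replicate_F, rep(f_exp, dbl$n_replicates))
  replicated <- eps != 0 && sum(sign(eps_rep) == sign(eps)) >= 2

  significant <- abs(eps) >= config$epsilon_threshold &&
    replicated && p_adj < config$alpha
  category <- if (!significant) "none" else if (eps < 0) "aggravating" else "alleviating"

  data.frame(
    gene_a = fit_a$genotype_id, gene_b = fit_b$genotype_id,
    F_obs = dbl$F, F_exp = f_exp, epsilon = eps,
    p_raw = p_raw, p_adj = p_adj,
    n_replicates = dbl$n_replicates,
    significant = significant,
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Run the full interaction screen on a plate table
#'
#' Splits genotypes into singles and doubles (double-mutant genotype ids are
#' `"geneA;geneB"`), estimates single-mutant fitness, and calls every double
#' with [call_interaction()], using the number of doubles as the Bonferroni
#' family size.
#'
#' @param plates Plate observations for singles and doubles.
#' @param config An [sgi_config()].
#' @param sep Separator splitting the two gene names in a double-mutant
#'   genotype id (default `";"`).
#' @return Data frame of interaction results, one row per double mutant.
#' @export
sgi_screen <- function(plates, config = sgi_config(), sep = ";") {
  validate_plates(plates)
  nf <- config$null_fraction
  ids <- unique(plates$genotype_id)
  is_double <- grepl(sep, ids, fixed = TRUE)
  doubles <- ids[is_double]
  if (length(doubles) == 0) stop("no double-mutant genotypes (ids with '", sep, "') found")

  singles <- lapply(ids[!is_double], function(g) {
    fitness_estimate(plates[plates$genotype_id == g, , drop = FALSE], nf)
  })
  names(singles) <- ids[!is_double]

  m <- length(doubles)
  rows <- lapply(doubles, function(d) {
    genes <- strsplit(d, sep, fixed = TRUE)[[1]]
    if (length(genes) != 2) stop("double genotype id '", d, "' does not split into two genes")
    if (!all(genes %in% names(singles))) {
      stop("double '", d, "' lacks single-mutant plates for: ",
           paste(setdiff(genes, names(singles)), collapse = ", "))
    }
    call_interaction(
      plates[plates$genotype_id == d, , drop = FALSE],
      singles[[genes[1]]], singles[[genes[2]]], m, config
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise an interaction screen
#'
#' Counts significant interactions (synthetic lethality counts as an
#' interaction), the fraction of tested pairs that interact, the per-gene
#' interaction degree, a symmetric epsilon matrix for heatmap display with a
#' companion lethality mask, and a weighted edge list for network display.
#'
#' @param results Interaction results from [sgi_screen()] or
#'   [call_interaction()].
#' @return A list: `n_tested`, `n_significant`, `rate`, `degree` (named
#'   integer vector), `epsilon_matrix`, `lethal_matrix`, `edges` (data frame
#'   `gene_a`, `gene_b`, `weight` = `|epsilon|`, significant pairs only).
#' @export
interaction_summary <- function(results) {
  genes <- sort(unique(c(results$gene_a, results$gene_b)))
  sig <- results[results$significant, , drop = FALSE]

  eps_mat <- matrix(NA_real_, length(genes), length(genes),
                    dimnames = list(genes, genes))
  lethal_mat <- matrix(FALSE, length(genes), length(genes),
                       dimnames = list(genes, genes))
  for (i in seq_len(nrow(results))) {
    a <- results$gene_a[i]; b <- results$gene_b[i]
    eps_mat[a, b] <- eps_mat[b, a] <- results$epsilon[i]
    if (results$category[i] == "lethal") {
      lethal_mat[a, b] <- lethal_mat[b, a] <- TRUE
    }
  }

  degree <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(sig))) {
    degree[sig$gene_a[i]] <- degree[sig$gene_a[i]] + 1L
    degree[sig$gene_b[i]] <- degree[sig$gene_b[i]] + 1L
  }

  edges <- data.frame(
    gene_a = sig$gene_a, gene_b = sig$gene_b,
    weight = abs(sig$epsilon),
    stringsAsFactors = FALSE
  )

  list(
    n_tested = nrow(results),
    n_significant = nrow(sig),
    rate = if (nrow(results) > 0) nrow(sig) / nrow(results) else 0,
    degree = degree,
    epsilon_matrix = eps_mat,
    lethal_matrix = lethal_mat,
    edges = edges
  )
}
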