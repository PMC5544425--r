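#' Parse a STAR splice-junction count file
#'
#' Reads one `SJ.out.tab`-dialect file: nine tab-separated columns
#' (chromosome, intron start, intron end, strand code, motif code, annotated
#' flag, uniquely-mapping read count, multi-mapping read count, maximum
#' overhang), 1-based inclusive intron coordinates, no header.
#'
#' @param path Path to the junction file.
#' @param sample_id Label under which this sample's counts are registered.
#' @return Data frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand_code` (0 undefined, 1 plus, 2 minus), `motif_code`,
#'   `annotated`, `unique_reads`, `multi_reads`, `max_overhang`,
#'   `sample_id`. Empty files give a zero-row frame.
#' @export
parse_star_sj <- function(path, sample_id) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  lines <- readLines(path)
  cols <- c("chrom", "intron_start", "intron_end", "strand_code",
            "motif_code", "annotated", "unique_reads", "multi_reads",
            "max_overhang")
  empty <- stats::setNames(
    data.frame(character(), integer(), integer(), integer(), integer(),
               integer(), integer(), integer(), integer(),
               stringsAsFactors = FALSE),
    cols
  )
  if (length(lines) == 0) {
    empty$sample_id <- character()
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad) > 0) {
    stop("malformed junction row at line ", bad[1], " of ", path,
         ": expected 9 tab-separated fields, found ", lengths(fields)[bad[1]])
  }
  mat <- do.call(rbind, fields)
  ints <- suppressWarnings(
    apply(mat[, 2:9, drop = FALSE], 2, as.integer)
  )
  if (length(lines) == 1) ints <- matrix(ints, nrow = 1)
  bad_int <- which(apply(ints, 1, anyNA))
  if (length(bad_int) > 0) {
    stop("malformed junction row at line ", bad_int[1], " of ", path,
         ": non-integer coordinate or count")
  }
  out <- data.frame(
    chrom = mat[, 1],
    intron_start = ints[, 1], intron_end = ints[, 2],
    strand_code = ints[, 3], motif_code = ints[, 4], annotated = ints[, 5],
    unique_reads = ints[, 6], multi_reads = ints[, 7],
    max_overhang = ints[, 8],
    stringsAsFactors = FALSE
  )
  if (any(out$intron_start > out$intron_end)) {
    stop("junction with intron_start > intron_end in ", path)
  }
  if (any(out$unique_reads < 0) || any(out$multi_reads < 0)) {
    stop("negative read count in ", path)
  }
  out$sample_id <- sample_id
  out
}

#' Write junctions in STAR SJ.out.tab format
#'
#' Inverse of [parse_star_sj()]; used by the synthetic-data generators and
#' for round-trip checks.
#'
#' @param junctions Data frame with the columns produced by
#'   [parse_star_sj()] (the `sample_id` column is ignored if present).
#' @param path Output path.
#' @export
write_star_sj <- function(junctions, path) {
  cols <- c("chrom", "intron_start", "intron_end", "strand_code",
            "motif_code", "annotated", "unique_reads", "multi_reads",
            "max_overhang")
  utils::write.table(junctions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Merge per-sample junction lists into one junction table
#'
#' Junctions are keyed by (chromosome, intron start, intron end); a strand
#' disagreement between samples for the same coordinates is an error.
#' Samples in which a junction was not reported get a zero count. Only
#' uniquely-mapping reads are carried into the count matrix.
#'
#' @param junction_list List of data frames from [parse_star_sj()], each
#'   with a `sample_id` column.
#' @return A junction table: list with `meta` (data frame `chrom`,
#'   `intron_start`, `intron_end`, `strand_code`, `motif_code`, `annotated`)
#'   and `counts` (integer matrix, junctions x samples, unique reads).
#' @export
merge_samples <- function(junction_list) {
  all_j <- do.call(rbind, junction_list)
  if (is.null(all_j) || nrow(all_j) == 0) {
    stop("no junctions to merge")
  }
  samples <- unique(all_j$sample_id)
  key <- paste(all_j$chrom, all_j$intron_start, all_j$intron_end, sep = ":")
  ukey <- unique(key)
  idx <- match(key, ukey)

  strands <- tapply(all_j$strand_code, idx, function(s) length(unique(s)))
  if (any(strands > 1)) {
    first_bad <- ukey[as.integer(names(strands)[strands > 1])[1]]
    stop("strand conflict between samples for junction ", first_bad)
  }

  first <- !duplicated(idx)
  meta <- data.frame(
    chrom = all_j$chrom[first],
    intron_start = all_j$intron_start[first],
    intron_end = all_j$intron_end[first],
    strand_code = all_j$strand_code[first],
    motif_code = all_j$motif_code[first],
    annotated = all_j$annotated[first],
    stringsAsFactors = FALSE
  )[order(unique(idx)), , drop = FALSE]
  o <- order(meta$chrom, meta$intron_start, meta$intron_end)
  meta <- meta[o, , drop = FALSE]
  rownames(meta) <- NULL

  counts <- matrix(0L, nrow = nrow(meta), ncol = length(samples),
                   dimnames = list(NULL, samples))
  meta_key <- paste(meta$chrom, meta$intron_start, meta$intron_end, sep = ":")
  row_of <- match(key, meta_key)
  col_of <- match(all_j$sample_id, samples)
  for (i in seq_len(nrow(all_j))) {
    counts[row_of[i], col_of[i]] <- counts[row_of[i], col_of[i]] +
      all_j$unique_reads[i]
  }
  list(meta = meta, counts = counts)
}

#' Find alternative junction pairs
#'
#' Two junctions on the same chromosome form an alternative pair when they
#' share exactly their start coordinate (same donor side, different
#' acceptors) or exactly their end coordinate. When more than two junctions
#' share a site, every pair among them is emitted. Within a pair, `j1` is
#' the junction with the smaller non-shared coordinate, fixing the direction
#' of the usage ratio.
#'
#' @param jt Junction table from [merge_samples()].
#' @return Data frame with one row per pair: `pair_id`, `shared_site`
#'   (`shared_start` or `shared_end`), `chrom`, `j1`/`j2` row indices into
#'   `jt$meta`, the four junction coordinates, and `strand_code`.
#' @export
find_alternative_pairs <- function(jt) {
  meta <- jt$meta
  emit <- function(groups, shared) {
    gs <- groups[lengths(groups) >= 2]
    if (length(gs) == 0) return(NULL)
    cmb <- do.call(cbind, lapply(gs, function(g) utils::combn(g, 2)))
    i <- cmb[1, ]; j <- cmb[2, ]
    # j1 carries the smaller non-shared coordinate
    swap <- if (shared == "shared_start") {
      meta$intron_end[i] > meta$intron_end[j]
    } else {
      meta$intron_start[i] > meta$intron_start[j]
    }
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    data.frame(
      shared_site = shared, chrom = meta$chrom[i],
      j1 = i, j2 = j,
      j1_start = meta$intron_start[i], j1_end = meta$intron_end[i],
      j2_start = meta$intron_start[j], j2_end = meta$intron_end[j],
      strand_code = meta$strand_code[i],
      stringsAsFactors = FALSE
    )
  }
  by_start <- split(seq_len(nrow(meta)),
                    paste(meta$chrom, meta$intron_start, sep = ":"))
  by_end <- split(seq_len(nrow(meta)),
                  paste(meta$chrom, meta$intron_end, sep = ":"))
  rows <- Filter(Negate(is.null),
                 list(emit(by_start, "shared_start"),
                      emit(by_end, "shared_end")))
  if (length(rows) == 0) {
    return(data.frame(
      pair_id = character(), shared_site = character(), chrom = character(),
      j1 = integer(), j2 = integer(),
      j1_start = integer(), j1_end = integer(),
      j2_start = integer(), j2_end = integer(),
      strand_code = integer(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$pair_id <- paste0(out$chrom, ":", out$j1_start, "-", out$j1_end, "|",
                        out$j2_start, "-", out$j2_end, ":", out$shared_site)
  o <- order(out$chrom, out$j1_start, out$j1_end, out$j2_start, out$j2_end,
             out$shared_site)
  out <- out[o, c("pair_id", "shared_site", "chrom", "j1", "j2",
                  "j1_start", "j1_end", "j2_start", "j2_end", "strand_code")]
  rownames(out) <- NULL
  out
}

#' Filter alternative pairs by total read support
#'
#' Keeps a pair when the two junctions' unique read counts summed over all
#' samples reach `min_total` (default 30, boundary inclusive).
#'
#' @param pairs Pairs from [find_alternative_pairs()].
#' @param jt Junction table from [merge_samples()].
#' @param min_total Minimum total count across all samples.
#' @return The filtered pairs data frame.
#' @export
filter_min_counts <- function(pairs, jt, min_total = 30) {
  if (nrow(pairs) == 0) return(pairs)
  total <- rowSums(jt$counts[pairs$j1, , drop = FALSE]) +
    rowSums(jt$counts[pairs$j2, , drop = FALSE])
  out <- pairs[total >= min_total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative junction usage
#'
#' The fraction of reads supporting junction 1 of an alternative pair,
#' `c1 / (c1 + c2)`; `NA` when neither junction has reads.
#'
#' @param c1,c2 Non-negative read counts. Vectorised.
#' @return Usage in `[0, 1]`, or `NA` where `c1 + c2 == 0`.
#' @export
relative_usage <- function(c1, c2) {
  if (any(is.na(c1)) || any(is.na(c2)) || any(c1 < 0) || any(c2 < 0)) {
    stop("counts must be non-negative")
  }
  total <- c1 + c2
  ifelse(total > 0, c1 / total, NA_real_)
}

#' Differential junction usage between two genotypes
#'
#' Pools replicate counts within each genotype, applies a two-sided Fisher
#' exact test to the 2x2 table of (junction 1, junction 2) counts in
#' genotype A versus genotype B, and Bonferroni-corrects over the pairs
#' tested in this comparison. Pairs with zero pooled counts in either
#' genotype are flagged untestable (`NA` p-values, never significant).
#'
#' @param pairs Count-filtered pairs from [filter_min_counts()].
#' @param jt Junction table from [merge_samples()].
#' @param samples_a,samples_b Column names of `jt$counts` belonging to the
#'   two genotypes.
#' @param alpha Bonferroni-adjusted significance threshold (default 0.05).
#' @param m_tests Bonferroni family size; defaults to `nrow(pairs)`.
#' @return `pairs` with appended columns `c1_a`, `c2_a`, `c1_b`, `c2_b`,
#'   `u_a`, `u_b`, `delta_u` (`u_b - u_a`), `p_raw`, `p_adj`, `untestable`,
#'   `significant`.
#' @export
differential_usage <- function(pairs, jt, samples_a, samples_b,
                               alpha = 0.05, m_tests = nrow(pairs)) {
  if (nrow(pairs) == 0) stop("no pairs to test")
  if (m_tests < 1) stop("'m_tests' must be a positive integer")
  stopifnot(all(samples_a %in% colnames(jt$counts)),
            all(samples_b %in% colnames(jt$counts)))
  c1_a <- rowSums(jt$counts[pairs$j1, samples_a, drop = FALSE])
  c2_a <- rowSums(jt$counts[pairs$j2, samples_a, drop = FALSE])
  c1_b <- rowSums(jt$counts[pairs$j1, samples_b, drop = FALSE])
  c2_b <- rowSums(jt$counts[pairs$j2, samples_b, drop = FALSE])

  untestable <- (c1_a + c2_a) == 0 | (c1_b + c2_b) == 0
  p_raw <- rep(NA_real_, nrow(pairs))
  for (i in which(!untestable)) {
    p_raw[i] <- fisher_exact_two_sided(c1_a[i], c2_a[i], c1_b[i], c2_b[i])
  }
  p_adj <- ifelse(is.na(p_raw), NA_real_, pmin(1, p_raw * m_tests))

  out <- pairs
  out$c1_a <- c1_a; out$c2_a <- c2_a; out$c1_b <- c1_b; out$c2_b <- c2_b
  out$u_a <- relative_usage(c1_a, c2_a)
  out$u_b <- relative_usage(c1_b, c2_b)
  out$delta_u <- out$u_b - out$u_a
  out$p_raw <- p_raw
  out$p_adj <- p_adj
  out$untestable <- untestable
  out$significant <- !is.na(p_adj) & p_adj < alpha
  out
}

#' Classify alternative-splicing event types from junction context
#'
#' A pair is a cassette exon when its longer junction (the skipping
#' junction) spans an inclusion chain: some junction shares the long
#' junction's start and ends before another junction that shares the long
#' junction's end begins — the enclosed segment is the cassette exon.
#' Otherwise a shared-start pair is an alternative 3' splice site on the
#' plus strand (alternative 5' on the minus strand) and a shared-end pair
#' the converse. Junctions with undefined strand are classified under
#' plus-strand conventions and flagged low confidence.
#'
#' @param pairs Pairs from [find_alternative_pairs()].
#' @param jt Junction table from [merge_samples()] giving the full junction
#'   context.
#' @return `pairs` with appended columns `class` (one of `cassette_exon`,
#'   `alt_5prime_ss`, `alt_3prime_ss`, `other`) and `low_confidence`.
#' @export
classify_event <- function(pairs, jt) {
  meta <- jt$meta
  n <- nrow(pairs)
  cls <- character(n)
  lowconf <- pairs$strand_code == 0
  for (i in seq_len(n)) {
    span1 <- pairs$j1_end[i] - pairs$j1_start[i]
    span2 <- pairs$j2_end[i] - pairs$j2_start[i]
    if (span1 == span2) { cls[i] <- "other"; next }
    long <- if (span1 > span2) pairs$j1[i] else pairs$j2[i]
    Ls <- meta$intron_start[long]; Le <- meta$intron_end[long]
    on_chrom <- meta$chrom == meta$chrom[long]
    inc1_ends <- meta$intron_end[on_chrom & meta$intron_start == Ls &
                                   meta$intron_end < Le]
    inc2_starts <- meta$intron_start[on_chrom & meta$intron_end == Le &
                                       meta$intron_start > Ls]
    if (length(inc1_ends) > 0 && length(inc2_starts) > 0 &&
        min(inc1_ends) < max(inc2_starts)) {
      cls[i] <- "cassette_exon"
      next
    }
    minus <- pairs$strand_code[i] == 2
    if (pairs$shared_site[i] == "shared_start") {
      cls[i] <- if (minus) "alt_5prime_ss" else "alt_3prime_ss"
    } else {
      cls[i] <- if (minus) "alt_3prime_ss" else "alt_5prime_ss"
    }
  }
  out <- pairs
  out$class <- cls
  out$low_confidence <- lowconf
  out
}

#' Compare the event-class distribution with a reference
#'
#' Tabulates observed event-class fractions next to externally supplied
#' reference proportions (e.g. genome-wide alternative-splicing frequencies)
#' and tests goodness of fit with a chi-square test.
#'
#' @param classes Character vector of event classes.
#' @param reference_proportions Named numeric vector of reference fractions
#'   over the same class labels; must sum to 1 (tolerance 1e-6).
#' @return A list with `table` (class, n, observed fraction, reference
#'   fraction) and `p_chisq`.
#' @export
event_class_distribution <- function(classes, reference_proportions) {
  if (abs(sum(reference_proportions) - 1) > 1e-6) {
    stop("reference proportions must sum to 1")
  }
  lvls <- names(reference_proportions)
  unknown <- setdiff(unique(classes), lvls)
  if (length(unknown) > 0) {
    stop("classes without a reference proportion: ",
         paste(unknown, collapse = ", "))
  }
  n <- table(factor(classes, levels = lvls))
  tab <- data.frame(
    class = lvls,
    n = as.integer(n),
    observed = as.numeric(n) / length(classes),
    reference = as.numeric(reference_proportions),
    stringsAsFactors = FALSE
  )
  p <- suppressWarnings(
    stats::chisq.test(as.integer(n), p = reference_proportions)$p.value
  )
  list(table = tab, p_chisq = p)
}

#' Per-sample usage matrix for significant pairs, ordered by K-means cluster
#'
#' Builds the relative-usage matrix (rows = significant junction pairs,
#' columns = samples), clusters the rows with [kmeans_cluster()], and
#' returns the matrix with rows reordered by cluster label. Samples in which
#' a pair has no reads get the pair's mean usage over the remaining samples
#' so that clustering sees a complete matrix.
#'
#' @param pairs_sig Significant pairs (rows of a [differential_usage()]
#'   result with `significant == TRUE`).
#' @param jt Junction table from [merge_samples()].
#' @param samples Column names of `jt$counts` to include, in display order.
#' @param k,runs,seed Clustering parameters passed to [kmeans_cluster()]
#'   (defaults 10 clusters, 1000 restarts).
#' @return A list with `matrix` (usage values, rows ordered by cluster),
#'   `labels` (cluster index per row of `matrix`), `inertia`.
#' @export
usage_heatmap_matrix <- function(pairs_sig, jt, samples, k = 10, runs = 1000,
                                 seed = 1) {
  if (nrow(pairs_sig) == 0) stop("no significant pairs to cluster")
  if (k > nrow(pairs_sig)) {
    stop("'k' (", k, ") exceeds the number of significant pairs (",
         nrow(pairs_sig), ")")
  }
  c1 <- jt$counts[pairs_sig$j1, samples, drop = FALSE]
  c2 <- jt$counts[pairs_sig$j2, samples, drop = FALSE]
  u <- c1 / (c1 + c2)
  rownames(u) <- pairs_sig$pair_id
  # impute empty-sample cells with the pair's mean usage elsewhere
  for (i in seq_len(nrow(u))) {
    miss <- is.na(u[i, ])
    if (any(miss)) u[i, miss] <- mean(u[i, !miss])
  }
  cl <- kmeans_cluster(u, k = k, runs = runs, seed = seed)
  o <- order(cl$labels)
  list(matrix = u[o, , drop = FALSE], labels = cl$labels[o],
       inertia = cl$inertia)
}

#' Full differential-usage pipeline from a sample sheet
#'
#' Parses every sample's STAR junction file, merges them, enumerates
#' alternative pairs, applies the minimum-count filter, tests differential
#' usage between two genotypes and classifies event types.
#'
#' @param sample_sheet Data frame with columns `sample_id`, `genotype_id`,
#'   `replicate_id`, `path`.
#' @param genotype_a,genotype_b The two genotypes to compare.
#' @param min_total Minimum pair count across all samples (default 30).
#' @param alpha Bonferroni-adjusted significance threshold (default 0.05).
#' @return A list with `results` (classified [differential_usage()] table),
#'   `jt` (the merged junction table), and `samples_a`/`samples_b`.
#' @export
differential_junction_usage <- function(sample_sheet, genotype_a, genotype_b,
                                        min_total = 30, alpha = 0.05) {
  required <- c("sample_id", "genotype_id", "replicate_id", "path")
  if (!all(required %in% names(sample_sheet))) {
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  }
  jlist <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    parse_star_sj(sample_sheet$path[i], sample_sheet$sample_id[i])
  })
  jt <- merge_samples(jlist)
  pairs <- find_alternative_pairs(jt)
  pairs <- filter_min_counts(pairs, jt, min_total)
  samples_a <- sample_sheet$sample_id[sample_sheet$genotype_id == genotype_a]
  samples_b <- sample_sheet$sample_id[sample_sheet$genotype_id == genotype_b]
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    stop("genotype not present in the sample sheet")
  }
  res <- differential_usage(pairs, jt, samples_a, samples_b, alpha = alpha)
  res <- classify_event(res, jt)
  list(results = res, jt = jt, samples_a = samples_a, samples_b = samples_b)
}
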