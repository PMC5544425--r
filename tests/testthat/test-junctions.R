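test_that("STAR junction files parse field-by-field and round-trip", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines("I\t1001\t1100\t1\t1\t1\t57\t3\t38", path)
  j <- parse_star_sj(path, "s1")
  expect_equal(j$chrom, "I")
  expect_equal(j$intron_start, 1001L)
  expect_equal(j$intron_end, 1100L)
  expect_equal(j$strand_code, 1L)
  expect_equal(j$unique_reads, 57L)
  expect_equal(j$sample_id, "s1")

  # empty file -> empty frame
  writeLines(character(), path)
  expect_equal(nrow(parse_star_sj(path, "s1")), 0)

  # write -> parse identity on a 3-junction fixture
  trio <- make_trio_junctions()$j1[1:3, ]
  write_star_sj(trio, path)
  back <- parse_star_sj(path, "s1")
  cols <- c("chrom", "intron_start", "intron_end", "strand_code",
            "motif_code", "annotated", "unique_reads", "multi_reads",
            "max_overhang")
  expect_equal(back[, cols], trio[, cols], ignore_attr = TRUE)
})

test_that("malformed junction rows fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("I\t1\t100\t1\t1\t1\t5\t0\t20", "I\t200\t300\t1\t1"), path)
  expect_error(parse_star_sj(path, "s"), "line 2")
  writeLines("I\t1\tX\t1\t1\t1\t5\t0\t20", path)
  expect_error(parse_star_sj(path, "s"), "line 1")
})

test_that("merging registers counts per sample and fills zeros", {
  jl <- make_trio_junctions()
  jt <- merge_samples(list(jl$j1, jl$j2))
  expect_equal(nrow(jt$meta), 5)
  expect_equal(colnames(jt$counts), c("s1", "s2"))

  # disjoint junction sets union with zeros
  a <- jl$j1[1, ]; b <- jl$j2[2, ]
  jt2 <- merge_samples(list(a, b))
  expect_equal(nrow(jt2$meta), 2)
  expect_equal(sum(jt2$counts == 0), 2)

  # strand conflict for identical coordinates
  bad <- jl$j2; bad$strand_code <- 2L
  expect_error(merge_samples(list(jl$j1, bad)), "strand conflict")
})

test_that("alternative pairs share exactly one coordinate", {
  jl <- make_trio_junctions()
  jt <- merge_samples(list(jl$j1, jl$j2))
  pairs <- find_alternative_pairs(jt)
  # trio: shared-start and shared-end pair; alt pair: one shared-start
  expect_equal(sum(pairs$shared_site == "shared_start"), 2)
  expect_equal(sum(pairs$shared_site == "shared_end"), 1)
  # j1 carries the smaller non-shared coordinate
  ss <- pairs[pairs$shared_site == "shared_start", ]
  expect_true(all(ss$j1_end < ss$j2_end))
  se <- pairs[pairs$shared_site == "shared_end", ]
  expect_true(all(se$j1_start < se$j2_start))

  # three junctions sharing one start emit all three pairs
  tri <- data.frame(
    chrom = "II", intron_start = 100L, intron_end = c(200L, 300L, 400L),
    strand_code = 1L, motif_code = 1L, annotated = 1L,
    unique_reads = 10L, multi_reads = 0L, max_overhang = 30L,
    sample_id = "s1", stringsAsFactors = FALSE
  )
  p3 <- find_alternative_pairs(merge_samples(list(tri)))
  expect_equal(nrow(p3), 3)

  # output independent of input row order
  shuf <- merge_samples(list(jl$j1[c(4, 2, 5, 1, 3), ], jl$j2))
  expect_equal(find_alternative_pairs(shuf)$pair_id, pairs$pair_id)
})

test_that("the 30-count filter is boundary-inclusive over all samples", {
  mk <- function(c1, c2) {
    j <- data.frame(
      chrom = "I", intron_start = 10L, intron_end = c(50L, 90L),
      strand_code = 1L, motif_code = 1L, annotated = 1L,
      unique_reads = as.integer(c(c1, c2)), multi_reads = 0L,
      max_overhang = 30L, sample_id = "s1", stringsAsFactors = FALSE
    )
    jt <- merge_samples(list(j))
    filter_min_counts(find_alternative_pairs(jt), jt, 30)
  }
  expect_equal(nrow(mk(20, 10)), 1)   # total 30: kept
  expect_equal(nrow(mk(20, 9)), 0)    # total 29: dropped
  expect_equal(nrow(mk(0, 0)), 0)
})

test_that("relative usage handles zeros and scale", {
  expect_equal(relative_usage(30, 10), 0.75)
  expect_equal(relative_usage(0, 10), 0)
  expect_true(is.na(relative_usage(0, 0)))
  expect_error(relative_usage(-1, 5), "non-negative")
  # scale invariance of u; p-value can only sharpen with more reads
  expect_equal(relative_usage(30, 10), relative_usage(300, 100))
  p_small <- fisher_exact_two_sided(30, 10, 10, 30)
  p_big <- fisher_exact_two_sided(300, 100, 100, 300)
  expect_lt(p_big, p_small)
})

test_that("differential usage tests pooled group counts", {
  jl <- make_trio_junctions()
  jt <- merge_samples(list(jl$j1, jl$j2))
  pairs <- filter_min_counts(find_alternative_pairs(jt), jt, 30)
  du <- differential_usage(pairs, jt, "s1", "s2", alpha = 0.05)
  expect_true(all(du$delta_u >= -1 & du$delta_u <= 1, na.rm = TRUE))
  expect_equal(du$p_adj, pmin(1, du$p_raw * nrow(du)))

  # identical pooled proportions -> p = 1 (up to summation round-off)
  du_same <- differential_usage(pairs, jt, c("s1", "s2"), c("s1", "s2"))
  expect_equal(du_same$p_raw, rep(1, nrow(du_same)))
  expect_false(any(du_same$significant))

  # complete usage switch: tail mass 2 / C(200,100), frozen from lchoose
  p <- fisher_exact_two_sided(100, 0, 0, 100)
  expect_equal(p, 2.2087606932e-59, tolerance = 1e-9)
  expect_equal(p, exp(log(2) - lchoose(200, 100)), tolerance = 1e-12)
})

test_that("event classification follows the junction-chain rule", {
  jl <- make_trio_junctions()
  jt <- merge_samples(list(jl$j1, jl$j2))
  pairs <- classify_event(find_alternative_pairs(jt), jt)
  trio <- pairs[pairs$j1_start >= 1001 & pairs$j1_end <= 1300, ]
  expect_true(all(trio$class == "cassette_exon"))
  lone <- pairs[pairs$j1_start == 5001, ]
  expect_equal(lone$class, "alt_3prime_ss")   # shared donor on plus strand

  # lone shared-end pair on plus strand is an alternative 5' site
  se <- data.frame(
    chrom = "III", intron_start = c(100L, 250L), intron_end = 400L,
    strand_code = 1L, motif_code = 1L, annotated = 1L,
    unique_reads = 20L, multi_reads = 0L, max_overhang = 30L,
    sample_id = "s1", stringsAsFactors = FALSE
  )
  jt_se <- merge_samples(list(se))
  cls <- classify_event(find_alternative_pairs(jt_se), jt_se)
  expect_equal(cls$class, "alt_5prime_ss")

  # minus strand flips the splice-site assignment
  se$strand_code <- 2L
  jt_m <- merge_samples(list(se))
  expect_equal(classify_event(find_alternative_pairs(jt_m), jt_m)$class,
               "alt_3prime_ss")

  # undefined strand: plus-strand convention with a low-confidence flag
  se$strand_code <- 0L
  jt_0 <- merge_samples(list(se))
  cls0 <- classify_event(find_alternative_pairs(jt_0), jt_0)
  expect_equal(cls0$class, "alt_5prime_ss")
  expect_true(cls0$low_confidence)
})

test_that("event-class distribution compares against a reference", {
  ref <- c(cassette_exon = 0.4, alt_5prime_ss = 0.3, alt_3prime_ss = 0.3)
  obs <- rep(names(ref), times = c(40, 30, 30))
  d <- event_class_distribution(obs, ref)
  expect_equal(d$table$observed, d$table$reference)
  expect_gt(d$p_chisq, 0.99)

  d2 <- event_class_distribution(rep("cassette_exon", 10), ref)
  expect_equal(d2$table$observed[d2$table$class == "cassette_exon"], 1)

  expect_error(event_class_distribution(obs, ref * 0.5), "sum to 1")
})

test_that("usage heatmap matrix clusters planted archetypes", {
  sc <- splicing_scenario(n_cassette = 0, n_alt5 = 30, n_alt3 = 30,
                          n_diff = 0, depth = 300, seed = 21)
  sim <- simulate_junction_counts(sc)
  # overwrite psi into two archetypes: low vs high usage
  jt <- sim$jt
  pairs <- filter_min_counts(find_alternative_pairs(jt), jt, 30)
  du <- differential_usage(pairs, jt, colnames(jt$counts)[1:3],
                           colnames(jt$counts)[4:6])
  du$significant <- TRUE  # cluster all pairs regardless of the test
  # plant archetypes directly in the counts
  half <- seq_len(nrow(du)) <= nrow(du) / 2
  jt$counts[du$j1[half], ] <- 270L
  jt$counts[du$j2[half], ] <- 30L
  jt$counts[du$j1[!half], ] <- 30L
  jt$counts[du$j2[!half], ] <- 270L
  hm <- usage_heatmap_matrix(du, jt, colnames(jt$counts), k = 2, runs = 20,
                             seed = 3)
  expect_equal(dim(hm$matrix), c(nrow(du), 6))
  expect_equal(length(unique(hm$labels)), 2)
  # rows are ordered by cluster label
  expect_true(!is.unsorted(hm$labels))
  # archetypes separate perfectly
  row_mean <- rowMeans(hm$matrix)
  expect_true(all(tapply(row_mean > 0.5, hm$labels, function(z) {
    length(unique(z)) == 1
  })))
  # deterministic under a fixed seed
  hm2 <- usage_heatmap_matrix(du, jt, colnames(jt$counts), k = 2, runs = 20,
                              seed = 3)
  expect_identical(hm$labels, hm2$labels)

  expect_error(usage_heatmap_matrix(du[1:3, ], jt, colnames(jt$counts),
                                    k = 10, runs = 5, seed = 1), "exceeds")
})
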