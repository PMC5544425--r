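# Independent oracles and small fixture builders shared across test files.

# Exhaustive two-sided Fisher p by direct factorial arithmetic: enumerate
# every table with the observed margins and sum the probabilities of tables
# no more probable than the observed one (same tie tolerance as the
# implementation, but probabilities computed from lchoose, not dhyper).
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, r1 - (n - c1))
  hi <- min(r1, c1)
  logp <- vapply(lo:hi, function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }, numeric(1))
  lobs <- lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)
  min(1, sum(exp(logp[logp <= lobs + log(1 + 1e-7)])))
}

# Brute-force overlapping k-mer counting by sliding a window.
count_kmers_brute <- function(sequence, motifs) {
  k <- nchar(motifs[1])
  n <- nchar(sequence)
  if (n < k) return(0L)
  windows <- substring(sequence, 1:(n - k + 1), k:n)
  sum(windows %in% motifs)
}

# A three-junction cassette trio plus a lone alt-SS pair, as parsed
# per-sample junction frames for two samples.
make_trio_junctions <- function(counts1 = c(50, 50, 50, 30, 20),
                                counts2 = c(40, 40, 60, 25, 25)) {
  base <- data.frame(
    chrom = "I",
    intron_start = c(1001L, 1001L, 1201L, 5001L, 5001L),
    intron_end = c(1100L, 1300L, 1300L, 5200L, 5350L),
    strand_code = 1L, motif_code = 1L, annotated = 1L,
    multi_reads = 0L, max_overhang = 40L,
    stringsAsFactors = FALSE
  )
  j1 <- base; j1$unique_reads <- as.integer(counts1); j1$sample_id <- "s1"
  j2 <- base; j2$unique_reads <- as.integer(counts2); j2$sample_id <- "s2"
  list(j1 = j1, j2 = j2)
}

# Hand-built 2 kb plus/minus gene pair for region-extraction oracles:
# returns genome string, annotation rows, and the 0-based half-open
# coordinates of each feature.
make_toy_gene <- function(seed = 42) {
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
  coords <- list(
    ue = c(100, 200), ui = c(200, 500), ca = c(500, 580),
    di = c(580, 900), de = c(900, 1000)
  )
  ann_plus <- data.frame(
    chrom = "chrT",
    start = vapply(coords, `[`, numeric(1), 1),
    end = vapply(coords, `[`, numeric(1), 2),
    strand = "+", event_id = "evP",
    region = c("upstream_exon", "upstream_intron", "cassette_exon",
               "downstream_intron", "downstream_exon"),
    stringsAsFactors = FALSE
  )
  ann_minus <- ann_plus
  ann_minus$strand <- "-"
  ann_minus$event_id <- "evM"
  # transcript orientation flips on the minus strand
  ann_minus$region <- rev(ann_plus$region)
  list(genome = genome, coords = coords,
       annotation = rbind(ann_plus, ann_minus))
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
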