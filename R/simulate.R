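#' Competition-screen scenario
#'
#' Describes an in-silico all-against-all competitive-fitness screen: the
#' true relative fitness of each single mutant, the pairs carrying a
#' planted synthetic effect, and the plate design. Defaults describe a
#' 13-gene screen (78 double mutants) with three aggravating interactions
#' of epsilon -0.4 planted among wild-type-fit singles. Doubles get three
#' plates of 200 worms (600 pooled); singles get six plates: each
#' single-mutant estimate enters every expected-fitness product of its 12
#' pairs, so the screen design measures the few singles at twice the depth
#' of any one double.
#'
#' @param genes Gene labels.
#' @param fitness Named numeric vector of true single-mutant fitness
#'   values in `[0, 2]`.
#' @param interactions Data frame `gene_a`, `gene_b`, `epsilon` of planted
#'   synthetic effects; unlisted pairs follow the multiplicative null.
#' @param plates_singles Biological replicates per single mutant.
#' @param plates_doubles Biological replicates per double mutant.
#' @param worms_per_plate Worms counted per plate.
#' @param seed Integer seed.
#' @return A list of class `competition_scenario`.
#' @export
competition_scenario <- function(genes = sprintf("g%02d", 1:13),
                                 fitness = stats::setNames(rep(1, length(genes)), genes),
                                 interactions = data.frame(
                                   gene_a = genes[c(1, 3, 5)],
                                   gene_b = genes[c(2, 4, 6)],
                                   epsilon = rep(-0.4, 3),
                                   stringsAsFactors = FALSE
                                 ),
                                 plates_singles = 6,
                                 plates_doubles = 3,
                                 worms_per_plate = 200,
                                 seed = 1) {
  if (anyDuplicated(genes)) stop("gene labels must be distinct")
  if (!all(genes %in% names(fitness))) stop("every gene needs a fitness value")
  if (any(fitness < 0) || any(fitness > 2)) stop("fitness must lie in [0, 2]")
  structure(
    list(genes = genes, fitness = fitness, interactions = interactions,
         plates_singles = plates_singles, plates_doubles = plates_doubles,
         worms_per_plate = worms_per_plate, seed = seed),
    class = "competition_scenario"
  )
}

#' Simulate competition plates for a full screen
#'
#' Every single mutant gets `plates_singles` plates and every unordered
#' double mutant `plates_doubles` plates; on each plate the mutant count
#' is a binomial draw with success probability `F_true / 2` (the plate
#' fraction implied by the true fitness). Double-mutant truth is
#' `F1 * F2 + epsilon` for planted pairs and `F1 * F2` otherwise.
#'
#' @param scenario A [competition_scenario()].
#' @return A list with `plates` (the plate table consumed by
#'   [sgi_screen()]) and `truth` (per-double true fitness and epsilon).
#' @export
simulate_competition <- function(scenario) {
  stopifnot(inherits(scenario, "competition_scenario"))
  set.seed(as.integer(scenario$seed))
  pairs <- enumerate_pairs(scenario$genes)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  planted <- stats::setNames(
    scenario$interactions$epsilon,
    key(scenario$interactions$gene_a, scenario$interactions$gene_b)
  )
  eps <- planted[key(pairs$gene_a, pairs$gene_b)]
  eps[is.na(eps)] <- 0
  f_true_dbl <- scenario$fitness[pairs$gene_a] * scenario$fitness[pairs$gene_b] + eps
  if (any(f_true_dbl < 0) || any(f_true_dbl > 2)) {
    stop("planted epsilon implies a double-mutant fitness outside [0, 2]")
  }

  genotypes <- c(scenario$genes, paste(pairs$gene_a, pairs$gene_b, sep = ";"))
  f_true <- c(scenario$fitness[scenario$genes], f_true_dbl)
  n_plates <- c(rep(scenario$plates_singles, length(scenario$genes)),
                rep(scenario$plates_doubles, nrow(pairs)))

  rows <- list()
  for (g in seq_along(genotypes)) {
    for (r in seq_len(n_plates[g])) {
      rows[[length(rows) + 1]] <- data.frame(
        genotype_id = genotypes[g],
        replicate_id = paste0("r", r),
        mutant_count = stats::rbinom(1, scenario$worms_per_plate, f_true[g] / 2),
        total_count = scenario$worms_per_plate,
        stringsAsFactors = FALSE
      )
    }
  }
  plates <- do.call(rbind, rows)
  truth <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    f_true = f_true_dbl, epsilon_true = eps,
    stringsAsFactors = FALSE
  )
  list(plates = plates, truth = truth)
}

#' Splicing-simulation scenario
#'
#' Describes a toy transcriptome of cassette-exon trios and alternative
#' splice-site pairs with per-genotype inclusion levels, sequencing depth
#' per event per sample, and replicate structure. Defaults give 500
#' testable junction pairs (100 cassette trios contributing two pairs
#' each, plus 150 alternative 5' and 150 alternative 3' pairs), three
#' replicates per genotype at depth 200, with 50 cassette events planted
#' differential at `|delta_psi| = 0.4` (25 in each direction).
#'
#' Baseline inclusion levels are drawn uniformly per event; planted events
#' shift exactly by `delta_psi` between genotypes.
#'
#' @param n_cassette,n_alt5,n_alt3 Event counts per class.
#' @param n_diff Number of planted differential cassette events (split
#'   evenly between increased and decreased inclusion). Zero gives a null
#'   scenario.
#' @param delta_psi Planted inclusion difference.
#' @param depth Reads per event per sample.
#' @param replicates Biological replicates per genotype.
#' @param genotypes Two genotype labels.
#' @param seed Integer seed.
#' @return A list of class `splicing_scenario`.
#' @export
splicing_scenario <- function(n_cassette = 100, n_alt5 = 150, n_alt3 = 150,
                              n_diff = 50, delta_psi = 0.4, depth = 200,
                              replicates = 3, genotypes = c("WT", "mut"),
                              seed = 1) {
  if (n_diff > n_cassette) stop("'n_diff' cannot exceed 'n_cassette'")
  if (delta_psi < 0 || delta_psi > 0.9) stop("'delta_psi' must lie in [0, 0.9]")
  if (length(genotypes) != 2) stop("exactly two genotypes are required")
  structure(
    list(n_cassette = n_cassette, n_alt5 = n_alt5, n_alt3 = n_alt3,
         n_diff = n_diff, delta_psi = delta_psi, depth = depth,
         replicates = replicates, genotypes = genotypes, seed = seed),
    class = "splicing_scenario"
  )
}

# fixed layout of the toy transcriptome (bases)
.layout <- list(
  exon_flank = 150, intron = 400, cassette = 120, spacer = 300,
  altss_block = 600, alt_short = 200, alt_long = 350
)

# event geometry: one row per junction, plus the cassette-region table
.splicing_layout <- function(scenario) {
  L <- .layout
  nc <- scenario$n_cassette
  n5 <- scenario$n_alt5
  n3 <- scenario$n_alt3
  block_c <- 2L * L$exon_flank + 2L * L$intron + L$cassette + L$spacer

  # cassette trios, alternating strand
  junctions <- NULL; regions <- NULL; truth <- NULL
  cass_end <- 0L
  if (nc > 0) {
    o <- (seq_len(nc) - 1L) * block_c      # 0-based block offsets
    strand <- ifelse(seq_len(nc) %% 2 == 1, "+", "-")
    id <- sprintf("ev%04d", seq_len(nc))
    ue_s <- o
    ui_s <- ue_s + L$exon_flank
    ca_s <- ui_s + L$intron
    di_s <- ca_s + L$cassette
    de_s <- di_s + L$intron
    de_e <- de_s + L$exon_flank
    junctions <- data.frame(
      event_id = rep(id, each = 3),
      junction = rep(c("inc1", "inc2", "skip"), nc),
      intron_start = as.integer(rbind(ui_s + 1L, di_s + 1L, ui_s + 1L)),
      intron_end = as.integer(rbind(ca_s, de_s, de_s)),
      strand_code = rep(ifelse(strand == "+", 1L, 2L), each = 3),
      stringsAsFactors = FALSE
    )
    labels <- c("upstream_exon", "upstream_intron", "cassette_exon",
                "downstream_intron", "downstream_exon")
    regions <- data.frame(
      chrom = "I",
      start = as.integer(rbind(ue_s, ui_s, ca_s, di_s, de_s)),
      end = as.integer(rbind(ui_s, ca_s, di_s, de_s, de_e)),
      strand = rep(strand, each = 5),
      event_id = rep(id, each = 5),
      # transcript order flips on the minus strand
      region = as.vector(vapply(strand, function(s) {
        if (s == "+") labels else rev(labels)
      }, character(5))),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(event_id = id, class = "cassette_exon",
                        strand = strand, stringsAsFactors = FALSE)
    cass_end <- nc * block_c
  }

  # alternative splice-site pairs, plus strand
  if (n5 + n3 > 0) {
    o <- cass_end + (seq_len(n5 + n3) - 1L) * L$altss_block
    cls <- rep(c("alt_5prime_ss", "alt_3prime_ss"), c(n5, n3))
    id <- sprintf("ev%04d", nc + seq_len(n5 + n3))
    s <- o + 100L
    is5 <- cls == "alt_5prime_ss"
    # alt 3'ss: shared donor (start), two acceptors
    # alt 5'ss: shared acceptor (end), two donors
    j1_start <- s + 1L
    j1_end <- ifelse(is5, s + L$alt_long, s + L$alt_short)
    j2_start <- ifelse(is5, s + (L$alt_long - L$alt_short) + 1L, s + 1L)
    j2_end <- s + L$alt_long
    alt_j <- data.frame(
      event_id = rep(id, each = 2),
      junction = rep(c("j1", "j2"), n5 + n3),
      intron_start = as.integer(rbind(j1_start, j2_start)),
      intron_end = as.integer(rbind(j1_end, j2_end)),
      strand_code = 1L, stringsAsFactors = FALSE
    )
    junctions <- rbind(junctions, alt_j)
    truth <- rbind(truth, data.frame(event_id = id, class = cls,
                                     strand = "+", stringsAsFactors = FALSE))
    cass_end <- cass_end + (n5 + n3) * L$altss_block
  }

  list(
    junctions = junctions,
    regions = regions,
    truth = truth,
    genome_length = cass_end + L$spacer
  )
}

#' Simulate junction count tables in memory
#'
#' Draws per-sample junction counts for the scenario's events: for a
#' cassette event the inclusion reads are a binomial draw
#' `Binomial(depth, psi)` shared by both inclusion junctions and the
#' remainder supports the skipping junction; for an alternative
#' splice-site event the short junction gets the binomial draw. Planted
#' events shift psi by exactly `delta_psi` between the genotypes,
#' alternating direction.
#'
#' @param scenario A [splicing_scenario()].
#' @return A list with `jt` (junction table as from [merge_samples()]),
#'   `sample_sheet` (without paths), `truth` (per event: class, strand,
#'   `psi_a`, `psi_b`, `planted`, `direction`), and `layout` internals.
#' @export
simulate_junction_counts <- function(scenario) {
  stopifnot(inherits(scenario, "splicing_scenario"))
  set.seed(as.integer(scenario$seed))
  lay <- .splicing_layout(scenario)
  truth <- lay$truth
  n_ev <- nrow(truth)

  truth$planted <- FALSE
  truth$direction <- NA_character_
  if (scenario$n_diff > 0) {
    planted_idx <- seq_len(scenario$n_diff)  # first cassette events
    truth$planted[planted_idx] <- TRUE
    truth$direction[planted_idx] <-
      rep(c("up", "down"), length.out = scenario$n_diff)
  }
  d <- scenario$delta_psi
  psi_a <- numeric(n_ev)
  base_null <- stats::runif(n_ev, 0.2, 0.8)
  psi_a <- base_null
  up <- which(truth$planted & truth$direction == "up")
  down <- which(truth$planted & truth$direction == "down")
  psi_a[up] <- stats::runif(length(up), 0.05, 0.95 - d)
  psi_a[down] <- stats::runif(length(down), 0.05 + d, 0.95)
  psi_b <- psi_a
  psi_b[up] <- psi_a[up] + d
  psi_b[down] <- psi_a[down] - d
  truth$psi_a <- psi_a
  truth$psi_b <- psi_b

  samples <- expand.grid(
    replicate_id = paste0("r", seq_len(scenario$replicates)),
    genotype_id = scenario$genotypes,
    stringsAsFactors = FALSE
  )
  samples$sample_id <- paste(samples$genotype_id, samples$replicate_id, sep = "_")
  sample_sheet <- samples[, c("sample_id", "genotype_id", "replicate_id")]

  jmeta <- lay$junctions
  counts <- matrix(0L, nrow = nrow(jmeta), ncol = nrow(sample_sheet),
                   dimnames = list(NULL, sample_sheet$sample_id))
  # junction rows grouped by event in truth order: index each role once
  is_cass <- truth$class == "cassette_exon"
  rows_inc1 <- which(jmeta$junction == "inc1")
  rows_inc2 <- which(jmeta$junction == "inc2")
  rows_skip <- which(jmeta$junction == "skip")
  rows_j1 <- which(jmeta$junction == "j1")
  rows_j2 <- which(jmeta$junction == "j2")
  for (s in seq_len(nrow(sample_sheet))) {
    psi <- if (sample_sheet$genotype_id[s] == scenario$genotypes[1]) {
      truth$psi_a
    } else {
      truth$psi_b
    }
    inc <- stats::rbinom(n_ev, scenario$depth, psi)
    counts[rows_inc1, s] <- inc[is_cass]
    counts[rows_inc2, s] <- inc[is_cass]
    counts[rows_skip, s] <- scenario$depth - inc[is_cass]
    counts[rows_j1, s] <- inc[!is_cass]
    counts[rows_j2, s] <- scenario$depth - inc[!is_cass]
  }

  meta <- data.frame(
    chrom = "I",
    intron_start = jmeta$intron_start, intron_end = jmeta$intron_end,
    strand_code = jmeta$strand_code, motif_code = 1L, annotated = 1L,
    stringsAsFactors = FALSE
  )
  o <- order(meta$intron_start, meta$intron_end)
  list(
    jt = list(meta = meta[o, , drop = FALSE], counts = counts[o, , drop = FALSE]),
    sample_sheet = sample_sheet,
    truth = truth,
    layout = lay
  )
}

#' Simulate STAR junction files on disk
#'
#' Materialises [simulate_junction_counts()] as one `SJ.out.tab` file per
#' sample plus a sample-sheet CSV and a planted-truth TSV, ready for
#' [differential_junction_usage()].
#'
#' @param scenario A [splicing_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `sample_sheet` (including `path`), `truth`, and the
#'   file paths written.
#' @export
simulate_junction_files <- function(scenario, out_dir) {
  sim <- simulate_junction_counts(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$sample_sheet
  sheet$path <- file.path(out_dir, paste0(sheet$sample_id, ".SJ.out.tab"))
  for (s in seq_len(nrow(sheet))) {
    j <- sim$jt$meta
    j$unique_reads <- sim$jt$counts[, sheet$sample_id[s]]
    j$multi_reads <- 0L
    j$max_overhang <- 50L
    write_star_sj(j, sheet$path[s])
  }
  sheet_path <- file.path(out_dir, "samples.csv")
  utils::write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sample_sheet = sheet, truth = sim$truth,
       sheet_path = sheet_path, truth_path = truth_path)
}

#' Simulate a toy genome and cassette-exon annotation
#'
#' Generates a uniform-random genome long enough for the scenario's event
#' layout, together with the BED-like five-region annotation of every
#' cassette event. Junction coordinates of the simulated events fall
#' inside the annotated introns by construction, so region extraction on
#' this genome is exact.
#'
#' @param scenario A [splicing_scenario()].
#' @return A list with `genome` (`DNAStringSet`, one chromosome `I`) and
#'   `annotation` (data frame as from [read_region_annotation()]).
#' @export
simulate_toy_genome <- function(scenario) {
  stopifnot(inherits(scenario, "splicing_scenario"))
  lay <- .splicing_layout(scenario)
  set.seed(as.integer(scenario$seed) + 104729L)  # independent stream
  seq <- paste(sample(c("A", "C", "G", "T"), lay$genome_length,
                      replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "I"))
  list(genome = genome, annotation = lay$regions)
}

#' Write a toy genome and annotation to disk
#'
#' @param toy Result of [simulate_toy_genome()].
#' @param fasta_path,annotation_path Output paths.
#' @export
write_toy_genome <- function(toy, fasta_path, annotation_path) {
  Biostrings::writeXStringSet(toy$genome, fasta_path)
  ann <- toy$annotation
  ann$role <- paste(ann$event_id, ann$region, sep = ":")
  utils::write.table(ann[, c("chrom", "start", "end", "strand", "role")],
                     annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Motif-planting scenario
#'
#' Two groups of random DNA sequences with a 7-mer motif planted at a
#' random position with a group-specific probability. Defaults mirror the
#' motif analysis design: 25 sequences per group, 250 bases each (the
#' proximal intron window).
#'
#' @param n_per_group Sequences per group.
#' @param length Sequence length in bases.
#' @param motifs Character vector of 7-mers to plant and scan for.
#' @param p_regulated,p_control Planting probability per sequence in each
#'   group.
#' @param seed Integer seed.
#' @return A list of class `motif_scenario`.
#' @export
motif_scenario <- function(n_per_group = 25, length = 250,
                           motifs = c("TTTATTT"),
                           p_regulated = 0.75, p_control = 0.15, seed = 1) {
  if (any(nchar(motifs) > length)) stop("motif longer than the sequence")
  if (p_regulated < 0 || p_regulated > 1 || p_control < 0 || p_control > 1) {
    stop("planting probabilities must lie in [0, 1]")
  }
  structure(
    list(n_per_group = n_per_group, length = length, motifs = motifs,
         p_regulated = p_regulated, p_control = p_control, seed = seed),
    class = "motif_scenario"
  )
}

#' Simulate motif-planted sequence groups
#'
#' @param scenario A [motif_scenario()].
#' @return A list with `regulated` and `control` (character vectors of
#'   sequences) and `truth` (data frame `group`, `seq_id`, `planted`).
#' @export
simulate_motif_sequences <- function(scenario) {
  stopifnot(inherits(scenario, "motif_scenario"))
  set.seed(as.integer(scenario$seed))
  draw_group <- function(n, p, group) {
    seqs <- character(n)
    planted <- logical(n)
    for (i in seq_len(n)) {
      s <- sample(c("A", "C", "G", "T"), scenario$length, replace = TRUE)
      if (stats::runif(1) < p) {
        m <- scenario$motifs[sample.int(length(scenario$motifs), 1)]
        pos <- sample.int(scenario$length - nchar(m) + 1, 1)
        s[pos:(pos + nchar(m) - 1)] <- strsplit(m, "")[[1]]
        planted[i] <- TRUE
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(seqs = seqs,
         truth = data.frame(group = group, seq_id = seq_len(n),
                            planted = planted, stringsAsFactors = FALSE))
  }
  reg <- draw_group(scenario$n_per_group, scenario$p_regulated, "regulated")
  ctl <- draw_group(scenario$n_per_group, scenario$p_control, "control")
  list(regulated = reg$seqs, control = ctl$seqs,
       truth = rbind(reg$truth, ctl$truth))
}
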