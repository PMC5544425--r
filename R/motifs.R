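#' Load a 7-mer motif set
#'
#' Reads one motif per line, uppercases, maps RNA `U` to DNA `T`, and
#' validates length-7 ACGT words. At most the first `max_motifs` (default
#' 10, the top-10 convention for RNA-binding-protein consensus lists) are
#' kept.
#'
#' @param path Plain-text file, one motif per line.
#' @param name Label for the motif set (default: file base name).
#' @param max_motifs Maximum number of motifs retained.
#' @return A list with `name` and `motifs` (character vector).
#' @export
load_motifs <- function(path, name = NULL, max_motifs = 10) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  motif_set(lines, name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
            max_motifs = max_motifs)
}

#' Construct a motif set from character motifs
#'
#' @param motifs Character vector of 7-mers (RNA `U` accepted).
#' @param name Label for the set.
#' @param max_motifs Maximum number of motifs retained.
#' @return A list with `name` and `motifs`.
#' @export
motif_set <- function(motifs, name = "motifs", max_motifs = 10) {
  motifs <- chartr("Uu", "Tt", toupper(motifs))
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != 7)) stop("motifs must be 7 nucleotides long")
  if (any(!grepl("^[ACGT]+$", motifs))) {
    stop("motifs must contain only A, C, G, T (or U)")
  }
  if (length(motifs) > max_motifs) motifs <- motifs[seq_len(max_motifs)]
  list(name = name, motifs = unique(motifs))
}

#' Count motif hits in a sequence
#'
#' Counts exact, possibly overlapping matches of any motif in the set
#' against a DNA sequence (e.g. `"AAAAAAAA"` contains the motif
#' `"AAAAAAA"` twice).
#'
#' @param sequence A character string or `DNAString` over A, C, G, T, N.
#' @param motifs A motif set from [motif_set()] or [load_motifs()].
#' @return A list with `count` (total hits over all motifs) and `present`
#'   (`count >= 1`).
#' @export
scan_motifs <- function(sequence, motifs) {
  seq_chr <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", seq_chr)) {
    stop("sequence contains characters outside A, C, G, T, N")
  }
  if (nchar(seq_chr) < 7) return(list(count = 0L, present = FALSE))
  subject <- Biostrings::DNAString(seq_chr)
  count <- sum(vapply(motifs$motifs, function(m) {
    Biostrings::countPattern(m, subject)
  }, integer(1)))
  list(count = count, present = count >= 1L)
}

#' Select the most-changed cassette events in each direction
#'
#' Ranks significant cassette-exon events by `|delta_u|` and takes the top
#' `n_each` with positive and the top `n_each` with negative usage change
#' (25 + 25 by default). Ties at the cutoff are broken by genomic
#' coordinate so the selection is deterministic.
#'
#' @param du_results Classified [differential_usage()] table.
#' @param n_each Events to take per direction (default 25).
#' @param significant_only Restrict to significant events (default TRUE).
#' @return A list with `up` and `down`: data frames of selected rows
#'   (ordered by decreasing `|delta_u|`).
#' @export
select_events <- function(du_results, n_each = 25, significant_only = TRUE) {
  ev <- du_results[du_results$class == "cassette_exon", , drop = FALSE]
  if (significant_only) ev <- ev[ev$significant, , drop = FALSE]
  pick <- function(rows, label) {
    o <- order(-abs(rows$delta_u), rows$chrom, rows$j1_start, rows$j1_end,
               rows$j2_start, rows$j2_end)
    rows <- rows[o, , drop = FALSE]
    if (nrow(rows) < n_each) {
      warning("only ", nrow(rows), " ", label, " events available (asked for ",
              n_each, "); taking all")
      return(rows)
    }
    rows[seq_len(n_each), , drop = FALSE]
  }
  list(
    up = pick(ev[!is.na(ev$delta_u) & ev$delta_u > 0, , drop = FALSE], "up"),
    down = pick(ev[!is.na(ev$delta_u) & ev$delta_u < 0, , drop = FALSE], "down")
  )
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by the first word of each header.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a BED-like cassette-event region annotation
#'
#' Tab-separated, no header: `chrom, start, end, strand, role` with 0-based
#' half-open coordinates and `role` of the form `event_id:region`, region
#' one of `upstream_exon`, `upstream_intron`, `cassette_exon`,
#' `downstream_intron`, `downstream_exon`.
#'
#' @param path Annotation file.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `event_id`, `region`.
#' @export
read_region_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "start", "end", "strand", "role"))
  parts <- strsplit(ann$role, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("annotation 'role' must be 'event_id:region'")
  }
  ann$event_id <- vapply(parts, `[[`, character(1), 1)
  ann$region <- vapply(parts, `[[`, character(1), 2)
  valid <- c("upstream_exon", "upstream_intron", "cassette_exon",
             "downstream_intron", "downstream_exon")
  bad <- setdiff(unique(ann$region), valid)
  if (length(bad) > 0) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  ann$role <- NULL
  ann
}

#' Extract cassette-exon region sequences
#'
#' For each event, slices the five regions from the genome: the flanking
#' exons in full, the cassette exon in full, and for each flanking intron
#' the `intron_flank` bases adjacent to the cassette exon (the full intron,
#' flagged truncated, when it is shorter). Minus-strand events are
#' reverse-complemented so every sequence reads 5' to 3' along the
#' transcript.
#'
#' @param event_ids Character vector of event ids to extract.
#' @param genome `DNAStringSet` from [read_genome_fasta()].
#' @param annotation Data frame from [read_region_annotation()].
#' @param intron_flank Intron window adjacent to the cassette exon, in
#'   bases (default 250).
#' @return Data frame with columns `event_id`, `region`, `seq`,
#'   `truncated`.
#' @export
extract_regions <- function(event_ids, genome, annotation, intron_flank = 250) {
  rows <- list()
  for (ev in event_ids) {
    ann <- annotation[annotation$event_id == ev, , drop = FALSE]
    if (nrow(ann) == 0) stop("event '", ev, "' not found in the annotation")
    cass <- ann[ann$region == "cassette_exon", , drop = FALSE]
    if (nrow(cass) != 1) stop("event '", ev, "' needs exactly one cassette_exon row")
    for (i in seq_len(nrow(ann))) {
      chrom <- ann$chrom[i]
      if (!chrom %in% names(genome)) {
        stop("chromosome '", chrom, "' missing from the genome FASTA")
      }
      s <- ann$start[i]; e <- ann$end[i]   # 0-based half-open
      truncated <- FALSE
      if (ann$region[i] %in% c("upstream_intron", "downstream_intron")) {
        len <- e - s
        if (len > intron_flank) {
          # keep the window on the side adjacent to the cassette exon
          if (e <= cass$start[1]) s <- e - intron_flank else e <- s + intron_flank
        } else {
          truncated <- TRUE
        }
      }
      if (s < 0 || e > length(genome[[chrom]])) {
        stop("region outside chromosome bounds for event '", ev, "'")
      }
      sq <- Biostrings::subseq(genome[[chrom]], start = s + 1, end = e)
      if (ann$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
      rows[[length(rows) + 1]] <- data.frame(
        event_id = ev, region = ann$region[i],
        seq = as.character(sq), truncated = truncated,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif enrichment of regulated versus control sequences
#'
#' Scores each sequence for presence of any motif in the set and tests the
#' regulated-versus-control presence/absence 2x2 table with the two-sided
#' Fisher exact test. The odds ratio uses the Haldane correction (+0.5 to
#' every cell) when any cell is zero.
#'
#' @param regulated,control Character vectors of sequences (equal sizes
#'   expected; a mismatch warns).
#' @param motifs A motif set.
#' @param region Optional region label carried into the result.
#' @param direction Optional direction label carried into the result.
#' @param alpha Significance threshold on the Fisher p (default 0.05).
#' @return One-row data frame: `region`, `motif_set`, `direction`,
#'   `n_regulated_with_motif`, `n_regulated`, `n_control_with_motif`,
#'   `n_control`, `odds_ratio`, `p`, `significant`.
#' @export
enrichment_test <- function(regulated, control, motifs, region = NA_character_,
                            direction = NA_character_, alpha = 0.05) {
  if (length(regulated) == 0 || length(control) == 0) {
    stop("both sequence groups must be non-empty")
  }
  if (length(regulated) != length(control)) {
    warning("regulated (", length(regulated), ") and control (",
            length(control), ") group sizes differ")
  }
  hit <- function(seqs) {
    vapply(seqs, function(s) scan_motifs(s, motifs)$present, logical(1),
           USE.NAMES = FALSE)
  }
  rw <- sum(hit(regulated)); cw <- sum(hit(control))
  a <- rw; b <- length(regulated) - rw
  c <- cw; d <- length(control) - cw
  p <- fisher_exact_two_sided(a, b, c, d)
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  data.frame(
    region = region, motif_set = motifs$name, direction = direction,
    n_regulated_with_motif = a, n_regulated = length(regulated),
    n_control_with_motif = c, n_control = length(control),
    odds_ratio = or, p = p, significant = p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Region-by-direction motif enrichment scan
#'
#' Runs [enrichment_test()] for every combination of region and direction:
#' events with increased skipping and increased inclusion are tested
#' separately against the controls, per region and per motif set.
#'
#' @param regulated_regions [extract_regions()] output for the regulated
#'   events, with an added `direction` column (`increased_skipping` /
#'   `increased_inclusion`).
#' @param control_regions [extract_regions()] output for control events.
#' @param motif_sets List of motif sets.
#' @param alpha Significance threshold.
#' @return Data frame of [enrichment_test()] rows.
#' @export
motif_enrichment_scan <- function(regulated_regions, control_regions,
                                  motif_sets, alpha = 0.05) {
  if (!"direction" %in% names(regulated_regions)) {
    stop("regulated regions need a 'direction' column")
  }
  rows <- list()
  for (ms in motif_sets) {
    for (region in unique(regulated_regions$region)) {
      ctrl <- control_regions$seq[control_regions$region == region]
      for (dir in unique(regulated_regions$direction)) {
        reg <- regulated_regions$seq[
          regulated_regions$region == region &
            regulated_regions$direction == dir
        ]
        if (length(reg) == 0 || length(ctrl) == 0) next
        rows[[length(rows) + 1]] <- enrichment_test(
          reg, ctrl, ms, region = region, direction = dir, alpha = alpha
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
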