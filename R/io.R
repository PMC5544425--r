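#' Read a competition plate-count table
#'
#' CSV with header `genotype_id,replicate_id,mutant_count,total_count`;
#' lines starting with `#` are ignored.
#'
#' @param path CSV file.
#' @return Validated plate data frame.
#' @export
read_plates <- function(path) {
  plates <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_plates(plates)
}

#' Read a sample sheet for junction analysis
#'
#' CSV with header `sample_id,genotype_id,replicate_id,path`. Relative
#' junction-file paths are resolved against the sheet's directory when not
#' found as given.
#'
#' @param path CSV file.
#' @return Sample-sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "genotype_id", "replicate_id", "path")
  if (!all(required %in% names(sheet))) {
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  }
  base <- dirname(path)
  fix <- !file.exists(sheet$path) &
    file.exists(file.path(base, sheet$path))
  sheet$path[fix] <- file.path(base, sheet$path[fix])
  sheet
}

#' Write a result table as TSV with a metadata header
#'
#' Prepends `#`-prefixed lines recording the package version and any
#' parameters (including the seed) used to produce the table, then the
#' column header and tab-separated rows. The file is written to a
#' temporary path and renamed into place so readers never see a partial
#' file.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(df, path, params = list()) {
  version <- as.character(utils::packageVersion("sgisplice"))
  header <- c(
    paste0("# sgisplice ", version),
    vapply(names(params), function(k) {
      paste0("# ", k, "=", paste(format(params[[k]]), collapse = ","))
    }, character(1))
  )
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a TSV written by [write_tsv_output()]
#'
#' @param path TSV file.
#' @return Data frame (metadata lines skipped).
#' @export
read_tsv_output <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Analysis configuration with the screen's standard thresholds
#'
#' Collects every tunable threshold of the two pipelines with its
#' conventional default: `|epsilon|` cut 0.20 and Bonferroni-adjusted
#' alpha 0.01 for the interaction screen; adjusted alpha 0.05 and the
#' 30-count filter for differential junction usage; 10 clusters and 1000
#' K-means restarts for heatmaps; 25 events per direction and a 250-base
#' intron flank for the motif analysis.
#'
#' @param epsilon_threshold,alpha_fitness Interaction-screen thresholds.
#' @param null_fraction Expected mutant plate fraction under equal fitness.
#' @param alpha_splicing,min_total Differential-usage thresholds.
#' @param kmeans_k,kmeans_runs Clustering parameters.
#' @param n_each,intron_flank Motif-analysis parameters.
#' @param alpha_motif Motif enrichment threshold.
#' @param seed Default seed for seeded steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(epsilon_threshold = 0.20, alpha_fitness = 0.01,
                       null_fraction = 0.5, alpha_splicing = 0.05,
                       min_total = 30, kmeans_k = 10, kmeans_runs = 1000,
                       n_each = 25, intron_flank = 250, alpha_motif = 0.05,
                       seed = 1) {
  # store doubles throughout so a JSON round trip is type-identical
  cfg <- lapply(list(
    epsilon_threshold = epsilon_threshold, alpha_fitness = alpha_fitness,
    null_fraction = null_fraction, alpha_splicing = alpha_splicing,
    min_total = min_total, kmeans_k = kmeans_k, kmeans_runs = kmeans_runs,
    n_each = n_each, intron_flank = intron_flank, alpha_motif = alpha_motif,
    seed = seed
  ), as.numeric)
  stopifnot(epsilon_threshold > 0,
            alpha_fitness > 0, alpha_fitness < 1,
            alpha_splicing > 0, alpha_splicing < 1,
            alpha_motif > 0, alpha_motif < 1,
            null_fraction > 0, null_fraction < 1,
            min_total >= 0, kmeans_k >= 1, kmeans_runs >= 1,
            n_each >= 1, intron_flank >= 1)
  structure(cfg, class = "run_config")
}

#' Serialise a configuration to JSON
#'
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to their defaults, so
#' a round trip through [write_run_config()] is the identity.
#'
#' @param path JSON file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}
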