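#' Read and write spot tables and cohort metadata
#'
#' Spot tables use a simplified GenePix-style tab-delimited dialect with a
#' header row `sample_id, protein_id, spot_index, channel, fg_median,
#' bg_median`; metadata is plain TSV. These are deliberately minimal text
#' formats so simulated cohorts round-trip exactly through files.
#'
#' @param spots,metadata data frames as produced by [generate_cohort()].
#' @param path file path.
#' @return the read functions return data frames; the write functions return
#'   `path` invisibly.
#' @name spot_io
NULL

spot_columns <- c("sample_id", "protein_id", "spot_index", "channel",
                  "fg_median", "bg_median")

#' @rdname spot_io
#' @export
write_spot_table <- function(spots, path) {
  stopifnot(all(spot_columns %in% names(spots)))
  utils::write.table(spots[spot_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname spot_io
#' @export
read_spot_table <- function(path) {
  spots <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(spot_columns, names(spots))
  if (length(missing)) {
    stop("spot table is missing columns: ", paste(missing, collapse = ", "))
  }
  spots[spot_columns]
}

#' @rdname spot_io
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname spot_io
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(bclc_stage = "character"))
  md
}

#' Write a simulated cohort to a directory
#'
#' Emits `spots.tsv`, `metadata.tsv`, `truth.txt` and the generator
#' configuration as `config.yaml`.
#'
#' @param cohort a `sero_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sero_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_table(cohort$spots, file.path(dir, "spots.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  writeLines(cohort$truth, file.path(dir, "truth.txt"))
  cfg <- unclass(cohort$config)
  cfg$stage_probs <- as.list(cfg$stage_probs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
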