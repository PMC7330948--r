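#' Signal matrices
#'
#' A `signal_matrix` holds per-protein signal-to-noise ratios (SNR) for a set
#' of samples on one detection channel: a non-negative numeric matrix with
#' samples as rows and proteins as columns, plus provenance fields recording
#' the channel and normalization state.
#'
#' @param values numeric samples x proteins matrix with dimnames.
#' @param channel detection channel the values came from.
#' @param normalized has cross-array normalization been applied?
#' @param normalization name of the normalization method applied.
#' @return an object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, channel, normalized = FALSE,
                          normalization = "none") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("sample and protein labels must be unique")
  }
  if (anyNA(values)) stop("signal matrix must not contain missing values")
  if (any(values < 0)) stop("SNR values must be non-negative")
  structure(list(values = values, channel = channel,
                 normalized = normalized, normalization = normalization),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d samples x %d proteins, channel %s, %s\n",
              nrow(x$values), ncol(x$values), x$channel,
              if (x$normalized) paste0("normalized (", x$normalization, ")")
              else "unnormalized"))
  invisible(x)
}

#' @export
as.matrix.signal_matrix <- function(x, ...) x$values

#' @export
dim.signal_matrix <- function(x) dim(x$values)

# Accept either a signal_matrix or a bare matrix in analysis functions.
signal_values <- function(x) {
  if (inherits(x, "signal_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a signal_matrix or a numeric matrix")
}

is_normalized <- function(x) {
  if (inherits(x, "signal_matrix")) isTRUE(x$normalized) else NA
}

#' Compute per-protein SNR from a spot table
#'
#' The signal of a spot is the ratio of the foreground to the background
#' median intensity; duplicate spots of the same protein are combined by the
#' arithmetic mean of their spot SNRs. One matrix is produced per detection
#' channel present in the table.
#'
#' @param spots spot table data frame (see [read_spot_table()] for columns).
#' @return named list of [signal_matrix()] objects, one per channel.
#' @examples
#' spots <- data.frame(sample_id = "S1", protein_id = "P1", spot_index = 1:2,
#'                     channel = "IgG", fg_median = c(1500, 2500),
#'                     bg_median = c(500, 500))
#' compute_snr(spots)$IgG$values # mean of 3.0 and 5.0 -> 4.0
#' @export
compute_snr <- function(spots) {
  missing <- setdiff(spot_columns, names(spots))
  if (length(missing)) {
    stop("spot table is missing columns: ", paste(missing, collapse = ", "))
  }
  bad_bg <- which(spots$bg_median <= 0)
  if (length(bad_bg)) {
    i <- bad_bg[1]
    stop(sprintf(
      "non-positive background median at sample %s, protein %s, spot %d, channel %s",
      spots$sample_id[i], spots$protein_id[i], spots$spot_index[i],
      spots$channel[i]))
  }
  if (any(spots$fg_median < 0)) stop("negative foreground median")
  key <- paste(spots$sample_id, spots$protein_id, spots$spot_index,
               spots$channel, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    i <- dup[1]
    stop(sprintf(
      "duplicate spot key: sample %s, protein %s, spot %d, channel %s",
      spots$sample_id[i], spots$protein_id[i], spots$spot_index[i],
      spots$channel[i]))
  }

  snr <- spots$fg_median / spots$bg_median
  out <- lapply(split(seq_len(nrow(spots)), spots$channel), function(rows) {
    d_sample <- spots$sample_id[rows]
    d_protein <- spots$protein_id[rows]
    samples <- sort(unique(d_sample)) # deterministic regardless of row order
    proteins <- sort(unique(d_protein))
    si <- match(d_sample, samples)
    pi <- match(d_protein, proteins)
    cell <- (pi - 1L) * length(samples) + si
    agg <- rowsum(cbind(snr[rows], 1), group = cell)
    m <- matrix(NA_real_, length(samples), length(proteins),
                dimnames = list(samples, proteins))
    m[as.integer(rownames(agg))] <- agg[, 1] / agg[, 2]
    if (anyNA(m)) {
      stop("incomplete spot table: some sample/protein pairs have no spots")
    }
    signal_matrix(m, channel = spots$channel[rows[1]])
  })
  out[order(names(out))]
}

#' Normalize a signal matrix across arrays
#'
#' `quantile` maps every sample onto the cross-sample mean quantile profile
#' (via [limma::normalizeQuantiles()]), removing array-level distributional
#' differences while preserving within-sample rank order. `median_scale`
#' divides each sample by its median and multiplies by the grand median (the
#' median of the per-sample medians). `none` only flags the matrix.
#'
#' @param x a [signal_matrix()] (must not already be normalized).
#' @param method one of `"quantile"`, `"median_scale"`, `"none"`.
#' @return a normalized [signal_matrix()].
#' @export
normalize_signals <- function(x, method = c("quantile", "median_scale",
                                            "none")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "signal_matrix"))
  if (x$normalized) stop("signal matrix is already normalized")
  v <- x$values
  if (method == "quantile") {
    if (nrow(v) < 2) stop("quantile normalization needs at least 2 samples")
    # limma treats columns as arrays; our arrays are rows
    nv <- t(limma::normalizeQuantiles(t(v), ties = TRUE))
    dimnames(nv) <- dimnames(v)
  } else if (method == "median_scale") {
    med <- apply(v, 1, stats::median)
    if (any(med <= 0)) stop("non-positive sample median")
    grand <- stats::median(med)
    nv <- v * (grand / med)
  } else {
    nv <- v
  }
  signal_matrix(nv, channel = x$channel, normalized = TRUE,
                normalization = method)
}

#' Inter-replicate correlation of repeated scans
#'
#' Quantifies array reproducibility: given replicate SNR profiles of one
#' sample, returns the full pairwise Pearson correlation matrix and the mean
#' of its off-diagonal entries.
#'
#' @param scans a list of [signal_matrix()] objects (one sample each, same
#'   proteins) or single-row matrices, or a replicates x proteins matrix.
#' @return list with `correlations` (symmetric matrix, unit diagonal) and
#'   `mean_r`.
#' @export
replicate_correlation <- function(scans) {
  if (is.list(scans)) {
    rows <- lapply(scans, function(s) {
      v <- signal_values(s)
      if (nrow(v) != 1) stop("each replicate scan must hold one sample")
      v
    })
    proteins <- colnames(rows[[1]])
    for (r in rows) {
      if (!identical(colnames(r), proteins)) {
        stop("replicate scans cover different protein sets")
      }
    }
    m <- do.call(rbind, rows)
  } else {
    m <- scans
  }
  if (nrow(m) < 2) stop("need at least 2 replicate scans")
  cc <- stats::cor(t(m))
  diag(cc) <- 1
  list(correlations = cc, mean_r = mean(cc[upper.tri(cc)]))
}

#' Write / read a signal matrix as TSV with a provenance sidecar
#'
#' The TSV has proteins as columns and a leading `sample_id` column; a
#' sidecar JSON (`<path>.json`) records channel and normalization state.
#'
#' @param x a [signal_matrix()].
#' @param path TSV path.
#' @return `write_signal_matrix` returns `path` invisibly;
#'   `read_signal_matrix` returns a [signal_matrix()].
#' @export
write_signal_matrix <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(channel = x$channel, normalized = x$normalized,
         normalization = x$normalization),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  signal_matrix(v, channel = meta$channel, normalized = meta$normalized,
                normalization = meta$normalization)
}
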