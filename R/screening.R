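#' Positive ratio of case samples above the control reactivity cutoff
#'
#' A case sample is called seropositive for a protein when its signal is
#' strictly greater than the mean plus `k` standard deviations (sample SD)
#' of the healthy-control signals; the positive ratio is the fraction of
#' case samples called positive. With zero control variance the threshold
#' degenerates to the control mean and a warning is emitted.
#'
#' @param case_values,control_values numeric vectors of per-sample signals.
#' @param k SD multiplier of the cutoff (default 2).
#' @return list with `ratio`, `threshold` and `degenerate` flag.
#' @examples
#' positive_ratio(c(7, 5, 6.2, 1), 1:5) # threshold 3 + 2*sd(1:5), ratio 0.5
#' @export
positive_ratio <- function(case_values, control_values, k = 2) {
  if (length(control_values) < 2) {
    stop("need at least 2 control values to define the SD cutoff")
  }
  if (length(case_values) < 1) stop("need at least 1 case value")
  s <- stats::sd(control_values)
  degenerate <- s == 0
  if (degenerate) {
    warning("zero control variance: positivity threshold equals the control mean")
  }
  threshold <- mean(control_values) + k * s
  list(ratio = mean(case_values > threshold), threshold = threshold,
       degenerate = degenerate)
}

#' Sensitivity at a fixed minimum specificity
#'
#' Scans candidate thresholds at the observed values and picks the smallest
#' threshold whose specificity (fraction of controls at or below it; a call
#' is positive when strictly above) is at least `min_spec`; returns the
#' sensitivity achieved there. A threshold always exists because the largest
#' observed control value has specificity 1.
#'
#' @param case_values,control_values numeric vectors (both non-empty).
#' @param min_spec minimum specificity in (0, 1].
#' @return list with `sensitivity`, `threshold` and the realized
#'   `specificity`.
#' @examples
#' sensitivity_at_specificity(c(9.5, 10.5, 8, 11), 1:10) # 0.75 at threshold 9
#' @export
sensitivity_at_specificity <- function(case_values, control_values,
                                       min_spec = 0.90) {
  if (!length(case_values) || !length(control_values)) {
    stop("both groups must be non-empty")
  }
  if (min_spec <= 0 || min_spec > 1) stop("min_spec must lie in (0, 1]")
  cand <- sort(unique(c(case_values, control_values)))
  ctrl_sorted <- sort(control_values)
  case_sorted <- sort(case_values)
  spec <- findInterval(cand, ctrl_sorted) / length(control_values)
  ok <- which(spec >= min_spec)
  thr <- cand[ok[1]]
  sens <- (length(case_values) - findInterval(thr, case_sorted)) /
    length(case_values)
  list(sensitivity = sens, threshold = thr, specificity = spec[ok[1]])
}

# Shared screening statistics for one case/control comparison over all
# protein columns. `strict_p` selects p < alpha (test phase) versus
# p <= alpha (discovery phase).
screen_pair <- function(case, control, comparison, alpha, fc_min,
                        ratio_min = NULL, sens_min = NULL, min_spec = 0.90,
                        strict_p = FALSE) {
  w <- welch_columns(case, control)
  thr <- colMeans(control) + 2 * sqrt(col_vars(control))
  ratio <- colMeans(sweep(case, 2, thr, ">"))
  sens <- rep(NA_real_, ncol(case))
  sens_thr <- rep(NA_real_, ncol(case))
  if (!is.null(sens_min)) {
    for (j in seq_len(ncol(case))) {
      ss <- sensitivity_at_specificity(case[, j], control[, j], min_spec)
      sens[j] <- ss$sensitivity
      sens_thr[j] <- ss$threshold
    }
  }
  p_ok <- if (strict_p) w$p_value < alpha else w$p_value <= alpha
  pass <- p_ok & w$fold_change >= fc_min
  if (!is.null(ratio_min)) pass <- pass & ratio >= ratio_min
  if (!is.null(sens_min)) pass <- pass & sens > sens_min
  data.frame(
    protein_id = colnames(case), comparison = comparison,
    p_value = w$p_value, bh_q = stats::p.adjust(w$p_value, "BH"),
    fold_change = w$fold_change, positive_ratio = ratio,
    threshold_used = unname(thr), sens_at_spec = sens,
    sens_threshold = sens_thr, passes = pass,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

split_groups <- function(signal, metadata, needed) {
  v <- signal_values(signal)
  norm <- is_normalized(signal)
  if (isFALSE(norm)) {
    warning("screening an unnormalized signal matrix; ",
            "normalize_signals() is recommended first")
  }
  idx <- match(rownames(v), metadata$sample_id)
  if (anyNA(idx)) stop("signal matrix contains samples absent from metadata")
  grp <- metadata$group[idx]
  for (g in needed) {
    if (sum(grp == g) < 2) {
      stop(sprintf("group '%s' needs at least 2 samples", g))
    }
  }
  list(values = v, group = grp)
}

#' Discovery-phase marker filter
#'
#' Screens every protein for differential autoantibody reactivity between
#' HCC and healthy samples using three joint criteria: Welch t-test
#' p-value <= `alpha`, linear fold change of group means >= `fc_min`, and
#' positive ratio >= `ratio_min` (positivity cutoff: healthy mean + 2 SD).
#' All statistics are reported for every protein regardless of pass status;
#' a Benjamini-Hochberg adjusted p-value column is included for information
#' only (no multiple-testing correction enters the pass decision).
#'
#' @param signal a normalized [signal_matrix()] (or bare matrix).
#' @param metadata cohort metadata with `sample_id` and `group`.
#' @param alpha p-value bound (non-strict, p <= alpha).
#' @param fc_min minimum fold change (case mean / control mean).
#' @param ratio_min minimum positive ratio.
#' @return data frame with one row per protein: statistics, `threshold_used`
#'   and the `passes` flag (column `passes_discovery`).
#' @export
discovery_filter <- function(signal, metadata, alpha = 0.05, fc_min = 1.2,
                             ratio_min = 0.10) {
  sp <- split_groups(signal, metadata, c("HCC", "healthy"))
  res <- screen_pair(sp$values[sp$group == "HCC", , drop = FALSE],
                     sp$values[sp$group == "healthy", , drop = FALSE],
                     "HCC_vs_healthy", alpha, fc_min,
                     ratio_min = ratio_min, strict_p = FALSE)
  names(res)[names(res) == "passes"] <- "passes_discovery"
  res$sens_at_spec <- NULL
  res$sens_threshold <- NULL
  res
}

#' Test-phase marker filter
#'
#' Applies the focused-array criteria separately to HCC vs healthy and HCC
#' vs cirrhotic: p < `alpha` (strict), fold change >= `fc_min`, and
#' sensitivity > `sens_min` (strict) at specificity >= `min_spec`. Each
#' protein is additionally labeled with the comparison set in which it
#' passes: `"healthy_only"`, `"cirrhotic_only"`, `"both"` or `"none"`
#' (see [hit_classes()]).
#'
#' @inheritParams discovery_filter
#' @param sens_min minimum sensitivity (strict inequality).
#' @param min_spec specificity floor for the sensitivity criterion.
#' @return data frame with one row per protein x comparison (`passes_test`
#'   flag), carrying a `hit_class` column repeated across comparisons.
#' @export
test_phase_filter <- function(signal, metadata, alpha = 0.05, fc_min = 1.2,
                              sens_min = 0.15, min_spec = 0.90) {
  sp <- split_groups(signal, metadata, c("HCC", "healthy", "cirrhotic"))
  case <- sp$values[sp$group == "HCC", , drop = FALSE]
  res <- rbind(
    screen_pair(case, sp$values[sp$group == "healthy", , drop = FALSE],
                "HCC_vs_healthy", alpha, fc_min,
                sens_min = sens_min, min_spec = min_spec, strict_p = TRUE),
    screen_pair(case, sp$values[sp$group == "cirrhotic", , drop = FALSE],
                "HCC_vs_cirrhotic", alpha, fc_min,
                sens_min = sens_min, min_spec = min_spec, strict_p = TRUE)
  )
  names(res)[names(res) == "passes"] <- "passes_test"
  ph <- res$protein_id[res$comparison == "HCC_vs_healthy" & res$passes_test]
  pc <- res$protein_id[res$comparison == "HCC_vs_cirrhotic" & res$passes_test]
  cls <- ifelse(res$protein_id %in% ph & res$protein_id %in% pc, "both",
         ifelse(res$protein_id %in% ph, "healthy_only",
         ifelse(res$protein_id %in% pc, "cirrhotic_only", "none")))
  res$hit_class <- cls
  res
}

#' Per-protein hit classification from a test-phase screening result
#'
#' @param result output of [test_phase_filter()].
#' @return data frame with `protein_id` and `hit_class` (one row per
#'   protein).
#' @export
hit_classes <- function(result) {
  u <- !duplicated(result$protein_id)
  data.frame(protein_id = result$protein_id[u],
             hit_class = result$hit_class[u],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a screening report
#'
#' One TSV row per protein x comparison with all statistics and pass flags.
#'
#' @param result data frame from [discovery_filter()] or
#'   [test_phase_filter()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Literature-derived autoantibody targets printed on the focused array
#'
#' The 19 cancer-literature proteins added to the screened candidates when
#' fabricating the 100-protein HCC-focused array.
#' @export
hcc_literature_aabs <- c(
  "CTRL", "DCAF4L2", "BIRC5", "CCNB1IP1", "GPR78", "HM13", "HSPA2", "IMP3",
  "KDM1A", "MAPK1", "RALA", "RPLP0", "SARNP", "SF3A3", "TSPAN13", "TUBB6",
  "XRCC5", "CENPF", "CDKN2A"
)

#' The published 7-autoantibody consensus panel
#'
#' Shipped for documentation and annotation only; the panel identities are
#' data-dependent and are not re-derived by this package.
#' @export
hcc_consensus_panel <- c(
  "CIAPIN1", "EGFR", "MAS1", "SLC44A3", "ASAH1", "UBL7", "ZNF428"
)
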