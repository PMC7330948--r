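#' Area under the ROC curve by Mann-Whitney pair counting
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie), computed via the rank
#' formula (exactly the pair-counting definition, at O(n log n)).
#'
#' @param scores_case,scores_control numeric score vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 5), c(1, 4)) # 0.75
#' @export
roc_auc <- function(scores_case, scores_control) {
  m <- length(scores_case)
  n <- length(scores_control)
  if (!m || !n) stop("both groups must be non-empty")
  r <- rank(c(scores_case, scores_control))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' AFP diagnostic rule
#'
#' Calls a sample AFP-positive when its serum AFP strictly exceeds the
#' diagnostic cutoff (default 400 ng/mL); a value exactly at the cutoff is
#' negative.
#'
#' @param afp_ng_ml serum AFP in ng/mL (non-negative).
#' @param cutoff diagnostic cutoff in ng/mL.
#' @return factor with levels `negative`, `positive`.
#' @export
afp_rule <- function(afp_ng_ml, cutoff = 400) {
  if (any(afp_ng_ml < 0, na.rm = TRUE)) stop("AFP must be non-negative")
  factor(ifelse(afp_ng_ml > cutoff, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' AFP-negative flag
#'
#' An HCC case is AFP-negative when its serum AFP is strictly below 20
#' ng/mL; the AFP-negative subgroup is evaluated against all controls.
#'
#' @param afp_ng_ml serum AFP in ng/mL (non-negative).
#' @param cutoff AFP-negativity cutoff (default 20 ng/mL).
#' @return logical flag.
#' @export
afp_negative_flag <- function(afp_ng_ml, cutoff = 20) {
  if (any(afp_ng_ml < 0, na.rm = TRUE)) stop("AFP must be non-negative")
  afp_ng_ml < cutoff
}

#' Combine AFP with the committee vote
#'
#' Fits a two-variable logistic combiner over (log1p(AFP), vote) on
#' training-phase data; the combined score is the fitted case probability.
#' AFP is log1p-transformed to tame its heavy right tail. The fitted
#' combiner is frozen and applied unchanged to validation data via
#' `predict()`.
#'
#' @param afp_values training-phase AFP (ng/mL).
#' @param votes training-phase committee votes.
#' @param labels training-phase case labels.
#' @return object of class `afp_ann_combiner`.
#' @export
combine_afp_ann <- function(afp_values, votes, labels) {
  y <- as_case_indicator(labels)
  if (length(unique(y)) < 2) stop("training labels must contain both classes")
  df <- data.frame(lafp = log1p(afp_values), vote = votes, .y = y)
  fit <- suppressWarnings(
    stats::glm(.y ~ lafp + vote, family = stats::binomial(), data = df)
  )
  structure(list(fit = fit), class = "afp_ann_combiner")
}

#' @export
predict.afp_ann_combiner <- function(object, afp_values, votes, ...) {
  nd <- data.frame(lafp = log1p(afp_values), vote = votes)
  unname(stats::predict(object$fit, newdata = nd, type = "response"))
}

# Sensitivity/specificity at a fixed operating threshold
# (positive call = score strictly above the threshold).
operating_point <- function(scores_case, scores_control, threshold) {
  list(sensitivity = mean(scores_case > threshold),
       specificity = mean(scores_control <= threshold))
}

#' Stratified performance report
#'
#' Mirrors the structure of the study's performance tables: for every
#' stratum of the HCC cases (all cases, AFP-negative, HBsAg+/-, BCLC stage
#' groups), every detector (AFP at its 400 ng/mL cutoff, the ANN committee
#' vote at its threshold, and optionally the AFP+ANN logistic combiner at
#' 0.5) and every comparison (controls = healthy + cirrhotic pooled, healthy
#' only, cirrhotic only), reports AUC plus sensitivity and specificity at
#' the detector's operating point. Strata restrict the cases only; controls
#' are never stratified. Empty strata yield rows with counts and NA metrics
#' so table shapes are stable.
#'
#' @param metadata cohort metadata (`sample_id`, `group`, `afp_ng_ml`,
#'   `hbsag`, `bclc_stage`).
#' @param votes committee votes named by sample ID (or aligned with
#'   `metadata` rows).
#' @param combiner optional [combine_afp_ann()] fit, adds the `AFP+ANN`
#'   detector.
#' @param vote_threshold ANN operating threshold.
#' @param afp_cutoff AFP operating cutoff (ng/mL).
#' @param combined_threshold operating threshold of the combiner score.
#' @param strata character vector naming the case strata to report; any of
#'   `"all"`, `"AFP-"`, `"HBsAg+"`, `"HBsAg-"`, `"BCLC 0/A"`, `"BCLC B"`,
#'   `"BCLC C"`.
#' @return data frame of class `stratified_report` with one row per stratum
#'   x detector x comparison.
#' @export
stratified_report <- function(metadata, votes, combiner = NULL,
                              vote_threshold = 0.5, afp_cutoff = 400,
                              combined_threshold = 0.5,
                              strata = c("all", "AFP-", "HBsAg+", "HBsAg-",
                                         "BCLC 0/A", "BCLC B", "BCLC C")) {
  md <- metadata
  if (!is.null(names(votes))) {
    votes <- votes[md$sample_id]
  } else if (length(votes) != nrow(md)) {
    stop("votes must be named by sample ID or aligned with metadata rows")
  }
  scores <- list(AFP = md$afp_ng_ml, ANN = as.numeric(votes))
  thresholds <- c(AFP = afp_cutoff, ANN = vote_threshold)
  if (!is.null(combiner)) {
    scores[["AFP+ANN"]] <- predict(combiner, md$afp_ng_ml, votes)
    thresholds[["AFP+ANN"]] <- combined_threshold
  }

  is_case <- md$group == "HCC"
  case_strata <- list(
    "all" = is_case,
    "AFP-" = is_case & afp_negative_flag(md$afp_ng_ml),
    "HBsAg+" = is_case & md$hbsag == "pos",
    "HBsAg-" = is_case & md$hbsag == "neg",
    "BCLC 0/A" = is_case & md$bclc_stage %in% c("0", "A"),
    "BCLC B" = is_case & md$bclc_stage %in% "B",
    "BCLC C" = is_case & md$bclc_stage %in% "C"
  )[strata]
  control_sets <- list(
    "healthy+cirrhotic" = md$group %in% c("healthy", "cirrhotic"),
    "healthy" = md$group == "healthy",
    "cirrhotic" = md$group == "cirrhotic"
  )

  rows <- list()
  for (st in names(case_strata)) {
    for (det in names(scores)) {
      for (cmp in names(control_sets)) {
        ci <- case_strata[[st]]
        ki <- control_sets[[cmp]]
        sc <- scores[[det]]
        row <- data.frame(
          stratum = st, detector = det, comparison = cmp,
          n_case = sum(ci), n_control = sum(ki),
          auc = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
          stringsAsFactors = FALSE
        )
        if (sum(ci) > 0 && sum(ki) > 0) {
          op <- operating_point(sc[ci], sc[ki], thresholds[[det]])
          row$auc <- roc_auc(sc[ci], sc[ki])
          row$sensitivity <- op$sensitivity
          row$specificity <- op$specificity
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stratified_report", class(out))
  out
}

#' ROC curve coordinates
#'
#' Full empirical ROC curve over all observed thresholds (positive call
#' strictly above the threshold), for plotting or coordinate dumps.
#'
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores_case, scores_control) {
  thr <- c(-Inf, sort(unique(c(scores_case, scores_control))))
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores_case > t), 0),
    specificity = vapply(thr, function(t) mean(scores_control <= t), 0)
  )
}
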