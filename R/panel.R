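#' Build a cross-validation fold plan
#'
#' Partitions the cohort into `n_folds` near-equal folds (sizes differ by at
#' most one). With `stratified = TRUE` (default) samples are assigned within
#' each group so that every fold's class composition matches the global one
#' to within one sample: each class is shuffled and dealt cyclically over
#' the folds, always starting from the currently least-filled fold.
#'
#' @param metadata cohort metadata (`sample_id`, `group`) or a data frame
#'   with those columns.
#' @param n_folds number of folds (>= 2).
#' @param stratified stratify by `group`?
#' @param seed RNG seed; assignment is deterministic given it.
#' @return an object of class `fold_plan`: list with `n_folds`,
#'   `assignments` (named integer vector, sample_id -> fold), `stratified`,
#'   `seed`.
#' @export
make_folds <- function(metadata, n_folds = 10, stratified = TRUE, seed = 1) {
  ids <- metadata$sample_id
  n <- length(ids)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need at least n_folds samples")
  if (anyDuplicated(ids)) stop("sample IDs must be unique")
  cls <- if (stratified) as.character(metadata$group) else rep("all", n)

  assignments <- integer(n)
  names(assignments) <- ids
  withr::with_seed(as.integer(seed), {
    counts <- integer(n_folds)
    for (cl in unique(cls)) {
      members <- sample(which(cls == cl))
      ord <- order(counts, seq_len(n_folds))
      fold_seq <- rep(ord, length.out = length(members))
      assignments[members] <- fold_seq
      counts <- tabulate(assignments[assignments > 0], n_folds)
    }
  })
  structure(list(n_folds = as.integer(n_folds), assignments = assignments,
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d samples in %d folds (%sstratified), sizes %s\n",
              length(x$assignments), x$n_folds,
              if (x$stratified) "" else "not ",
              paste(tabulate(x$assignments, x$n_folds), collapse = "/")))
  invisible(x)
}

#' Differential markers on the training portion of one fold
#'
#' Applies the test-phase marker criteria restricted to the training samples
#' of a cross-validation fold. With `control = "pooled"` (default) HCC is
#' compared against healthy and cirrhotic samples pooled into one control
#' group, matching the HCC-vs-controls classification target; with
#' `control = "separate"` the two comparisons are run as in
#' [test_phase_filter()] and a protein qualifies if it passes either.
#'
#' @param signal a normalized [signal_matrix()] covering the cohort.
#' @param metadata cohort metadata.
#' @param train_ids sample IDs of the training portion.
#' @param control `"pooled"` or `"separate"`.
#' @param alpha,fc_min,sens_min,min_spec criteria, as in
#'   [test_phase_filter()].
#' @return character vector of candidate protein IDs.
#' @export
fold_differential <- function(signal, metadata, train_ids,
                              control = c("pooled", "separate"),
                              alpha = 0.05, fc_min = 1.2, sens_min = 0.15,
                              min_spec = 0.90) {
  control <- match.arg(control)
  v <- signal_values(signal)
  keep <- rownames(v) %in% train_ids
  v <- v[keep, , drop = FALSE]
  md <- metadata[match(rownames(v), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("training IDs absent from metadata")
  if (!any(md$group == "HCC") || all(md$group == "HCC")) {
    stop("training set must contain both classes")
  }
  if (control == "pooled") {
    case <- v[md$group == "HCC", , drop = FALSE]
    ctrl <- v[md$group != "HCC", , drop = FALSE]
    res <- screen_pair(case, ctrl, "HCC_vs_controls", alpha, fc_min,
                       sens_min = sens_min, min_spec = min_spec,
                       strict_p = TRUE)
    sort(res$protein_id[res$passes])
  } else {
    res <- test_phase_filter(signal_matrix(v, channel = "subset",
                                           normalized = TRUE,
                                           normalization = "inherited"),
                             md, alpha, fc_min, sens_min, min_spec)
    sort(unique(res$protein_id[res$passes_test]))
  }
}

# Logistic regression by iteratively reweighted least squares with a weak
# L2 penalty on the slopes; the penalty only bounds coefficients under
# perfect separation and is far too small to bias regular fits.
ridge_logistic <- function(x, y, lambda) {
  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1))
  for (it in 1:200) {
    eta <- drop(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    h <- crossprod(xd, xd * w) + diag(pen, p)
    beta_new <- drop(solve(h, crossprod(xd, w * z)))
    if (max(abs(beta_new - beta)) < 1e-9) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  names(beta) <- colnames(xd)
  beta
}

#' Stepwise logistic marker selection
#'
#' Bidirectional stepwise search over candidate markers on a logistic model
#' for case status, scored by an information
#' criterion (BIC by default; AIC via `criterion`) and started from the
#' intercept-only model. Columns are standardized (mean/SD) before fitting
#' and processed in ascending protein-ID order, making the search
#' deterministic; an identical duplicated column can never enter twice
#' because it adds no deviance improvement. Final coefficients for the
#' selected subset are refit by ridge-stabilized IRLS (penalty
#' `ridge * n`), which keeps them finite under perfect separation.
#'
#' @param x samples x candidate-markers numeric matrix with column names.
#' @param labels case indicator: logical, 0/1, or a factor/character where
#'   `"HCC"` is the positive class.
#' @param criterion information criterion scoring the search:
#'   `"BIC"` (default; parsimonious, keeps null panels empty) or `"AIC"`.
#' @param ridge relative strength of the stabilizing L2 penalty.
#' @return list of class `stepwise_fit`: `selected` (protein IDs, sorted),
#'   `coefficients` (on standardized inputs, including intercept), `center`,
#'   `scale`, `criterion`.
#' @export
stepwise_logistic <- function(x, labels, criterion = c("BIC", "AIC"),
                              ridge = 1e-8) {
  criterion <- match.arg(criterion)
  if (is.null(colnames(x))) stop("candidate matrix must have column names")
  if (ncol(x) < 1) stop("need at least one candidate marker")
  y <- as_case_indicator(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  x <- x[, order(colnames(x)), drop = FALSE]

  ctr <- colMeans(x)
  scl <- sqrt(col_vars(x))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  vars <- paste0("x", seq_len(ncol(xs))) # syntactic stand-ins for protein IDs
  df <- as.data.frame(xs)
  names(df) <- vars
  df$.y <- y
  k <- if (criterion == "AIC") 2 else log(nrow(xs))
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  upper <- stats::reformulate(vars, response = ".y")
  fit <- suppressWarnings(
    stats::step(null_fit, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0, k = k)
  )
  chosen <- attr(stats::terms(fit), "term.labels")
  selected <- sort(colnames(xs)[match(chosen, vars)])

  coefs <- if (length(selected)) {
    ridge_logistic(xs[, match(selected, colnames(xs)), drop = FALSE], y,
                   lambda = ridge * nrow(xs))
  } else {
    c(`(Intercept)` = stats::qlogis(mean(y)))
  }
  structure(list(selected = selected, coefficients = coefs,
                 center = ctr, scale = scl, criterion = criterion),
            class = "stepwise_fit")
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == "HCC")
}

#' Consensus of per-fold marker selections
#'
#' The consensus panel is the set of markers selected in at least
#' `require_folds` folds; by default all folds, i.e. the intersection of the
#' per-fold selected sets.
#'
#' @param per_fold_sets list of character vectors (one per fold).
#' @param require_folds minimum number of folds a marker must appear in
#'   (default: all folds).
#' @return object of class `panel_selection`: `consensus_panel` (sorted),
#'   `fold_frequency` (named integer vector over all markers seen),
#'   `per_fold_sets`, `require_folds`.
#' @export
consensus_select <- function(per_fold_sets, require_folds = NULL) {
  if (!length(per_fold_sets)) stop("need at least one fold selection")
  require_folds <- require_folds %||% length(per_fold_sets)
  if (require_folds < 1 || require_folds > length(per_fold_sets)) {
    stop("require_folds must lie in [1, number of folds]")
  }
  all_markers <- unlist(lapply(per_fold_sets, unique))
  freq <- table(all_markers)
  fold_frequency <- stats::setNames(as.integer(freq), names(freq))
  fold_frequency <- fold_frequency[order(names(fold_frequency))]
  consensus <- sort(names(fold_frequency)[fold_frequency >= require_folds])
  structure(list(consensus_panel = consensus,
                 fold_frequency = fold_frequency,
                 per_fold_sets = per_fold_sets,
                 require_folds = require_folds),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("panel_selection: %d folds, consensus panel of %d markers\n",
              length(x$per_fold_sets), length(x$consensus_panel)))
  if (length(x$consensus_panel)) {
    cat(" ", paste(x$consensus_panel, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select the consensus predictor panel by cross-validated stepwise logistic
#' regression
#'
#' Runs the full predictor-selection procedure: build a (stratified) fold
#' plan; for each fold, determine differential markers on the 9/10 training
#' portion ([fold_differential()]) and reduce them by stepwise logistic
#' regression ([stepwise_logistic()]); keep as predictors the markers
#' selected in every fold ([consensus_select()]); finally refit a consensus
#' logistic model on the full cohort over the consensus panel.
#'
#' @inheritParams fold_differential
#' @param n_folds number of cross-validation folds.
#' @param seed fold-plan seed.
#' @param stratified stratify folds by group?
#' @param criterion stepwise score, `"BIC"` (default) or `"AIC"`.
#' @param require_folds consensus requirement (default: all folds).
#' @param ... further arguments passed to [fold_differential()]
#'   (`alpha`, `fc_min`, `sens_min`, `min_spec`).
#' @return a `panel_selection` object, additionally carrying `fold_plan` and
#'   `consensus_fit` (intercept + per-marker coefficients on standardized
#'   signals, with the standardization parameters).
#' @export
select_panel <- function(signal, metadata, n_folds = 10, seed = 1,
                         stratified = TRUE, control = c("pooled", "separate"),
                         criterion = c("BIC", "AIC"), require_folds = NULL,
                         ...) {
  control <- match.arg(control)
  criterion <- match.arg(criterion)
  v <- signal_values(signal)
  md <- metadata[match(rownames(v), metadata$sample_id), , drop = FALSE]
  plan <- make_folds(md, n_folds = n_folds, stratified = stratified,
                     seed = seed)

  sets <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    train_ids <- names(plan$assignments)[plan$assignments != f]
    cand <- fold_differential(signal, md, train_ids, control = control, ...)
    if (length(cand) == 0) {
      sets[[f]] <- character(0)
      next
    }
    xtr <- v[rownames(v) %in% train_ids, cand, drop = FALSE]
    ytr <- md$group[match(rownames(xtr), md$sample_id)] == "HCC"
    sets[[f]] <- stepwise_logistic(xtr, ytr, criterion = criterion)$selected
  }
  sel <- consensus_select(sets, require_folds = require_folds)
  sel$fold_plan <- plan

  panel <- sel$consensus_panel
  if (length(panel)) {
    y <- md$group == "HCC"
    xp <- v[, panel, drop = FALSE]
    ctr <- colMeans(xp)
    scl <- sqrt(col_vars(xp))
    scl[scl == 0] <- 1
    xs <- sweep(sweep(xp, 2, ctr), 2, scl, "/")
    coefs <- ridge_logistic(xs, as.integer(y), lambda = 1e-8 * nrow(xs))
    names(coefs) <- c("(Intercept)", panel)
    sel$consensus_fit <- list(coefficients = coefs, center = ctr, scale = scl)
  }
  sel
}

#' Write a panel-selection report
#'
#' One TSV row per marker seen in any fold: fold frequency, consensus flag,
#' and (for consensus markers) the consensus-model coefficient.
#'
#' @param selection a `panel_selection` from [select_panel()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(selection, path) {
  freq <- selection$fold_frequency
  coefs <- selection$consensus_fit$coefficients
  df <- data.frame(
    protein_id = names(freq),
    fold_frequency = as.integer(freq),
    consensus = names(freq) %in% selection$consensus_panel,
    coefficient = if (is.null(coefs)) NA_real_ else
      unname(coefs[names(freq)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
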