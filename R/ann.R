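#' Hidden-layer sizing rule
#'
#' Number of hidden neurons as a function of the number of input neurons n:
#' evaluate (4n^2 + 3) / (n^2 - 8) and round half-up to the nearest integer.
#' For the 7-predictor panel this gives 199/41 = 4.854 -> 5. The rule is
#' only defined for n >= 3 (the denominator must be positive).
#'
#' @param n_inputs number of input neurons (>= 3).
#' @return integer number of hidden neurons.
#' @examples
#' hidden_size_rule(7) # 5
#' @export
hidden_size_rule <- function(n_inputs) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1 ||
      n_inputs != round(n_inputs)) {
    stop("n_inputs must be a single integer")
  }
  if (n_inputs <= 2) {
    stop("hidden_size_rule requires n_inputs >= 3 (denominator n^2 - 8 must be positive)")
  }
  x <- (4 * n_inputs^2 + 3) / (n_inputs^2 - 8)
  as.integer(floor(x + 0.5))
}

#' Specification of one committee member network
#'
#' A fully connected feedforward network with one hidden layer (logistic
#' sigmoid) and a two-node softmax output (control node, HCC node), trained
#' by full-batch gradient backpropagation on the cross-entropy loss. The
#' hidden-layer width defaults to [hidden_size_rule()] applied to the input
#' width.
#'
#' @param n_inputs number of input features.
#' @param n_hidden hidden-layer width; default from [hidden_size_rule()]
#'   (which requires `n_inputs >= 3` -- give `n_hidden` explicitly for
#'   narrower inputs).
#' @param learning_rate gradient-descent step size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without verification-loss improvement
#'   before training stops (only used when a verification set is supplied).
#' @param seed weight-initialization seed.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_inputs, n_hidden = NULL, learning_rate = 0.05,
                         max_epochs = 500, early_stop_patience = 20,
                         seed = 1L) {
  if (n_inputs < 1) stop("n_inputs must be >= 1")
  if (is.null(n_hidden)) n_hidden <- hidden_size_rule(n_inputs)
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden), n_outputs = 2L,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "network_spec")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

xent <- function(p_hcc, y) {
  p <- ifelse(y == 1, p_hcc, 1 - p_hcc)
  -mean(log(pmax(p, 1e-15)))
}

forward_hcc <- function(net, x) {
  h <- stats::plogis(x %*% net$w1 + rep(net$b1, each = nrow(x)))
  p <- softmax_rows(h %*% net$w2 + rep(net$b2, each = nrow(x)))
  p[, 2]
}

#' Train one feedforward committee member
#'
#' Backpropagation with full-batch gradient descent on cross-entropy. When a
#' verification set is given it is used for early stopping only (never for
#' weight updates): training halts once the verification loss has not
#' improved for `early_stop_patience` epochs, and the weights from the best
#' verification epoch are kept. Deterministic given the spec seed.
#'
#' @param x standardized training matrix (samples x features).
#' @param y case labels (see [stepwise_logistic()] label conventions).
#' @param spec a [network_spec()].
#' @param x_val,y_val optional verification set for early stopping.
#' @return object of class `sero_ann` holding the weight matrices, the spec
#'   and training diagnostics. `predict()` returns the HCC output-node
#'   probability.
#' @export
train_network <- function(x, y, spec, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  x <- as.matrix(x)
  y <- as_case_indicator(y)
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  if (ncol(x) != spec$n_inputs) stop("feature count does not match spec")
  n <- nrow(x)
  d <- spec$n_inputs
  hdim <- spec$n_hidden
  target <- cbind(1 - y, y)

  r1 <- sqrt(6 / (d + hdim))
  r2 <- sqrt(6 / (hdim + 2))
  withr::with_seed(spec$seed, {
    w1 <- matrix(stats::runif(d * hdim, -r1, r1), d, hdim)
    w2 <- matrix(stats::runif(hdim * 2, -r2, r2), hdim, 2)
  })
  b1 <- numeric(hdim)
  b2 <- numeric(2)

  use_val <- !is.null(x_val)
  if (use_val) {
    x_val <- as.matrix(x_val)
    y_val <- as_case_indicator(y_val)
  }
  best <- list(loss = Inf, w1 = w1, b1 = b1, w2 = w2, b2 = b2, epoch = 0L)
  stall <- 0L
  lr <- spec$learning_rate
  epoch <- 0L

  for (epoch in seq_len(spec$max_epochs)) {
    h <- stats::plogis(x %*% w1 + rep(b1, each = n))
    p <- softmax_rows(h %*% w2 + rep(b2, each = n))
    dscore <- (p - target) / n
    gw2 <- crossprod(h, dscore)
    gb2 <- colSums(dscore)
    dh <- (dscore %*% t(w2)) * h * (1 - h)
    gw1 <- crossprod(x, dh)
    gb1 <- colSums(dh)
    w1 <- w1 - lr * gw1
    b1 <- b1 - lr * gb1
    w2 <- w2 - lr * gw2
    b2 <- b2 - lr * gb2

    if (use_val) {
      net_now <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
      vloss <- xent(forward_hcc(net_now, x_val), y_val)
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= spec$early_stop_patience) break
      }
    }
  }
  if (use_val && is.finite(best$loss)) {
    w1 <- best$w1; b1 <- best$b1; w2 <- best$w2; b2 <- best$b2
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, spec = spec,
                 epochs_run = epoch,
                 val_loss = if (use_val) best$loss else NA_real_),
            class = "sero_ann")
}

#' @export
predict.sero_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$n_inputs) {
    stop("feature count does not match the trained network")
  }
  drop(forward_hcc(object, newdata))
}

#' Build a committee of networks over repeated k-fold splits
#'
#' For each of `n_repeats` independent stratified fold plans, one network is
#' trained per fold on the ~90% training portion, with the held-out ~10%
#' fold used as verification set for early stopping, yielding
#' `n_folds * n_repeats` member networks. Inputs are standardized once with
#' the full training cohort's mean/SD, stored in the model for reuse at
#' prediction time. If a fold plan produces a single-class training or
#' verification fold, that repeat's plan is re-drawn (and the redraw
#' logged via `message()`).
#'
#' Out-of-fold committee votes are recorded: each sample's vote is the mean
#' output of the networks whose verification fold contained it (one per
#' repeat), giving an unbiased in-cohort performance estimate.
#'
#' @param x samples x panel-markers matrix (raw scale; standardization is
#'   handled internally). Row names are used as sample IDs.
#' @param labels case labels.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats independent repeats (default 50, i.e. 500 networks).
#' @param spec a [network_spec()]; default sized by [hidden_size_rule()].
#' @param seed master seed for fold plans and weight initialization.
#' @param vote_threshold classification threshold on the committee vote.
#' @return object of class `committee_model`: `networks` (each with
#'   `repeat`/`fold` provenance), `center`/`scale`, `panel`, `sample_ids`,
#'   `oof_votes`, `vote_threshold`, `n_folds`, `n_repeats`, `seed`.
#' @export
build_committee <- function(x, labels, n_folds = 10, n_repeats = 50,
                            spec = NULL, seed = 1, vote_threshold = 0.5) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%04d", seq_len(nrow(x)))
  y <- as_case_indicator(labels)
  if (nrow(x) < n_folds) stop("need at least n_folds samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (vote_threshold <= 0 || vote_threshold >= 1) {
    stop("vote_threshold must lie in (0, 1)")
  }
  if (is.null(spec)) spec <- network_spec(ncol(x))
  if (spec$n_inputs != ncol(x)) stop("spec width does not match panel size")

  ctr <- colMeans(x)
  scl <- sqrt(col_vars(x))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  md <- data.frame(sample_id = rownames(x),
                   group = ifelse(y == 1, "HCC", "control"),
                   stringsAsFactors = FALSE)

  networks <- vector("list", n_folds * n_repeats)
  oof <- matrix(NA_real_, nrow(x), n_repeats,
                dimnames = list(rownames(x), NULL))
  k <- 0L
  for (r in seq_len(n_repeats)) {
    plan <- NULL
    for (attempt in seq_len(100)) {
      cand_plan <- make_folds(md, n_folds = n_folds, stratified = TRUE,
                              seed = derive_seed(seed, 70L, r, attempt))
      splits_ok <- all(vapply(seq_len(n_folds), function(f) {
        tr <- y[cand_plan$assignments != f]
        ve <- y[cand_plan$assignments == f]
        length(unique(tr)) == 2 && length(unique(ve)) == 2
      }, logical(1)))
      if (splits_ok) {
        plan <- cand_plan
        if (attempt > 1) {
          message(sprintf("repeat %d: fold plan re-drawn %d time(s)",
                          r, attempt - 1L))
        }
        break
      }
    }
    if (is.null(plan)) stop("could not draw a fold plan with both classes in every fold")
    for (f in seq_len(n_folds)) {
      k <- k + 1L
      tr <- plan$assignments != f
      member_spec <- spec
      member_spec$seed <- derive_seed(seed, 71L, r, f)
      net <- train_network(xs[tr, , drop = FALSE], y[tr], member_spec,
                           x_val = xs[!tr, , drop = FALSE],
                           y_val = y[!tr])
      net$provenance <- list(repeat_index = r, fold = f)
      networks[[k]] <- net
      oof[!tr, r] <- predict(net, xs[!tr, , drop = FALSE])
    }
  }
  structure(list(networks = networks, center = ctr, scale = scl,
                 panel = colnames(x), sample_ids = rownames(x),
                 labels = y, oof_votes = rowMeans(oof),
                 vote_threshold = vote_threshold,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), spec = spec),
            class = "committee_model")
}

#' @export
print.committee_model <- function(x, ...) {
  cat(sprintf(
    "committee_model: %d networks (%d folds x %d repeats), %d-%d-2 architecture, panel: %s\n",
    length(x$networks), x$n_folds, x$n_repeats,
    x$spec$n_inputs, x$spec$n_hidden, paste(x$panel, collapse = ", ")))
  invisible(x)
}

#' Committee vote for new samples
#'
#' The committee vote is the arithmetic mean of all member networks' HCC
#' output-node probabilities; it always lies in \[0, 1\].
#'
#' @param model a [build_committee()] model.
#' @param newdata feature vector or samples x markers matrix on the raw
#'   signal scale (the model's stored standardization is applied).
#' @return numeric vote per sample.
#' @export
committee_vote <- function(model, newdata) {
  stopifnot(inherits(model, "committee_model"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(model$panel)) {
    stop(sprintf("expected %d panel features, got %d",
                 length(model$panel), ncol(newdata)))
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), model$panel)) {
    if (!setequal(colnames(newdata), model$panel)) {
      stop("feature names do not match the model panel")
    }
    newdata <- newdata[, model$panel, drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  votes <- rowMeans(vapply(model$networks, function(net) predict(net, xs),
                           numeric(nrow(xs))))
  unname(votes)
}

#' Classify committee votes
#'
#' A sample is called HCC when its vote is strictly greater than the
#' threshold; a vote exactly at the threshold is called control.
#'
#' @param vote numeric votes in \[0, 1\].
#' @param threshold classification threshold (default 0.5).
#' @return factor with levels `control`, `HCC`.
#' @export
classify_votes <- function(vote, threshold = 0.5) {
  if (any(vote < 0 | vote > 1)) stop("votes must lie in [0, 1]")
  factor(ifelse(vote > threshold, "HCC", "control"),
         levels = c("control", "HCC"))
}

#' Blind prediction on an independent validation cohort
#'
#' Applies a frozen committee to new samples with no refitting: the training
#' phase's standardization parameters are reused unchanged. Any overlap
#' between training and blind sample IDs raises an error (leakage guard)
#' unless explicitly disabled.
#'
#' @param model a [build_committee()] model.
#' @param new_matrix samples x markers matrix with row-name sample IDs.
#' @param allow_overlap disable the ID-overlap guard (testing only).
#' @return named numeric vote per sample.
#' @export
blind_predict <- function(model, new_matrix, allow_overlap = FALSE) {
  stopifnot(inherits(model, "committee_model"))
  new_matrix <- as.matrix(new_matrix)
  ids <- rownames(new_matrix)
  if (!allow_overlap && !is.null(ids)) {
    shared <- intersect(ids, model$sample_ids)
    if (length(shared)) {
      stop("blind set shares sample IDs with the training phase: ",
           paste(utils::head(shared, 5), collapse = ", "))
    }
  }
  votes <- committee_vote(model, new_matrix)
  if (!is.null(ids)) names(votes) <- ids
  votes
}

#' Serialize / restore a committee model as JSON
#'
#' Stores architecture, all member weights, standardization parameters,
#' fold/repeat provenance and seeds at full floating-point precision, so a
#' restored committee reproduces blind predictions.
#'
#' @param model a `committee_model`.
#' @param path JSON file path.
#' @return `write_committee` returns `path` invisibly; `read_committee`
#'   returns the restored `committee_model`.
#' @export
write_committee <- function(model, path) {
  stopifnot(inherits(model, "committee_model"))
  nets <- lapply(model$networks, function(net) {
    list(w1 = net$w1, b1 = net$b1, w2 = net$w2, b2 = net$b2,
         epochs_run = net$epochs_run, val_loss = net$val_loss,
         provenance = net$provenance, seed = net$spec$seed)
  })
  payload <- list(
    spec = unclass(model$spec), networks = nets,
    center = as.list(model$center), scale = as.list(model$scale),
    panel = model$panel, sample_ids = model$sample_ids,
    labels = model$labels, oof_votes = as.list(model$oof_votes),
    vote_threshold = model$vote_threshold, n_folds = model$n_folds,
    n_repeats = model$n_repeats, seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_committee
#' @export
read_committee <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(as.list(p$spec), class = "network_spec")
  rebuild <- function(i) {
    net <- list(
      w1 = matrix(unlist(p$networks$w1[[i]]), spec$n_inputs, spec$n_hidden),
      b1 = as.numeric(p$networks$b1[[i]]),
      w2 = matrix(unlist(p$networks$w2[[i]]), spec$n_hidden, 2),
      b2 = as.numeric(p$networks$b2[[i]]),
      epochs_run = p$networks$epochs_run[i],
      val_loss = p$networks$val_loss[i],
      provenance = list(repeat_index = p$networks$provenance$repeat_index[i],
                        fold = p$networks$provenance$fold[i]),
      spec = spec
    )
    class(net) <- "sero_ann"
    net
  }
  n_nets <- length(p$networks$b1)
  structure(list(
    networks = lapply(seq_len(n_nets), rebuild),
    center = unlist(p$center), scale = unlist(p$scale),
    panel = p$panel, sample_ids = p$sample_ids, labels = p$labels,
    oof_votes = unlist(p$oof_votes), vote_threshold = p$vote_threshold,
    n_folds = p$n_folds, n_repeats = p$n_repeats, seed = p$seed,
    spec = spec
  ), class = "committee_model")
}
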