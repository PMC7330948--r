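test_that("the hidden-layer sizing rule matches direct evaluation", {
  expect_identical(hidden_size_rule(7), 5L)   # 199/41 = 4.854 -> 5
  expect_identical(hidden_size_rule(3), 39L)  # 39/1
  expect_identical(hidden_size_rule(100), 4L) # -> 4 asymptotically
  expect_error(hidden_size_rule(2), "n_inputs >= 3")
  expect_error(hidden_size_rule(1), "n_inputs >= 3")
  expect_error(hidden_size_rule(2.5), "single integer")
})

test_that("network training separates separable data and is deterministic", {
  g <- gaussian_markers(40, 40, c(4, 4), seed = 2)
  spec <- network_spec(2, n_hidden = 4, learning_rate = 0.5,
                       max_epochs = 500, seed = 3)
  net <- train_network(g$x, g$y, spec)
  acc <- mean((predict(net, g$x) > 0.5) == (g$y == 1))
  expect_equal(acc, 1.0)

  net2 <- train_network(g$x, g$y, spec)
  expect_identical(net$w1, net2$w1)
  expect_identical(net$w2, net2$w2)

  expect_error(train_network(g$x, rep(1, 80), spec), "both classes")
})

test_that("shuffled labels give chance-level held-out discrimination", {
  g <- gaussian_markers(150, 150, rep(0.9, 4), seed = 5)
  y_perm <- withr::with_seed(6, sample(g$y))
  tr <- 1:200
  te <- 201:300
  spec <- network_spec(4, learning_rate = 0.05, max_epochs = 300, seed = 8)
  net <- train_network(g$x[tr, ], y_perm[tr], spec)
  p <- predict(net, g$x[te, ])
  auc <- roc_auc(p[y_perm[te] == 1], p[y_perm[te] == 0])
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("committee bookkeeping follows the folds-by-repeats product", {
  g <- gaussian_markers(30, 30, c(1.5, 1.0, 0.5), seed = 9)
  cm <- build_committee(g$x, g$y, n_folds = 2, n_repeats = 3,
                        spec = network_spec(3, n_hidden = 3,
                                            max_epochs = 60),
                        seed = 10)
  expect_length(cm$networks, 6)
  prov <- t(vapply(cm$networks,
                   function(n) unlist(n$provenance), numeric(2)))
  expect_equal(nrow(unique(prov)), 6) # every (repeat, fold) pair distinct
  # training portions are ~ (n_folds-1)/n_folds of the cohort
  expect_true(all(vapply(cm$networks, function(n) n$epochs_run >= 1, NA)))
  expect_true(all(cm$oof_votes >= 0 & cm$oof_votes <= 1))
})

test_that("committee votes are the arithmetic mean of member outputs", {
  g <- gaussian_markers(25, 25, c(1, 1, 1), seed = 12)
  cm <- build_committee(g$x, g$y, n_folds = 2, n_repeats = 2,
                        spec = network_spec(3, n_hidden = 3,
                                            max_epochs = 60),
                        seed = 13)
  xs <- sweep(sweep(g$x, 2, cm$center), 2, cm$scale, "/")
  member <- vapply(cm$networks, function(n) predict(n, xs),
                   numeric(nrow(g$x)))
  expect_equal(committee_vote(cm, g$x), unname(rowMeans(member)))
  expect_true(all(committee_vote(cm, g$x) >= 0 &
                    committee_vote(cm, g$x) <= 1))
  expect_error(committee_vote(cm, g$x[, 1:2]), "expected 3 panel features")
})

test_that("vote classification uses a strict threshold with ties to control", {
  expect_equal(as.character(classify_votes(c(0.51, 0.5, 0.49))),
               c("HCC", "control", "control"))
  votes <- seq(0, 1, by = 0.05)
  n_pos <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(t) sum(classify_votes(votes, t) == "HCC"), 0L)
  expect_true(all(diff(n_pos) <= 0))
  expect_error(classify_votes(1.2), "votes must lie")
})

test_that("blind prediction guards against sample leakage", {
  g <- gaussian_markers(25, 25, c(1.2, 1.2, 0.8), seed = 15)
  cm <- build_committee(g$x, g$y, n_folds = 2, n_repeats = 2,
                        spec = network_spec(3, n_hidden = 3,
                                            max_epochs = 60),
                        seed = 16)
  expect_error(blind_predict(cm, g$x), "leakage|shares sample IDs")
  # guard disabled: identical to in-sample committee votes
  expect_equal(unname(blind_predict(cm, g$x, allow_overlap = TRUE)),
               committee_vote(cm, g$x))
  fresh <- g$x
  rownames(fresh) <- paste0("new", seq_len(nrow(fresh)))
  expect_silent(v <- blind_predict(cm, fresh))
  expect_named(v, rownames(fresh))
})

test_that("blind votes are distributionally stable across phases", {
  # validation cohort drawn from the training distribution: blind AUC close
  # to the out-of-fold AUC
  diffs <- vapply(1:10, function(s) {
    tr <- gaussian_markers(120, 120, rep(0.7, 4), seed = 600 + s)
    va <- gaussian_markers(120, 120, rep(0.7, 4), seed = 700 + s)
    rownames(va$x) <- paste0("v", seq_len(nrow(va$x)))
    cm <- build_committee(tr$x, tr$y, n_folds = 5, n_repeats = 2,
                          spec = network_spec(4, n_hidden = 4,
                                              max_epochs = 200),
                          seed = 800 + s)
    oof <- roc_auc(cm$oof_votes[tr$y == 1], cm$oof_votes[tr$y == 0])
    bv <- blind_predict(cm, va$x)
    blind <- roc_auc(bv[va$y == 1], bv[va$y == 0])
    blind - oof
  }, 0)
  expect_lt(mean(abs(diffs)), 0.05)
})

test_that("a committee is no worse than its median member", {
  g <- gaussian_markers(100, 100, rep(0.8, 5), seed = 20)
  cm <- build_committee(g$x, g$y, n_folds = 5, n_repeats = 2,
                        spec = network_spec(5, max_epochs = 200),
                        seed = 21)
  xs <- sweep(sweep(g$x, 2, cm$center), 2, cm$scale, "/")
  member_auc <- vapply(cm$networks, function(n) {
    p <- predict(n, xs)
    roc_auc(p[g$y == 1], p[g$y == 0])
  }, 0)
  votes <- committee_vote(cm, g$x)
  committee_auc <- roc_auc(votes[g$y == 1], votes[g$y == 0])
  expect_gte(committee_auc, median(member_auc) - 0.02)
})

test_that("committee models round-trip through JSON", {
  g <- gaussian_markers(20, 20, c(1.5, 0.5, 1.0), seed = 24)
  cm <- build_committee(g$x, g$y, n_folds = 2, n_repeats = 2,
                        spec = network_spec(3, n_hidden = 3,
                                            max_epochs = 50),
                        seed = 25)
  path <- withr::local_tempfile(fileext = ".json")
  write_committee(cm, path)
  back <- read_committee(path)
  expect_equal(length(back$networks), length(cm$networks))
  expect_equal(back$center, cm$center)
  fresh <- g$x
  rownames(fresh) <- paste0("n", seq_len(nrow(fresh)))
  expect_equal(blind_predict(back, fresh), blind_predict(cm, fresh),
               tolerance = 1e-12)
})
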