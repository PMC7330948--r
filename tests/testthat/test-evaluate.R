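test_that("AUC matches brute-force pair counting and pROC", {
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(roc_auc(6:9, 1:4), 1.0)        # perfect separation
  expect_equal(roc_auc(rep(2, 5), rep(2, 7)), 0.5) # all ties
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")

  brute <- function(case, ctrl) {
    mean(outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(41, {
    for (rep in 1:10) {
      case <- round(rnorm(20, 0.5), 1) # coarse rounding forces ties
      ctrl <- round(rnorm(25), 1)
      expect_equal(roc_auc(case, ctrl), brute(case, ctrl))
    }
  })
  skip_if_not_installed("pROC")
  withr::with_seed(42, {
    case <- rnorm(30, 1)
    ctrl <- rnorm(40)
  })
  ref <- suppressMessages(pROC::auc(
    rep(c(1, 0), c(30, 40)), c(case, ctrl), direction = "<"))
  expect_equal(roc_auc(case, ctrl), as.numeric(ref))
})

test_that("AUC respects complement symmetry and monotone invariance", {
  withr::with_seed(43, {
    case <- rlnorm(25, 0.8)
    ctrl <- rlnorm(30)
  })
  expect_equal(roc_auc(case, ctrl) + roc_auc(ctrl, case), 1)
  expect_equal(roc_auc(log(case), log(ctrl)), roc_auc(case, ctrl))
  expect_equal(roc_auc(case^3, ctrl^3), roc_auc(case, ctrl))
})

test_that("AFP rules use the documented strict inequalities", {
  expect_equal(as.character(afp_rule(c(401, 400, 12))),
               c("positive", "negative", "negative"))
  expect_error(afp_rule(-1), "non-negative")
  expect_identical(afp_negative_flag(c(19.9, 20, 500)),
                   c(TRUE, FALSE, FALSE))
})

test_that("the AFP+ANN combiner is dominated by a perfect vote and helps otherwise", {
  withr::with_seed(45, {
    y <- rep(c(1, 0), each = 100)
    vote <- ifelse(y == 1, runif(200, 0.8, 1), runif(200, 0, 0.2))
    afp_noise <- rlnorm(200, 2, 1)
  })
  comb <- combine_afp_ann(afp_noise, vote, y)
  sc <- predict(comb, afp_noise, vote)
  expect_equal(roc_auc(sc[y == 1], sc[y == 0]), 1.0)

  # two independently informative detectors: combination does not hurt
  ok <- vapply(1:10, function(s) {
    withr::with_seed(900 + s, {
      y <- rep(c(1, 0), each = 150)
      vote <- plogis(rnorm(300, ifelse(y == 1, 1, 0)))
      afp <- rlnorm(300, ifelse(y == 1, 3.5, 2), 1)
    })
    comb <- combine_afp_ann(afp, vote, y)
    sc <- predict(comb, afp, vote)
    auc_c <- roc_auc(sc[y == 1], sc[y == 0])
    auc_v <- roc_auc(vote[y == 1], vote[y == 0])
    auc_a <- roc_auc(afp[y == 1], afp[y == 0])
    auc_c >= max(auc_v, auc_a) - 0.02
  }, NA)
  expect_gte(mean(ok), 0.9)

  # deterministic given identical inputs
  c1 <- combine_afp_ann(afp_noise, vote, y)
  expect_equal(coef(c1$fit), coef(comb$fit))
  expect_error(combine_afp_ann(afp_noise, vote, rep(1, 200)), "both classes")
})

test_that("stratified reports mirror the unstratified evaluation and conserve counts", {
  coh <- generate_cohort(small_config(n_hcc = 120, n_cirrhotic = 40,
                                      n_healthy = 60, n_proteins = 12,
                                      n_informative = 3, seed = 71L))
  md <- coh$metadata
  sig <- normalize_signals(compute_snr(coh$spots)$IgG)
  # use a simple standardized marker-mean score as the vote
  sc <- rowMeans(scale(sig$values[, coh$truth]))
  votes <- stats::setNames(plogis(sc), rownames(sig$values))

  rep_all <- stratified_report(md, votes)
  row_all <- rep_all[rep_all$stratum == "all" & rep_all$detector == "ANN" &
                       rep_all$comparison == "healthy+cirrhotic", ]
  hcc <- md$group == "HCC"
  ctl <- md$group != "HCC"
  expect_equal(row_all$auc, roc_auc(votes[md$sample_id[hcc]],
                                    votes[md$sample_id[ctl]]))
  expect_equal(row_all$n_case, 120)
  expect_equal(row_all$n_control, 100)

  # BCLC strata partition the staged HCC cases
  stage_rows <- rep_all[rep_all$detector == "AFP" &
                          rep_all$comparison == "healthy" &
                          rep_all$stratum %in% c("BCLC 0/A", "BCLC B",
                                                 "BCLC C"), ]
  expect_equal(sum(stage_rows$n_case), sum(!is.na(md$bclc_stage)))

  # sensitivity/specificity pairs lie on the empirical ROC curve
  cc <- roc_coordinates(votes[md$sample_id[hcc]], votes[md$sample_id[ctl]])
  expect_true(any(abs(cc$sensitivity - row_all$sensitivity) < 1e-12 &
                    abs(cc$specificity - row_all$specificity) < 1e-12))
})

test_that("empty strata yield NA rows instead of disappearing", {
  md <- toy_metadata(rep(c("HCC", "healthy"), each = 10))
  md$hbsag <- "pos" # no HBsAg- cases at all
  votes <- stats::setNames(rep(c(0.9, 0.1), each = 10), md$sample_id)
  rep_ <- stratified_report(md, votes, strata = c("all", "HBsAg-"))
  neg <- rep_[rep_$stratum == "HBsAg-", ]
  expect_equal(nrow(neg), 2 * 3) # detectors x comparisons, all retained
  expect_true(all(is.na(neg$auc)))
  expect_true(all(neg$n_case == 0))
})

test_that("stage-independent effects give stage-stable AUCs", {
  # the generator never couples marker effects to stage, so stage-stratified
  # AUCs should agree within sampling error
  cfg <- small_config(n_hcc = 360, n_cirrhotic = 0, n_healthy = 150,
                      n_proteins = 10, n_informative = 4,
                      effect_size = 1.0, seed = 73L)
  coh <- generate_cohort(cfg)
  md <- coh$metadata
  sig <- normalize_signals(compute_snr(coh$spots)$IgG)
  sc <- rowMeans(scale(sig$values[, coh$truth]))
  votes <- stats::setNames(plogis(sc / 3), rownames(sig$values))
  rep_ <- stratified_report(md, votes,
                            strata = c("BCLC 0/A", "BCLC B", "BCLC C"))
  aucs <- rep_$auc[rep_$detector == "ANN" & rep_$comparison == "healthy"]
  expect_gte(min(rep_$n_case), 50)
  expect_lt(max(aucs) - min(aucs), 0.1) # +/- 0.05 around their centre
})

test_that("realized AFP positivity matches the generator target", {
  coh <- generate_cohort(sim_config(n_proteins = 2, n_informative = 0,
                                    seed = 90L))
  md <- coh$metadata
  pos <- afp_rule(md$afp_ng_ml[md$group == "HCC"]) == "positive"
  expect_lt(abs(mean(pos) - 0.30), 3 * sqrt(0.3 * 0.7 / length(pos)))
})
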