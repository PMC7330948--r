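test_that("positive ratio implements the mean + 2 SD rule", {
  pr <- positive_ratio(c(7, 5, 6.2, 1), c(1, 2, 3, 4, 5))
  expect_equal(pr$threshold, 3 + 2 * sd(1:5))
  expect_equal(pr$ratio, 0.5)

  # nothing at the control mean can be positive
  expect_equal(positive_ratio(rep(3, 5), c(1, 2, 3, 4, 5))$ratio, 0)

  # zero-variance controls: degenerate threshold with a warning
  expect_warning(pr0 <- positive_ratio(c(2, 2), c(1, 1, 1, 1)),
                 "zero control variance")
  expect_equal(pr0$ratio, 1)
  expect_true(pr0$degenerate)

  expect_error(positive_ratio(1, 2), "at least 2 control")
})

test_that("positive ratio is monotone non-increasing in the SD multiplier", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      ctrl <- rlnorm(30)
      case <- rlnorm(40, 0.5)
      ratios <- vapply(c(0, 0.5, 1, 2, 3, 5),
                       function(k) positive_ratio(case, ctrl, k = k)$ratio, 0)
      expect_true(all(diff(ratios) <= 0))
    }
  })
})

test_that("sensitivity at fixed specificity uses the smallest qualifying threshold", {
  ss <- sensitivity_at_specificity(c(9.5, 10.5, 8, 11), 1:10,
                                   min_spec = 0.9)
  expect_equal(ss$threshold, 9)
  expect_equal(ss$sensitivity, 0.75)

  # perfect separation
  expect_equal(sensitivity_at_specificity(6:9, 1:4)$sensitivity, 1.0)
  # identical constant vectors: nothing separates
  expect_equal(sensitivity_at_specificity(rep(2, 4), rep(2, 6))$sensitivity,
               0.0)
  expect_error(sensitivity_at_specificity(1, 2, min_spec = 0), "min_spec")
  expect_error(sensitivity_at_specificity(numeric(0), 1:3), "non-empty")
})

test_that("sensitivity is monotone non-increasing in the specificity floor", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      ctrl <- rnorm(50)
      case <- rnorm(50, 1)
      sens <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95, 1), function(ms) {
        sensitivity_at_specificity(case, ctrl, min_spec = ms)$sensitivity
      }, 0)
      expect_true(all(diff(sens) <= 0))
    }
  })
})

test_that("discovery filter applies the three joint criteria", {
  # overwhelming planted effect passes everything
  withr::with_seed(5, {
    v <- cbind(strong = exp(c(rnorm(50, 2), rnorm(50))),
               null = exp(c(rnorm(50), rnorm(50))))
  })
  rownames(v) <- sprintf("S%03d", 1:100)
  md <- toy_metadata(rep(c("HCC", "healthy"), each = 50))
  res <- discovery_filter(toy_signal(v), md)
  expect_true(res$passes_discovery[res$protein_id == "strong"])
  expect_false(res$passes_discovery[res$protein_id == "null"])

  # significant p but fold change below 1.2 fails the fold-change rule
  withr::with_seed(6, {
    tight <- cbind(shift = c(rnorm(200, 1.1, 0.05), rnorm(200, 1.0, 0.05)))
  })
  rownames(tight) <- sprintf("S%03d", 1:400)
  md2 <- toy_metadata(rep(c("HCC", "healthy"), each = 200))
  res2 <- discovery_filter(toy_signal(tight), md2)
  expect_lt(res2$p_value, 0.05)
  expect_lt(res2$fold_change, 1.2)
  expect_false(res2$passes_discovery)

  expect_error(discovery_filter(toy_signal(v), toy_metadata(rep("HCC", 100))),
               "group 'healthy'")
})

test_that("discovery filter pass set shrinks as criteria tighten", {
  coh <- generate_cohort(small_config(n_hcc = 40, n_cirrhotic = 0,
                                      n_healthy = 40, n_proteins = 80,
                                      n_informative = 10, effect_size = 0.6,
                                      seed = 51L))
  sig <- normalize_signals(compute_snr(coh$spots)$IgG)
  base <- discovery_filter(sig, coh$metadata)
  passed <- function(r) r$protein_id[r$passes_discovery]
  for (args in list(list(alpha = 0.01), list(fc_min = 1.5),
                    list(ratio_min = 0.3))) {
    tighter <- do.call(discovery_filter,
                       c(list(sig, coh$metadata), args))
    expect_true(all(passed(tighter) %in% passed(base)))
  }
})

test_that("Welch p-values agree with t.test and a permutation oracle", {
  withr::with_seed(77, {
    case <- matrix(rnorm(15 * 3, mean = 0.4, sd = 1.3), 15, 3)
    ctrl <- matrix(rnorm(20 * 3), 20, 3)
  })
  w <- seromics:::welch_columns(case, ctrl)
  for (j in 1:3) {
    expect_equal(w$p_value[j], t.test(case[, j], ctrl[, j])$p.value)
  }
  # permutation oracle on the first column (difference of means statistic)
  x <- c(case[, 1], ctrl[, 1])
  lab <- rep(c(TRUE, FALSE), c(15, 20))
  obs <- abs(mean(x[lab]) - mean(x[!lab]))
  perm <- withr::with_seed(78, {
    replicate(4000, {
      l <- sample(lab)
      abs(mean(x[l]) - mean(x[!l]))
    })
  })
  expect_lt(abs(mean(perm >= obs) - w$p_value[1]), 0.05)
})

test_that("test-phase filter classifies hits by comparison", {
  cfg <- small_config(n_hcc = 60, n_cirrhotic = 40, n_healthy = 60,
                      n_proteins = 30, n_informative = 3,
                      effect_size = 1.8, cirrhosis_leak = 0, seed = 13L)
  coh <- generate_cohort(cfg)
  sig <- normalize_signals(compute_snr(coh$spots)$IgG)
  res <- test_phase_filter(sig, coh$metadata)
  cls <- hit_classes(res)
  # with no cirrhosis leak, strong markers separate HCC from both controls
  expect_true(all(cls$hit_class[cls$protein_id %in% coh$truth] == "both"))

  # full leak: elevated equally in cirrhosis, so the HCC-vs-cirrhotic
  # comparison must fail for the planted markers
  cfg1 <- small_config(n_hcc = 60, n_cirrhotic = 40, n_healthy = 60,
                       n_proteins = 30, n_informative = 3,
                       effect_size = 1.8, cirrhosis_leak = 1, seed = 14L)
  coh1 <- generate_cohort(cfg1)
  sig1 <- normalize_signals(compute_snr(coh1$spots)$IgG)
  res1 <- test_phase_filter(sig1, coh1$metadata)
  vs_cir <- res1[res1$comparison == "HCC_vs_cirrhotic", ]
  expect_false(any(vs_cir$passes_test[vs_cir$protein_id %in% coh1$truth]))
})

test_that("planted both-type markers are recovered across seeds", {
  recovered <- vapply(1:20, function(s) {
    cfg <- sim_config(n_hcc = 250, n_cirrhotic = 250, n_healthy = 250,
                      n_proteins = 50, n_informative = 10,
                      effect_size = 1.5, cirrhosis_leak = 0,
                      channels = "IgG", seed = 1000L + s)
    coh <- generate_cohort(cfg)
    sig <- normalize_signals(compute_snr(coh$spots)$IgG)
    cls <- hit_classes(test_phase_filter(sig, coh$metadata))
    sum(cls$hit_class[cls$protein_id %in% coh$truth] == "both")
  }, 0)
  expect_gte(mean(recovered), 9)
})

test_that("screening reports are written as one row per protein x comparison", {
  coh <- generate_cohort(small_config(n_hcc = 10, n_cirrhotic = 6,
                                      n_healthy = 10, n_proteins = 8,
                                      n_informative = 2))
  sig <- normalize_signals(compute_snr(coh$spots)$IgG)
  res <- test_phase_filter(sig, coh$metadata)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screening_report(res, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 8 * 2)
  expect_true(all(c("p_value", "fold_change", "positive_ratio",
                    "sens_at_spec", "passes_test", "hit_class") %in%
                    names(back)))
})

test_that("shipped constants have the printed cardinalities", {
  expect_length(hcc_literature_aabs, 19)
  expect_length(hcc_consensus_panel, 7)
  expect_false(anyDuplicated(hcc_literature_aabs) > 0)
})
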