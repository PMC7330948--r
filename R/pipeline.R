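#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis: simulation of the
#' test and validation cohorts (or paths to existing spot tables), signal
#' quantification and normalization, screening thresholds, panel selection,
#' committee training and evaluation. All randomness derives from
#' `master_seed`, and the full configuration is echoed into the output
#' provenance.
#'
#' @param output_dir directory for all reports and the serialized model.
#' @param master_seed master seed for the whole run.
#' @param test_config,validation_config [sim_config()] objects for the two
#'   cohorts (their own `seed` fields are overridden from `master_seed`).
#' @param test_dir,validation_dir optional directories of existing cohorts
#'   (as written by [write_cohort()]); when given, simulation is skipped.
#' @param channel detection channel used for analysis (default IgG).
#' @param normalization cross-array normalization method.
#' @param screen arguments for the test-phase screen / per-fold filter:
#'   `alpha`, `fc_min`, `sens_min`, `min_spec`, `control`.
#' @param n_folds,criterion,require_folds panel-selection parameters.
#' @param n_repeats committee repeats (networks = `n_folds * n_repeats`).
#' @param network list of [network_spec()] overrides (`n_hidden`,
#'   `learning_rate`, `max_epochs`, `early_stop_patience`).
#' @param vote_threshold committee classification threshold.
#' @param write_inputs also write the simulated cohorts to the output
#'   directory?
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            master_seed = 1L,
                            test_config = sim_config(),
                            validation_config = sim_config(
                              n_hcc = 279, n_cirrhotic = 119,
                              n_healthy = 179),
                            test_dir = NULL, validation_dir = NULL,
                            channel = "IgG",
                            normalization = c("quantile", "median_scale",
                                              "none"),
                            screen = list(),
                            n_folds = 10, criterion = "BIC",
                            require_folds = NULL,
                            n_repeats = 50, network = list(),
                            vote_threshold = 0.5,
                            write_inputs = FALSE) {
  normalization <- match.arg(normalization)
  screen_defaults <- list(alpha = 0.05, fc_min = 1.2, sens_min = 0.15,
                          min_spec = 0.90, control = "pooled")
  screen <- utils::modifyList(screen_defaults, screen)
  structure(list(
    output_dir = output_dir, master_seed = as.integer(master_seed),
    test_config = test_config, validation_config = validation_config,
    test_dir = test_dir, validation_dir = validation_dir,
    channel = channel, normalization = normalization, screen = screen,
    n_folds = as.integer(n_folds), criterion = criterion,
    require_folds = require_folds, n_repeats = as.integer(n_repeats),
    network = network, vote_threshold = vote_threshold,
    write_inputs = write_inputs
  ), class = "pipeline_config")
}

config_as_json <- function(config) {
  strip <- function(x) {
    if (inherits(x, "sim_config")) x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

load_phase <- function(config, phase) {
  dir <- if (phase == "test") config$test_dir else config$validation_dir
  if (!is.null(dir)) {
    list(spots = read_spot_table(file.path(dir, "spots.tsv")),
         metadata = read_metadata(file.path(dir, "metadata.tsv")))
  } else {
    sim <- if (phase == "test") config$test_config else
      config$validation_config
    # one shared seed across phases: protein content (and the informative
    # set) is common to the whole study, while per-sample streams are
    # already keyed by phase and therefore independent between cohorts
    sim$seed <- derive_seed(config$master_seed, 10L)
    generate_cohort(sim, phase = phase)
  }
}

quantify_phase <- function(config, cohort) {
  mats <- compute_snr(cohort$spots)
  if (!config$channel %in% names(mats)) {
    stop(sprintf("channel %s absent from spot tables", config$channel))
  }
  normalize_signals(mats[[config$channel]], method = config$normalization)
}

#' Run the full seromics analysis pipeline
#'
#' Executes the end-to-end procedure: simulate (or load) the test and
#' validation cohorts; quantify per-protein SNR on the analysis channel and
#' normalize within each phase; screen the test phase with the test-phase
#' criteria; select the consensus predictor panel by cross-validated
#' stepwise logistic regression; train the committee of networks on the test
#' phase; blind-predict the validation phase with the frozen committee; and
#' emit stratified AFP / ANN / AFP+ANN performance reports for both phases.
#' Any sample-ID overlap between test and validation phases aborts the run
#' (leakage guard). All artifacts are stamped with the seed and a hash of
#' the full configuration; a rerun with the same configuration reproduces
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory artifacts (`screen`,
#'   `panel`, `committee`, `votes`, `reports`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  test <- load_phase(config, "test")
  validation <- load_phase(config, "validation")
  shared <- intersect(test$metadata$sample_id, validation$metadata$sample_id)
  if (length(shared)) {
    stop("phase leakage: sample IDs shared between test and validation: ",
         paste(utils::head(shared, 5), collapse = ", "))
  }
  if (config$write_inputs && inherits(test, "sero_cohort")) {
    write_cohort(test, file.path(out, "test_cohort"))
    write_cohort(validation, file.path(out, "validation_cohort"))
  }

  sig_test <- quantify_phase(config, test)
  sig_validation <- quantify_phase(config, validation)
  write_signal_matrix(sig_test, file.path(out, "signals_test.tsv"))
  write_signal_matrix(sig_validation, file.path(out, "signals_validation.tsv"))
  message(sprintf("quantified %d test / %d validation samples, %d proteins",
                  nrow(sig_test$values), nrow(sig_validation$values),
                  ncol(sig_test$values)))

  scr <- test_phase_filter(sig_test, test$metadata,
                           alpha = config$screen$alpha,
                           fc_min = config$screen$fc_min,
                           sens_min = config$screen$sens_min,
                           min_spec = config$screen$min_spec)
  write_screening_report(scr, file.path(out, "screening_report.tsv"))
  n_hits <- length(unique(scr$protein_id[scr$passes_test]))
  message(sprintf("test-phase screen: %d candidate markers", n_hits))

  panel_sel <- select_panel(
    sig_test, test$metadata, n_folds = config$n_folds,
    seed = derive_seed(config$master_seed, 3L),
    control = config$screen$control, criterion = config$criterion,
    require_folds = config$require_folds,
    alpha = config$screen$alpha, fc_min = config$screen$fc_min,
    sens_min = config$screen$sens_min, min_spec = config$screen$min_spec)
  write_panel_report(panel_sel, file.path(out, "panel_report.tsv"))
  panel <- panel_sel$consensus_panel
  message(sprintf("consensus panel: %d markers (%s)", length(panel),
                  paste(panel, collapse = ", ")))
  if (length(panel) < 1) {
    stop("consensus panel is empty; no committee can be trained")
  }

  spec_args <- c(list(n_inputs = length(panel)), config$network)
  if (is.null(spec_args$n_hidden) && length(panel) < 3) {
    spec_args$n_hidden <- max(2L, length(panel))
  }
  spec <- do.call(network_spec, spec_args)
  committee <- build_committee(
    sig_test$values[, panel, drop = FALSE],
    test$metadata$group[match(rownames(sig_test$values),
                              test$metadata$sample_id)] == "HCC",
    n_folds = config$n_folds, n_repeats = config$n_repeats, spec = spec,
    seed = derive_seed(config$master_seed, 4L),
    vote_threshold = config$vote_threshold)
  write_committee(committee, file.path(out, "committee_model.json"))
  message(sprintf("committee: %d networks trained",
                  length(committee$networks)))

  votes_test <- committee$oof_votes
  missing_panel <- setdiff(panel, colnames(sig_validation$values))
  if (length(missing_panel)) {
    stop("validation cohort lacks panel proteins: ",
         paste(missing_panel, collapse = ", "))
  }
  votes_validation <- blind_predict(
    committee, sig_validation$values[, panel, drop = FALSE])

  md_test <- test$metadata
  md_val <- validation$metadata
  combiner <- combine_afp_ann(
    md_test$afp_ng_ml[match(names(votes_test), md_test$sample_id)],
    votes_test, md_test$group[match(names(votes_test),
                                    md_test$sample_id)] == "HCC")

  report_test <- stratified_report(md_test, votes_test, combiner,
                                   vote_threshold = config$vote_threshold)
  report_validation <- stratified_report(md_val, votes_validation, combiner,
                                         vote_threshold =
                                           config$vote_threshold)

  write_votes <- function(votes, path) {
    utils::write.table(
      data.frame(sample_id = names(votes), vote = unname(votes)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_votes(votes_test, file.path(out, "votes_test.tsv"))
  write_votes(votes_validation, file.path(out, "votes_validation.tsv"))
  utils::write.table(report_test, file.path(out, "report_test.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report_validation,
                     file.path(out, "report_validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_json <- as.character(config_as_json(config))
  jsonlite::write_json(
    list(seed = config$master_seed, config_hash = config_hash(cfg_json),
         config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
         n_test = nrow(md_test), n_validation = nrow(md_val),
         n_screen_hits = n_hits, panel = panel,
         n_networks = length(committee$networks)),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    screen = scr, panel = panel_sel, committee = committee,
    votes = list(test = votes_test, validation = votes_validation),
    reports = list(test = report_test, validation = report_validation),
    combiner = combiner,
    paths = list(output_dir = out)
  ))
}
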