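# Shared fixture builders: everything is generated in code at test time.

small_config <- function(...) {
  defaults <- list(n_hcc = 30, n_cirrhotic = 15, n_healthy = 30,
                   n_proteins = 40, n_informative = 4, effect_size = 1.5,
                   cirrhosis_leak = 0, channels = "IgG", seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# A hand-built spot table: one sample, explicit intensities.
toy_spots <- function(snr_by_protein, sample_id = "S1", channel = "IgG",
                      bg = 500) {
  rows <- lapply(names(snr_by_protein), function(p) {
    s <- snr_by_protein[[p]]
    data.frame(sample_id = sample_id, protein_id = p,
               spot_index = seq_along(s), channel = channel,
               fg_median = bg * s, bg_median = bg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Direct signal_matrix from a plain matrix (marked normalized so screening
# functions stay quiet).
toy_signal <- function(values, channel = "IgG") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("P%03d", seq_len(ncol(values)))
  }
  signal_matrix(values, channel = channel, normalized = TRUE,
                normalization = "none")
}

toy_metadata <- function(groups, ids = NULL) {
  ids <- ids %||% sprintf("S%03d", seq_along(groups))
  data.frame(sample_id = ids, group = groups,
             afp_ng_ml = 5, hbsag = "neg", bclc_stage = NA_character_,
             phase = "test", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian marker cohort with per-marker standardized shift delta for cases;
# the analytic optimal AUC for independent unit-variance markers is
# pnorm(sqrt(sum(delta^2)) / sqrt(2)).
gaussian_markers <- function(n_case, n_control, delta, seed) {
  d <- length(delta)
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_case * d), n_case, d) +
        matrix(delta, n_case, d, byrow = TRUE),
      matrix(rnorm(n_control * d), n_control, d)
    )
  })
  rownames(x) <- sprintf("g%04d", seq_len(n_case + n_control))
  colnames(x) <- sprintf("M%02d", seq_len(d))
  list(x = x, y = rep(c(1L, 0L), c(n_case, n_control)))
}
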