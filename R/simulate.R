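#' Configuration for the synthetic seromics cohort generator
#'
#' Builds and validates the parameter set describing a simulated case-control
#' autoantibody study: a three-group serum cohort (HCC, cirrhotic, healthy)
#' profiled on protein arrays with duplicate spots and up to two detection
#' channels, where a minority of printed proteins carry a true group effect.
#'
#' The generative model is: per-spot background median ~ Gamma(`bg_shape`,
#' scale = `bg_scale`) (right-skewed, strictly positive); latent per-protein
#' log signal-to-noise ratio (SNR) ~ Normal with a protein-specific baseline
#' (SD `protein_sdlog`) plus biological noise (SD `noise_sdlog`); foreground
#' median = background x SNR with additional per-spot technical noise (SD
#' `spot_sdlog` on the log scale). Informative proteins receive a mean
#' log-SNR shift of `effect_size` in HCC samples and `effect_size *
#' cirrhosis_leak` in cirrhotic samples, on the IgG channel only.
#'
#' Serum AFP (ng/mL) in HCC is drawn from a two-component log-normal mixture
#' calibrated in closed form so that the expected fraction above the 400
#' ng/mL diagnostic cutoff equals `afp_params$target_pos400` and the expected
#' AFP-negative fraction (< 20 ng/mL) equals `afp_params$target_neg20`;
#' controls are drawn from single low log-normals.
#'
#' @param n_hcc,n_cirrhotic,n_healthy group sizes. Defaults are the test-phase
#'   cohort composition (282/130/164).
#' @param n_proteins number of printed proteins (default 100, a focused array).
#' @param n_informative number of truly discriminative proteins.
#' @param effect_size mean log-scale SNR shift for informative proteins in HCC
#'   samples; must be non-negative.
#' @param cirrhosis_leak fraction (0-1) of the informative effect also
#'   expressed in cirrhotic samples.
#' @param duplicate_spots printed spots per protein per channel (default 2).
#' @param channels detection channels, a subset of `c("IgG", "IgM")`.
#' @param afp_params list with elements `target_pos400`, `target_neg20`,
#'   `high_median`, `high_sdlog`, `low_sdlog`, `cirrhotic_median`,
#'   `cirrhotic_sdlog`, `healthy_median`, `healthy_sdlog`.
#' @param stage_probs named probabilities over BCLC stages `0`, `A`, `B`, `C`
#'   for HCC samples; must sum to 1.
#' @param hbsag_pos_frac fraction of HCC samples positive for HBsAg.
#' @param protein_sdlog,noise_sdlog,spot_sdlog log-scale SDs of the protein
#'   baseline, the per-sample biological noise, and the per-spot technical
#'   noise.
#' @param bg_shape,bg_scale Gamma parameters of the background median.
#' @param seed master seed; all randomness is derived from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [generate_replicate_scans()]
#' @export
sim_config <- function(n_hcc = 282, n_cirrhotic = 130, n_healthy = 164,
                       n_proteins = 100, n_informative = 7,
                       effect_size = 1.2, cirrhosis_leak = 0.25,
                       duplicate_spots = 2, channels = c("IgG", "IgM"),
                       afp_params = list(), stage_probs = NULL,
                       hbsag_pos_frac = 0.72,
                       protein_sdlog = 0.30, noise_sdlog = 0.50,
                       spot_sdlog = 0.05,
                       bg_shape = 4, bg_scale = 150, seed = 1L) {
  afp_defaults <- list(target_pos400 = 0.30, target_neg20 = 0.40,
                       high_median = 1500, high_sdlog = 1.2, low_sdlog = 1.0,
                       cirrhotic_median = 10, cirrhotic_sdlog = 1.8,
                       healthy_median = 4, healthy_sdlog = 0.8)
  afp_params <- utils::modifyList(afp_defaults, afp_params)
  if (is.null(stage_probs)) {
    stage_probs <- c(`0` = 0.10, A = 0.35, B = 0.25, C = 0.30)
  }

  counts <- c(n_hcc = n_hcc, n_cirrhotic = n_cirrhotic, n_healthy = n_healthy)
  if (any(counts < 0)) stop("group counts must be non-negative")
  if (n_proteins <= 0) stop("n_proteins must be positive")
  if (n_informative < 0 || n_informative > n_proteins) {
    stop("n_informative must lie in [0, n_proteins]")
  }
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (cirrhosis_leak < 0 || cirrhosis_leak > 1) {
    stop("cirrhosis_leak must lie in [0, 1]")
  }
  if (duplicate_spots < 1) stop("duplicate_spots must be >= 1")
  channels <- match.arg(channels, c("IgG", "IgM"), several.ok = TRUE)
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("stage_probs must sum to 1")
  if (!setequal(names(stage_probs), c("0", "A", "B", "C"))) {
    stop("stage_probs must be named over BCLC stages 0, A, B, C")
  }
  if (hbsag_pos_frac < 0 || hbsag_pos_frac > 1) {
    stop("hbsag_pos_frac must lie in [0, 1]")
  }

  structure(list(
    n_hcc = as.integer(n_hcc), n_cirrhotic = as.integer(n_cirrhotic),
    n_healthy = as.integer(n_healthy),
    n_proteins = as.integer(n_proteins),
    n_informative = as.integer(n_informative),
    effect_size = effect_size, cirrhosis_leak = cirrhosis_leak,
    duplicate_spots = as.integer(duplicate_spots), channels = channels,
    afp_params = afp_params, stage_probs = stage_probs[c("0", "A", "B", "C")],
    hbsag_pos_frac = hbsag_pos_frac,
    protein_sdlog = protein_sdlog, noise_sdlog = noise_sdlog,
    spot_sdlog = spot_sdlog, bg_shape = bg_shape, bg_scale = bg_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Closed-form calibration of the HCC AFP mixture. The high component has a
# fixed median/sdlog; its weight w is chosen so that w * P_high(AFP > 400)
# hits the AFP+ target (the low component's mass above 400 is negligible by
# construction but is accounted for exactly below via the meanlog solve).
afp_mixture <- function(p) {
  p_high_400 <- stats::plnorm(400, log(p$high_median), p$high_sdlog,
                              lower.tail = FALSE)
  w <- p$target_pos400 / p_high_400
  if (w <= 0 || w >= 1) stop("AFP mixture targets are infeasible")
  p_high_20 <- stats::plnorm(20, log(p$high_median), p$high_sdlog)
  q <- (p$target_neg20 - w * p_high_20) / (1 - w)
  if (q <= 0 || q >= 1) stop("AFP mixture targets are infeasible")
  low_meanlog <- log(20) - stats::qnorm(q) * p$low_sdlog
  list(w_high = w, high_meanlog = log(p$high_median),
       high_sdlog = p$high_sdlog, low_meanlog = low_meanlog,
       low_sdlog = p$low_sdlog)
}

# Protein-level quantities shared by every sample of a cohort: IDs, the set
# of informative proteins, and per-protein baseline log-SNR.
protein_params <- function(config) {
  ids <- sprintf("P%04d", seq_len(config$n_proteins))
  withr::with_seed(derive_seed(config$seed, 101L), {
    informative <- sort(sample(ids, config$n_informative))
    baseline <- stats::rnorm(config$n_proteins, 0, config$protein_sdlog)
  })
  names(baseline) <- ids
  list(ids = ids, informative = informative, baseline = baseline)
}

group_codes <- c(HCC = "HCC", cirrhotic = "CIR", healthy = "HLT")

# Spot rows for one sample: channels x proteins x duplicate spots.
sample_spots <- function(config, sample_id, group, params) {
  P <- config$n_proteins
  dup <- config$duplicate_spots
  shift <- numeric(P)
  names(shift) <- params$ids
  if (group == "HCC") {
    shift[params$informative] <- config$effect_size
  } else if (group == "cirrhotic") {
    shift[params$informative] <- config$effect_size * config$cirrhosis_leak
  }
  out <- lapply(config$channels, function(ch) {
    eff <- if (ch == "IgG") shift else numeric(P)
    latent <- params$baseline + eff + stats::rnorm(P, 0, config$noise_sdlog)
    lsnr <- rep(latent, each = dup) +
      stats::rnorm(P * dup, 0, config$spot_sdlog)
    bg <- stats::rgamma(P * dup, shape = config$bg_shape,
                        scale = config$bg_scale)
    data.frame(
      sample_id = sample_id,
      protein_id = rep(params$ids, each = dup),
      spot_index = rep(seq_len(dup), times = P),
      channel = ch,
      fg_median = bg * exp(lsnr),
      bg_median = bg,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Clinical metadata for one sample; draws happen inside the sample's own
# RNG stream, before its spot intensities.
sample_metadata <- function(config, sample_id, group, phase, mix) {
  if (group == "HCC") {
    hi <- stats::runif(1) < mix$w_high
    afp <- if (hi) {
      stats::rlnorm(1, mix$high_meanlog, mix$high_sdlog)
    } else {
      stats::rlnorm(1, mix$low_meanlog, mix$low_sdlog)
    }
    hbsag <- if (stats::runif(1) < config$hbsag_pos_frac) "pos" else "neg"
    stage <- sample(names(config$stage_probs), 1,
                    prob = config$stage_probs)
  } else if (group == "cirrhotic") {
    ap <- config$afp_params
    afp <- stats::rlnorm(1, log(ap$cirrhotic_median), ap$cirrhotic_sdlog)
    hbsag <- if (stats::runif(1) < 0.85) "pos" else "neg"
    stage <- NA_character_
  } else {
    ap <- config$afp_params
    afp <- stats::rlnorm(1, log(ap$healthy_median), ap$healthy_sdlog)
    hbsag <- "neg"
    stage <- NA_character_
  }
  data.frame(sample_id = sample_id, group = group, afp_ng_ml = afp,
             hbsag = hbsag, bclc_stage = stage, phase = phase,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic seromics cohort
#'
#' Simulates spot-level array scans and clinical metadata for a three-group
#' serum cohort under the model described in [sim_config()]. Output is fully
#' deterministic given the configuration: each sample owns an RNG stream
#' derived from (master seed, phase, group, within-group index), so enlarging
#' one group appends new samples without perturbing any existing ones.
#'
#' @param config a [sim_config()] object.
#' @param phase cohort phase label recorded in the metadata
#'   (`"discovery"`, `"test"` or `"validation"`); also keys the RNG streams so
#'   phases are independent cohorts.
#' @param id_prefix prefix for sample IDs; defaults to the first letter of
#'   the phase.
#'
#' @return a list of class `sero_cohort` with elements
#'   \describe{
#'     \item{spots}{data frame of spot rows: `sample_id`, `protein_id`,
#'       `spot_index`, `channel`, `fg_median`, `bg_median`.}
#'     \item{metadata}{data frame: `sample_id`, `group`, `afp_ng_ml`,
#'       `hbsag`, `bclc_stage`, `phase`.}
#'     \item{truth}{character vector of the truly informative protein IDs.}
#'     \item{config, phase}{echo of the inputs.}
#'   }
#' @export
generate_cohort <- function(config,
                            phase = c("test", "validation", "discovery"),
                            id_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  phase <- match.arg(phase)
  if (is.null(id_prefix)) {
    id_prefix <- c(test = "T", validation = "V", discovery = "D")[[phase]]
  }
  phase_key <- match(phase, c("discovery", "test", "validation"))
  params <- protein_params(config)
  mix <- afp_mixture(config$afp_params)

  groups <- c("HCC", "cirrhotic", "healthy")
  sizes <- c(config$n_hcc, config$n_cirrhotic, config$n_healthy)
  spot_chunks <- list()
  meta_chunks <- list()
  k <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (j in seq_len(sizes[gi])) {
      k <- k + 1L
      sid <- sprintf("%s_%s_%03d", id_prefix, group_codes[[g]], j)
      seed_j <- derive_seed(config$seed, phase_key, gi, j)
      withr::with_seed(seed_j, {
        meta_chunks[[k]] <- sample_metadata(config, sid, g, phase, mix)
        spot_chunks[[k]] <- sample_spots(config, sid, g, params)
      })
    }
  }
  spots <- do.call(rbind, spot_chunks)
  metadata <- do.call(rbind, meta_chunks)
  rownames(spots) <- NULL
  rownames(metadata) <- NULL
  structure(list(spots = spots, metadata = metadata,
                 truth = params$informative, config = config, phase = phase),
            class = "sero_cohort")
}

#' @export
print.sero_cohort <- function(x, ...) {
  cat(sprintf(
    "sero_cohort: %d samples (%s phase), %d proteins (%d informative), %d spot rows\n",
    nrow(x$metadata), x$phase, x$config$n_proteins,
    length(x$truth), nrow(x$spots)))
  invisible(x)
}

#' Generate replicate scans of a single serum sample
#'
#' Emulates applying one serum sample to several arrays: every replicate
#' shares one latent per-protein log-SNR profile and differs only by
#' array-level noise. The noise SD is either given directly or calibrated in
#' closed form so that the expected pairwise Pearson correlation of the
#' duplicate-averaged linear-scale SNR profiles equals `target_r`: for
#' log-normal signals with latent log variance v and per-replicate log noise
#' variance t2, r = (exp(v) - 1) / (exp(v + t2) - 1), solved for t2 (the
#' duplicate-averaged spot noise is folded into t2).
#'
#' @param config a [sim_config()] object (protein content and noise model).
#' @param n_replicates number of replicate arrays (>= 2).
#' @param seed seed for the latent profile and replicate noise.
#' @param target_r target mean inter-replicate Pearson correlation; ignored
#'   when `noise_sdlog` is given.
#' @param noise_sdlog optional explicit array-noise SD on the log scale;
#'   `0` yields byte-identical SNR profiles (pairwise r exactly 1).
#' @param group group whose effect profile the latent sample carries
#'   (default `"HCC"`, mimicking a pooled HCC serum).
#'
#' @return list of spot-table data frames, one per replicate, with sample IDs
#'   `REP01`, `REP02`, ...
#' @export
generate_replicate_scans <- function(config, n_replicates, seed = config$seed,
                                     target_r = 0.95, noise_sdlog = NULL,
                                     group = "HCC") {
  stopifnot(inherits(config, "sim_config"))
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  params <- protein_params(config)
  P <- config$n_proteins
  dup <- config$duplicate_spots

  shift <- numeric(P)
  if (group == "HCC") shift[match(params$informative, params$ids)] <-
    config$effect_size
  latent <- withr::with_seed(derive_seed(seed, 555L), {
    params$baseline + shift + stats::rnorm(P, 0, config$noise_sdlog)
  })

  spot_sd <- config$spot_sdlog
  if (is.null(noise_sdlog)) {
    if (target_r <= 0 || target_r > 1) stop("target_r must lie in (0, 1]")
    v <- stats::var(latent)
    t2 <- log((exp(v) - 1) / target_r + 1) - v - spot_sd^2 / dup
    tau <- sqrt(max(t2, 0))
  } else {
    tau <- noise_sdlog
    if (tau == 0) spot_sd <- 0 # exact replicates on the SNR scale
  }

  lapply(seq_len(n_replicates), function(i) {
    withr::with_seed(derive_seed(seed, 556L, i), {
      rep_latent <- latent + stats::rnorm(P, 0, tau)
      lsnr <- rep(rep_latent, each = dup) +
        stats::rnorm(P * dup, 0, spot_sd)
      bg <- stats::rgamma(P * dup, shape = config$bg_shape,
                          scale = config$bg_scale)
      data.frame(
        sample_id = sprintf("REP%02d", i),
        protein_id = rep(params$ids, each = dup),
        spot_index = rep(seq_len(dup), times = P),
        channel = config$channels[1],
        fg_median = bg * exp(lsnr),
        bg_median = bg,
        stringsAsFactors = FALSE
      )
    })
  })
}
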