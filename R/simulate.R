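#' Configuration for the synthetic-study generator
#'
#' The defaults encode the study conditions the pipeline is designed for:
#' the four-batch exposure design of [default_study_design()] with N = 6
#' footprint replicates (N = 4 intracellular), QC injections interleaved
#' every 6 (LC-MS) or 8 (DIMS) study samples, multiplicative injection-order
#' drift, per-batch offsets, heteroscedastic (constant-CV) noise,
#' intensity-dependent left-censoring-like missingness, a planted
#' cardiotoxicity signature (reduced "ceramide-like" and increased
#' "AMP-like" features whose effect grows monotonically with exposure
#' duration and concentration), parent-xenobiotic features proportional to
#' free concentration, and biotransformation-product features at rule mass
#' shifts.
#'
#' @param design A `StudyDesign` (default [default_study_design()]).
#' @param assays Assay table (default [default_assays()]).
#' @param n_features Number of endogenous features per assay.
#' @param n_signature Planted signature features per assay.
#' @param n_signature_up How many of those are increased (the rest decreased).
#' @param effect_max_l2fc Maximum |log2 fold change| of planted features,
#'   reached at 72 h / high concentration.
#' @param duration_scaling Named non-decreasing multipliers of the effect per
#'   duration (hours).
#' @param conc_scaling Named non-decreasing multipliers per concentration level.
#' @param drift_amplitude Log-scale amplitude of the smooth injection-order
#'   drift (0 disables drift).
#' @param batch_sdlog Log-scale SD of per-feature batch offsets.
#' @param residual_cv Residual coefficient of variation of biological samples.
#' @param qc_cv Coefficient of variation of pooled-QC injections.
#' @param blank_fraction Endogenous carry-over intensity in process blanks,
#'   as a fraction of baseline.
#' @param n_contaminants Features planted at full intensity in blanks
#'   (exercises the blank filter).
#' @param missing_mid_log10,missing_width Midpoint and width (log10
#'   intensity) of the logistic missingness model.
#' @param missing_floor_rate Intensity-independent missingness floor rate.
#' @param intracellular_replicates Replicates per exposure group for
#'   intracellular (fingerprint) assays.
#' @param parent_response_per_um Detector response per micromolar of free
#'   parent xenobiotic.
#' @param btp_fraction Biotransformation-product response as a fraction of
#'   the (undecayed) parent response.
#' @param free_fraction Free (dissolved) fraction of the nominal
#'   concentration for most xenobiotics.
#' @param doxorubicin_free_fraction Free fraction for doxorubicin, set below
#'   the detection floor by default so the quantitation-failure path is
#'   exercised.
#' @param idarubicin_half_life Chemical-degradation half-life (hours) of
#'   idarubicin in medium.
#' @param calibration_levels Number of calibration-standard levels per curve.
#' @param calibration_cv Constant relative error of calibration responses.
#' @param seed Integer seed; fully determines all generated output.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(design = default_study_design(),
                              assays = default_assays(),
                              n_features = 1000L,
                              n_signature = 30L,
                              n_signature_up = 10L,
                              effect_max_l2fc = 0.6,
                              duration_scaling = c("6" = 0.25, "48" = 0.8, "72" = 1),
                              conc_scaling = c(low = 0.5, high = 1),
                              drift_amplitude = 0.08,
                              batch_sdlog = 0.15,
                              residual_cv = 0.2,
                              qc_cv = 0.1,
                              blank_fraction = 0.01,
                              n_contaminants = 10L,
                              missing_mid_log10 = 3.7,
                              missing_width = 0.3,
                              missing_floor_rate = 0.01,
                              intracellular_replicates = 4L,
                              parent_response_per_um = 5e5,
                              btp_fraction = 0.5,
                              free_fraction = 0.7,
                              doxorubicin_free_fraction = 0.002,
                              idarubicin_half_life = 48,
                              calibration_levels = 7L,
                              calibration_cv = 0.05,
                              seed = 1L) {
  validate_study_design(design)
  if (is.unsorted(duration_scaling)) {
    stop("duration_scaling must be non-decreasing in duration")
  }
  if (is.unsorted(conc_scaling)) {
    stop("conc_scaling must be non-decreasing (low before high)")
  }
  stopifnot(drift_amplitude >= 0, residual_cv >= 0, qc_cv >= 0,
            n_signature_up <= n_signature,
            n_signature + n_contaminants < n_features,
            calibration_levels >= 5L)
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Free concentration of a xenobiotic in medium
#'
#' Free (dissolved) concentration given nominal level and exposure duration:
#' a xenobiotic-specific free fraction of nominal, with first-order decay for
#' idarubicin and a near-zero fraction for doxorubicin (undetectable by
#' design).
#'
#' @param cfg A `SimulationConfig`.
#' @param xenobiotic Xenobiotic name.
#' @param level `"low"` or `"high"`.
#' @param duration Hours.
#' @return Free concentration in uM.
#' @export
free_concentration <- function(cfg, xenobiotic, level, duration) {
  i <- match(xenobiotic, cfg$design$xenobiotic)
  if (is.na(i)) stop("unknown xenobiotic '", xenobiotic, "'")
  nominal <- if (level == "high") cfg$design$nominal_high[i] else
    cfg$design$nominal_low[i]
  frac <- if (xenobiotic == "doxorubicin") cfg$doxorubicin_free_fraction else
    cfg$free_fraction
  conc <- nominal * frac
  if (xenobiotic == "idarubicin") {
    conc <- conc * 2^(-duration / cfg$idarubicin_half_life)
  }
  conc
}

# Planted biotransformation events: two one-step products per xenobiotic,
# mostly phase I (hydroxylation, demethylation) with occasional phase II
# (glucuronidation, sulfation), mirroring a predominantly phase I system.
planted_btp_plan <- function(design) {
  rules <- c(hydroxylation = "+O", demethylation = "-CH2")
  plan <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    x <- design$xenobiotic[i]
    if (x == "doxorubicin") return(NULL)  # parent below floor; no products
    r1 <- "hydroxylation"
    r2 <- if (x %in% c("erlotinib", "sorafenib")) "glucuronidation" else
      "demethylation"
    data.frame(xenobiotic = x, rule = c(r1, r2), stringsAsFactors = FALSE)
  }))
  rule_tab <- default_btp_rules()
  j <- match(plan$rule, rule_tab$name)
  plan$mass_shift <- rule_tab$mass_shift[j]
  plan$phase <- rule_tab$phase[j]
  plan
}

build_sample_meta <- function(cfg, assay) {
  design <- cfg$design
  durations <- attr(design, "durations")
  n_rep <- if (assay$compartment == "footprint") attr(design, "replicates") else
    cfg$intracellular_replicates
  study <- NULL
  for (b in unique(design$batch)) {
    xb <- design$xenobiotic[design$batch == b]
    bio <- expand.grid(xenobiotic = xb, concentration_level = c("low", "high"),
                       duration = durations, replicate = seq_len(n_rep),
                       stringsAsFactors = FALSE)
    bio$sample_type <- "biological"
    ctl <- expand.grid(xenobiotic = "none", concentration_level = "none",
                       duration = durations, replicate = seq_len(n_rep),
                       stringsAsFactors = FALSE)
    ctl$sample_type <- "control"
    blk <- rbind(bio, ctl)
    blk$batch <- b
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]  # randomised acquisition
    study <- rbind(study, blk)
  }
  # weave QCs and process blanks through the acquisition sequence
  qi <- assay$qc_interval
  rows <- list()
  add <- function(type, batch = "none") {
    data.frame(xenobiotic = "none", concentration_level = "none",
               duration = NA_real_, replicate = NA_integer_,
               sample_type = type, batch = batch, stringsAsFactors = FALSE)
  }
  half <- ceiling(nrow(study) / 2)
  rows[[length(rows) + 1L]] <- add("blank")
  rows[[length(rows) + 1L]] <- add("qc")
  rows[[length(rows) + 1L]] <- add("qc")
  for (i in seq_len(nrow(study))) {
    rows[[length(rows) + 1L]] <- study[i, , drop = FALSE]
    if (i %% qi == 0L) rows[[length(rows) + 1L]] <- add("qc")
    if (i == half) rows[[length(rows) + 1L]] <- add("blank")
  }
  rows[[length(rows) + 1L]] <- add("qc")
  rows[[length(rows) + 1L]] <- add("blank")
  sm <- do.call(rbind, rows)
  sm$injection_order <- seq_len(nrow(sm))
  counters <- stats::ave(seq_len(nrow(sm)), sm$sample_type, FUN = seq_along)
  sm$sample_id <- ifelse(
    sm$sample_type == "biological",
    paste(assay$assay_id, sm$batch, sm$xenobiotic, sm$concentration_level,
          paste0(sm$duration, "h"), paste0("r", sm$replicate), sep = "_"),
    paste(assay$assay_id, sm$sample_type, counters, sep = "_"))
  sm$replicate[sm$sample_type != "biological"] <- counters[sm$sample_type != "biological"]
  rownames(sm) <- NULL
  sm[, c("sample_id", "batch", "xenobiotic", "concentration_level",
         "duration", "replicate", "sample_type", "injection_order")]
}

generate_assay_matrix <- function(cfg, assay, btp_plan) {
  design <- cfg$design
  sm <- build_sample_meta(cfg, assay)
  n_s <- nrow(sm)
  n_f <- cfg$n_features

  # endogenous feature metadata
  mz <- sort(stats::runif(n_f, 70, 1000))
  fm <- data.frame(feature_id = sprintf("%s_F%04d", assay$assay_id, seq_len(n_f)),
                   mz = mz,
                   rt = if (assay$has_rt) stats::runif(n_f, 60, 900) else NA_real_,
                   polarity = assay$polarity,
                   assay_id = assay$assay_id,
                   stringsAsFactors = FALSE)

  idx <- sample.int(n_f, cfg$n_signature + cfg$n_contaminants)
  sig_idx <- idx[seq_len(cfg$n_signature)]
  contam_idx <- idx[cfg$n_signature + seq_len(cfg$n_contaminants)]
  direction <- rep(-1, cfg$n_signature)
  if (cfg$n_signature_up > 0) {
    direction[seq_len(cfg$n_signature_up)] <- 1
  }
  direction <- direction[sample.int(cfg$n_signature)]

  baseline <- stats::rlnorm(n_f, meanlog = log(1e5), sdlog = 1.2)
  batches <- unique(design$batch)
  batch_offset <- matrix(stats::rlnorm(n_f * length(batches), 0, cfg$batch_sdlog),
                         n_f, length(batches), dimnames = list(NULL, batches))

  # smooth shared drift shape, per-feature amplitude and sign
  u <- (sm$injection_order - 1) / max(1, n_s - 1)
  shape_coef <- stats::rnorm(3)
  phase <- stats::runif(1, 0, 2 * pi)
  g <- shape_coef[1] * u + shape_coef[2] * u^2 +
    shape_coef[3] * sin(2 * pi * u + phase)
  if (stats::sd(g) > 0) g <- (g - mean(g)) / stats::sd(g)
  amp <- cfg$drift_amplitude * stats::runif(n_f, 0.5, 1.5) *
    sample(c(-1, 1), n_f, replace = TRUE)
  log_drift <- outer(amp, g)  # features x samples

  # condition effect of the planted signature (log2 fold change scale)
  sct <- design$xenobiotic[design$is_sct]
  eff_l2 <- matrix(0, n_f, n_s)
  is_sct_sample <- sm$sample_type == "biological" & sm$xenobiotic %in% sct
  if (any(is_sct_sample) && cfg$n_signature > 0) {
    dsc <- cfg$duration_scaling[as.character(sm$duration)]
    csc <- cfg$conc_scaling[sm$concentration_level]
    scale_s <- ifelse(is_sct_sample, dsc * csc, 0)
    scale_s[is.na(scale_s)] <- 0
    eff_l2[sig_idx, ] <- outer(direction * cfg$effect_max_l2fc, scale_s)
  }

  sdlog_bio <- sqrt(log(1 + cfg$residual_cv^2))
  sdlog_qc <- sqrt(log(1 + cfg$qc_cv^2))
  is_qc <- sm$sample_type == "qc"
  is_blank <- sm$sample_type == "blank"
  is_study <- !is_qc & !is_blank

  logx <- matrix(log(baseline), n_f, n_s)
  bo <- log(batch_offset[, match(sm$batch, batches), drop = FALSE])
  bo[, !is_study | sm$batch == "none"] <- 0
  logx <- logx + bo + log_drift + eff_l2 * log(2)
  logx[, is_blank] <- log(baseline * cfg$blank_fraction)
  logx[contam_idx, is_blank] <- log(baseline[contam_idx])
  noise_sd <- matrix(sdlog_bio, n_f, n_s)
  noise_sd[, is_qc] <- sdlog_qc
  logx <- logx + matrix(stats::rnorm(n_f * n_s), n_f, n_s) * noise_sd
  x <- exp(logx)

  # xenobiotic-related features: one parent + planted products per xenobiotic
  pol <- assay$polarity
  parent_adduct <- if (pol == "positive") "[M+H]+" else "[M-H]-"
  parent_rows <- list(); parent_meta <- list()
  truth_parents <- NULL; truth_btps <- NULL
  for (i in seq_len(nrow(design))) {
    xeno <- design$xenobiotic[i]
    M <- monoisotopic_mass(design$formula[i])
    exposed <- sm$sample_type == "biological" & sm$xenobiotic == xeno
    conc <- rep(0, n_s)
    conc[exposed] <- mapply(function(l, d) free_concentration(cfg, xeno, l, d),
                            sm$concentration_level[exposed],
                            sm$duration[exposed])
    resp <- conc * cfg$parent_response_per_um *
      exp(stats::rnorm(n_s, 0, sdlog_bio))
    resp[!exposed] <- 0
    fid <- sprintf("%s_parent_%s", assay$assay_id, xeno)
    parent_rows[[fid]] <- resp
    parent_meta[[fid]] <- data.frame(
      feature_id = fid, mz = expected_ion_mz(M, parent_adduct),
      rt = if (assay$has_rt) stats::runif(1, 60, 900) else NA_real_,
      polarity = pol, assay_id = assay$assay_id, stringsAsFactors = FALSE)
    detectable <- xeno != "doxorubicin"
    truth_parents <- rbind(truth_parents, data.frame(
      xenobiotic = xeno, feature_id = fid, neutral_mass = M,
      adduct = parent_adduct, detectable = detectable,
      stringsAsFactors = FALSE))
    bp <- btp_plan[btp_plan$xenobiotic == xeno, , drop = FALSE]
    for (j in seq_len(nrow(bp))) {
      # products scale with the free (undecayed) parent fraction of nominal
      nom <- ifelse(sm$concentration_level[exposed] == "high",
                    design$nominal_high[i], design$nominal_low[i])
      bresp <- rep(0, n_s)
      bresp[exposed] <- nom * cfg$free_fraction * cfg$parent_response_per_um *
        cfg$btp_fraction * exp(stats::rnorm(sum(exposed), 0, sdlog_bio))
      bmass <- M + bp$mass_shift[j]
      bfid <- sprintf("%s_btp_%s_%s", assay$assay_id, xeno, bp$rule[j])
      parent_rows[[bfid]] <- bresp
      parent_meta[[bfid]] <- data.frame(
        feature_id = bfid, mz = expected_ion_mz(bmass, parent_adduct),
        rt = if (assay$has_rt) stats::runif(1, 60, 900) else NA_real_,
        polarity = pol, assay_id = assay$assay_id, stringsAsFactors = FALSE)
      truth_btps <- rbind(truth_btps, data.frame(
        xenobiotic = xeno, feature_id = bfid, rule = bp$rule[j],
        phase = bp$phase[j], neutral_mass = bmass, adduct = parent_adduct,
        stringsAsFactors = FALSE))
    }
  }
  x <- rbind(x, do.call(rbind, parent_rows))
  fm <- rbind(fm, do.call(rbind, parent_meta))
  rownames(x) <- fm$feature_id
  colnames(x) <- sm$sample_id

  # intensity-dependent missingness (left-censoring-like) plus a floor rate
  p_miss <- stats::plogis(-(log10(pmax(x, 1e-12)) - cfg$missing_mid_log10) /
                            cfg$missing_width)
  p_miss <- p_miss + cfg$missing_floor_rate
  drop <- matrix(stats::runif(length(x)), nrow(x)) < p_miss
  x[drop] <- NA_real_
  x[x == 0] <- NA_real_  # a zero response is an absent peak here

  pm <- peak_matrix(x, fm, sm)
  truth <- list(
    signature = data.frame(feature_id = fm$feature_id[sig_idx],
                           direction = direction,
                           max_l2fc = direction * cfg$effect_max_l2fc,
                           stringsAsFactors = FALSE),
    contaminants = fm$feature_id[contam_idx],
    parents = truth_parents,
    btps = truth_btps,
    null_features = setdiff(fm$feature_id[seq_len(n_f)],
                            fm$feature_id[c(sig_idx, contam_idx)])
  )
  list(pm = pm, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Produces one `PeakMatrix` per analytical assay with the design's
#' biological and control samples, interleaved QCs and process blanks, plus
#' the planted ground truth and a calibration dataset for the quantitation
#' stage. The same seed always yields identical output.
#'
#' @param cfg A `SimulationConfig`.
#' @return A list with elements `matrices` (named list of `PeakMatrix`),
#'   `truth` (per-assay planted truth), `calibration` (see
#'   [generate_calibration_series()]), `design`, `config`.
#' @export
generate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  btp_plan <- planted_btp_plan(cfg$design)
  matrices <- list(); truth <- list()
  for (i in seq_len(nrow(cfg$assays))) {
    assay <- as.list(cfg$assays[i, ])
    res <- generate_assay_matrix(cfg, assay, btp_plan)
    matrices[[assay$assay_id]] <- res$pm
    truth[[assay$assay_id]] <- res$truth
  }
  calibration <- generate_calibration_series(cfg, seed = cfg$seed + 1000L)
  list(matrices = matrices, truth = truth, calibration = calibration,
       design = cfg$design, config = cfg)
}

#' Generate calibration standards, quant-QCs and study-sample responses
#'
#' For each xenobiotic: calibration standards at geometrically spaced levels
#' spanning the nominal range, with linear response and constant relative
#' (1/x^2-appropriate) noise; duplicate quant-QCs at the nominal low and
#' high concentrations for the start and end of the exposure-batch block;
#' quantitation blanks; and responses of the biological footprint samples
#' and stability controls at their true free concentrations.
#'
#' @param cfg A `SimulationConfig`.
#' @param seed Integer seed (defaults to `cfg$seed + 1000`).
#' @param n_stability Stability-control replicates per duration.
#' @return A list of data.frames: `standards` (`xenobiotic`, `occasion`,
#'   `nominal`, `response`), `quant_qcs`, `blanks`, `samples` (biological and
#'   stability-control responses with true concentrations), and `truth`
#'   (per-xenobiotic response slope).
#' @export
generate_calibration_series <- function(cfg, seed = cfg$seed + 1000L,
                                        n_stability = 3L) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(seed)
  design <- cfg$design
  durations <- attr(design, "durations")
  n_rep <- attr(design, "replicates")
  rel_noise <- function(n) exp(stats::rnorm(n, 0, sqrt(log(1 + cfg$calibration_cv^2))))
  standards <- NULL; qqcs <- NULL; samples <- NULL
  slopes <- stats::setNames(stats::runif(nrow(design), 5e4, 5e5),
                            design$xenobiotic)
  for (i in seq_len(nrow(design))) {
    xeno <- design$xenobiotic[i]
    lo <- design$nominal_low[i]; hi <- design$nominal_high[i]
    if (lo <= 0) stop("non-positive concentration level for ", xeno)
    levels <- exp(seq(log(lo / 3), log(hi * 2),
                      length.out = cfg$calibration_levels))
    slope <- slopes[[xeno]]
    for (occ in c("start", "end")) {
      standards <- rbind(standards, data.frame(
        xenobiotic = xeno, occasion = occ, nominal = levels,
        response = slope * levels * rel_noise(length(levels)),
        stringsAsFactors = FALSE))
      for (nom in c(lo, hi)) {
        qqcs <- rbind(qqcs, data.frame(
          xenobiotic = xeno, occasion = occ, nominal = nom,
          replicate = 1:2, response = slope * nom * rel_noise(2),
          stringsAsFactors = FALSE))
      }
    }
    grid <- expand.grid(concentration_level = c("low", "high"),
                        duration = durations, replicate = seq_len(n_rep),
                        stringsAsFactors = FALSE)
    true_conc <- mapply(function(l, d) free_concentration(cfg, xeno, l, d),
                        grid$concentration_level, grid$duration)
    grid2 <- expand.grid(concentration_level = "high", duration = durations,
                         replicate = seq_len(n_stability),
                         stringsAsFactors = FALSE)
    stab_conc <- mapply(function(l, d) free_concentration(cfg, xeno, l, d),
                        grid2$concentration_level, grid2$duration)
    samples <- rbind(samples,
      data.frame(xenobiotic = xeno, sample_type = "biological", grid,
                 true_concentration = true_conc,
                 response = slopes[[xeno]] * true_conc * rel_noise(nrow(grid)),
                 stringsAsFactors = FALSE),
      data.frame(xenobiotic = xeno, sample_type = "stability_control", grid2,
                 true_concentration = stab_conc,
                 response = slopes[[xeno]] * stab_conc * rel_noise(nrow(grid2)),
                 stringsAsFactors = FALSE))
  }
  blanks <- data.frame(xenobiotic = rep(design$xenobiotic, each = 2L),
                       occasion = rep(c("start", "end"), nrow(design)),
                       response = 0, stringsAsFactors = FALSE)
  list(standards = standards, quant_qcs = qqcs, blanks = blanks,
       samples = samples, truth = list(slopes = slopes))
}
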