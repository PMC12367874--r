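#' Preprocessing configuration
#'
#' @param blank_fold_min Minimum fold of median biological over median blank
#'   intensity for a feature to survive the blank filter (default 10).
#' @param detection_rate_min Minimum within-class detection rate (default 0.5).
#' @param qc_rsd_max Maximum QC relative standard deviation in percent
#'   (default 30).
#' @param qc_min_count Minimum QC observations for spline drift correction
#'   (default 5).
#' @param knn_k Neighbours for KNN imputation (default 5).
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(blank_fold_min = 10, detection_rate_min = 0.5,
                              qc_rsd_max = 30, qc_min_count = 5L, knn_k = 5L) {
  stopifnot(blank_fold_min > 0, detection_rate_min > 0, detection_rate_min <= 1,
            qc_rsd_max > 0, qc_min_count >= 4L, knn_k >= 1L)
  structure(list(blank_fold_min = blank_fold_min,
                 detection_rate_min = detection_rate_min,
                 qc_rsd_max = qc_rsd_max, qc_min_count = qc_min_count,
                 knn_k = knn_k),
            class = "PreprocessConfig")
}

row_median <- function(x) apply(x, 1L, stats::median, na.rm = TRUE)

#' Remove features attributable to the process blanks
#'
#' A feature is removed when its median intensity in biological samples is
#' less than `blank_fold_min` times its median intensity in blanks. Features
#' absent from every blank are retained. Without any blank sample the step
#' is skipped with a warning.
#'
#' @param pm A `PeakMatrix` containing blank samples.
#' @param blank_fold_min Fold threshold (default from [preprocess_config()]).
#' @return List with `pm` (filtered matrix) and `removed` (feature ids).
#' @export
blank_filter <- function(pm, blank_fold_min = 10) {
  validate_peak_matrix(pm)
  is_blank <- pm$sample_meta$sample_type == "blank"
  if (!any(is_blank)) {
    warning("no blank samples: blank filter skipped")
    return(list(pm = pm, removed = character(0)))
  }
  is_bio <- pm$sample_meta$sample_type %in% c("biological", "control")
  med_blank <- row_median(pm$intensities[, is_blank, drop = FALSE])
  med_bio <- row_median(pm$intensities[, is_bio, drop = FALSE])
  absent_blank <- is.na(med_blank)
  remove <- !absent_blank & (is.na(med_bio) | med_bio < blank_fold_min * med_blank)
  keep_ids <- pm$feature_meta$feature_id[!remove]
  list(pm = subset_peak_matrix(pm, features = feature_id %in% keep_ids),
       removed = pm$feature_meta$feature_id[remove])
}

#' QC-based robust spline correction of injection-order drift
#'
#' Per feature, a robust cubic smoothing spline is fitted to the
#' log-intensities of the QC injections against injection order (smoothing
#' selected by leave-one-out cross-validation; robustness by iterative
#' down-weighting of outlying QCs). Every sample's intensity is divided by
#' the interpolated drift multiplier, then rescaled so the feature's overall
#' median is preserved exactly. Features observed in fewer than
#' `qc_min_count` QCs pass through uncorrected and flagged.
#'
#' @param pm A `PeakMatrix` with QC samples.
#' @param qc_min_count Minimum QC observations (default 5).
#' @param robust_iterations Reweighting iterations (default 3).
#' @return List with `pm` (corrected matrix) and `report`: per-feature
#'   `corrected` flag, reason when uncorrected, QC RSD before/after (%),
#'   and residual Pearson correlation of corrected QC intensity with order.
#' @export
qc_rsc <- function(pm, qc_min_count = 5L, robust_iterations = 3L) {
  validate_peak_matrix(pm)
  is_qc <- pm$sample_meta$sample_type == "qc"
  if (!any(is_qc)) stop("qc_rsc: no QC samples; drift correction impossible")
  ord <- pm$sample_meta$injection_order
  x <- pm$intensities
  n_f <- nrow(x)
  report <- data.frame(feature_id = pm$feature_meta$feature_id,
                       corrected = FALSE, reason = "",
                       qc_rsd_before = NA_real_, qc_rsd_after = NA_real_,
                       residual_qc_order_r = NA_real_,
                       stringsAsFactors = FALSE)
  rsd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v) * 100
  }
  for (f in seq_len(n_f)) {
    qv <- x[f, is_qc]
    obs <- !is.na(qv) & qv > 0
    report$qc_rsd_before[f] <- rsd(qv)
    if (sum(obs) < qc_min_count) {
      report$reason[f] <- sprintf("only %d QC observations (< %d)",
                                  sum(obs), qc_min_count)
      next
    }
    qo <- ord[is_qc][obs]
    ly <- log(qv[obs])
    fit <- select_drift_spline(qo, ly, robust_iterations)
    if (is.null(fit)) {
      # the constant model wins the LOO comparison: no evidence of drift,
      # identity correction (explicit no-harm behaviour)
      report$corrected[f] <- TRUE
      report$reason[f] <- "no drift detected; identity correction"
      report$qc_rsd_after[f] <- report$qc_rsd_before[f]
      qa <- x[f, is_qc]
      ok <- !is.na(qa)
      if (sum(ok) >= 3 && stats::sd(qa[ok]) > 0) {
        report$residual_qc_order_r[f] <- stats::cor(ord[is_qc][ok], qa[ok])
      }
      next
    }
    drift_log <- stats::predict(fit, ord)$y
    # clamp extrapolation beyond the QC-covered range
    drift_log <- pmin(pmax(drift_log, min(stats::predict(fit, qo)$y) - 1),
                      max(stats::predict(fit, qo)$y) + 1)
    mult <- exp(drift_log - mean(drift_log))
    before <- x[f, ]
    after <- before / mult
    med_before <- stats::median(before, na.rm = TRUE)
    med_after <- stats::median(after, na.rm = TRUE)
    if (!is.na(med_after) && med_after > 0) {
      after <- after * (med_before / med_after)
    }
    x[f, ] <- after
    report$corrected[f] <- TRUE
    report$qc_rsd_after[f] <- rsd(after[is_qc])
    qa <- after[is_qc]
    ok <- !is.na(qa)
    if (sum(ok) >= 3 && stats::sd(qa[ok]) > 0) {
      report$residual_qc_order_r[f] <- stats::cor(ord[is_qc][ok], qa[ok])
    }
  }
  pm$intensities <- x
  list(pm = pm, report = report)
}

# Smoothing selection for QC-RSC: cubic smoothing splines over an 11-value
# grid of smoothing parameters (linear in spar = log-spaced in lambda),
# scored by exact leave-one-out CV via smoother leverages, competing against
# a constant (drift-free) model with a 20% improvement margin. Robustness:
# Tukey-bisquare reweighting at the selected smoothing.
select_drift_spline <- function(qo, ly, robust_iterations = 3L,
                                spars = seq(0.1, 1.5, length.out = 11L),
                                margin = 0.8) {
  n <- length(ly)
  loo_const <- mean(((ly - mean(ly)) * n / (n - 1))^2)
  best <- list(loo = Inf, spar = NA_real_, fit = NULL)
  for (s in spars) {
    fit <- tryCatch(stats::smooth.spline(qo, ly, spar = s, keep.data = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pr <- stats::predict(fit, qo)$y
    lev <- fit$lev
    if (any(lev > 0.999)) next
    loo <- mean(((ly - pr) / (1 - lev))^2)
    if (loo < best$loo) best <- list(loo = loo, spar = s, fit = fit)
  }
  if (!is.finite(best$loo) || best$loo >= margin * loo_const) return(NULL)
  fit <- best$fit
  w <- rep(1, n)
  for (it in seq_len(robust_iterations)) {
    res <- ly - stats::predict(fit, qo)$y
    s_mad <- stats::mad(res)
    if (s_mad <= 0) break
    u <- pmin(abs(res) / (4.685 * s_mad), 1)
    w <- pmax((1 - u^2)^2, 1e-6)
    refit <- tryCatch(
      stats::smooth.spline(qo, ly, w = w, spar = best$spar, keep.data = FALSE),
      error = function(e) NULL)
    if (is.null(refit)) break
    fit <- refit
  }
  fit
}

#' Remove features with unstable QC measurements
#'
#' Removes features whose relative standard deviation across QC injections
#' exceeds `qc_rsd_max` percent. With fewer than 3 QCs the step is skipped
#' with a warning.
#'
#' @param pm A `PeakMatrix`.
#' @param qc_rsd_max RSD threshold in percent (default 30).
#' @return List with `pm` and `removed` feature ids.
#' @export
qc_rsd_filter <- function(pm, qc_rsd_max = 30) {
  validate_peak_matrix(pm)
  is_qc <- pm$sample_meta$sample_type == "qc"
  if (sum(is_qc) < 3L) {
    warning("fewer than 3 QC samples: RSD filter skipped")
    return(list(pm = pm, removed = character(0)))
  }
  q <- pm$intensities[, is_qc, drop = FALSE]
  rsd <- apply(q, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v) * 100
  })
  remove <- !is.na(rsd) & rsd > qc_rsd_max
  keep_ids <- pm$feature_meta$feature_id[!remove]
  list(pm = subset_peak_matrix(pm, features = feature_id %in% keep_ids),
       removed = pm$feature_meta$feature_id[remove])
}

#' Remove sparsely detected features
#'
#' A feature is retained when observed in at least `detection_rate_min` of
#' the samples of at least one exposure-condition class (xenobiotic x
#' concentration x duration, controls stratified by batch x duration), or in
#' at least that fraction of the QC samples.
#'
#' @param pm A `PeakMatrix`.
#' @param detection_rate_min Minimum within-class detection rate (default 0.5).
#' @return List with `pm` and `removed` feature ids.
#' @export
detection_filter <- function(pm, detection_rate_min = 0.5) {
  validate_peak_matrix(pm)
  sm <- pm$sample_meta
  cls <- ifelse(sm$sample_type == "biological",
                paste(sm$xenobiotic, sm$concentration_level, sm$duration),
                ifelse(sm$sample_type == "control",
                       paste("control", sm$batch, sm$duration),
                       ifelse(sm$sample_type == "qc", "qc", NA)))
  keep <- rep(FALSE, nrow(pm$intensities))
  for (cl in unique(cls[!is.na(cls)])) {
    in_cl <- which(!is.na(cls) & cls == cl)
    rate <- rowMeans(!is.na(pm$intensities[, in_cl, drop = FALSE]))
    keep <- keep | rate >= detection_rate_min
  }
  keep_ids <- pm$feature_meta$feature_id[keep]
  list(pm = subset_peak_matrix(pm, features = feature_id %in% keep_ids),
       removed = pm$feature_meta$feature_id[!keep])
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' Neighbours are samples; distances are Euclidean over log-scale values of
#' the features observed in both samples (scaled by the number of shared
#' features, so samples with different overlap are comparable). Each missing
#' cell is replaced by the mean of the (log-scale) values of the `k` nearest
#' samples in which that feature is observed, back-transformed. Observed
#' cells are untouched. A sample sharing no observed features with any
#' other falls back to the feature median and is flagged.
#'
#' @param pm A `PeakMatrix` whose observed intensities are strictly positive.
#' @param k Number of neighbours (default 5).
#' @return List with `pm` (complete matrix) and `fallback_samples`.
#' @export
impute_knn <- function(pm, k = 5L) {
  validate_peak_matrix(pm)
  x <- pm$intensities
  if (any(x <= 0, na.rm = TRUE)) stop("impute_knn: non-positive intensities")
  lx <- log2(x)
  n_s <- ncol(lx)
  obs <- !is.na(lx)
  if (any(rowSums(obs) == 0L)) {
    stop("impute_knn: feature(s) observed nowhere: ",
         toString(pm$feature_meta$feature_id[rowSums(obs) == 0L]))
  }
  # mean squared difference over shared features as the scaled distance
  d2 <- matrix(Inf, n_s, n_s)
  for (i in seq_len(n_s)) {
    shared <- obs[, i] & obs
    diff2 <- (lx[, i] - lx)^2
    diff2[!shared] <- NA
    n_shared <- colSums(shared)
    msd <- colSums(diff2, na.rm = TRUE) / n_shared
    msd[n_shared == 0L] <- Inf
    d2[i, ] <- msd
  }
  diag(d2) <- Inf
  fallback <- character(0)
  out <- lx
  feat_med <- apply(lx, 1L, stats::median, na.rm = TRUE)
  for (s in seq_len(n_s)) {
    miss_f <- which(!obs[, s])
    if (!length(miss_f)) next
    if (all(!is.finite(d2[s, ]))) {
      out[miss_f, s] <- feat_med[miss_f]
      fallback <- c(fallback, pm$sample_meta$sample_id[s])
      next
    }
    for (f in miss_f) {
      donors <- which(obs[f, ] & is.finite(d2[s, ]))
      if (!length(donors)) {
        out[f, s] <- feat_med[f]
        next
      }
      nn <- donors[order(d2[s, donors])][seq_len(min(k, length(donors)))]
      out[f, s] <- mean(lx[f, nn])
    }
  }
  imp <- pm$intensities
  imp[!obs] <- 2^out[!obs]  # observed cells stay bit-identical
  pm$intensities <- imp
  list(pm = pm, fallback_samples = unique(fallback))
}

#' Log2 transform and per-sample unit-norm scaling
#'
#' Log2-transforms all intensities, then scales every sample vector to unit
#' Euclidean norm over features (vector normalisation). Observed
#' non-positive values are an error naming the offending cell.
#'
#' @param pm A `PeakMatrix`.
#' @return The transformed `PeakMatrix` (values are normalised log2
#'   intensities, no longer raw; negative values are permitted downstream).
#' @export
transform_normalise <- function(pm) {
  validate_peak_matrix(pm)
  x <- pm$intensities
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive intensity at feature '", rownames(x)[bad[1, 1]],
         "', sample '", colnames(x)[bad[1, 2]], "'")
  }
  lx <- log2(x)
  norms <- sqrt(colSums(lx^2, na.rm = TRUE))
  if (any(norms == 0)) stop("sample with zero norm")
  lx <- sweep(lx, 2L, norms, "/")
  out <- pm
  out$intensities <- lx
  # normalised log2 data may be negative; bypass non-negativity validation
  structure(out, class = "PeakMatrix", normalised = TRUE)
}

#' Normalise exposed samples against matched controls
#'
#' Each biological sample's intensities are divided by the per-feature
#' median over the control samples of the same batch and exposure duration.
#' Features whose control median is missing or zero in any required stratum
#' are dropped and logged. Control samples are consumed by this step: the
#' result contains only biological samples (relative responses).
#'
#' @param pm A `PeakMatrix` with biological and control samples.
#' @param min_controls Minimum controls per (batch, duration) stratum
#'   (default 3).
#' @return List with `pm` (relative responses, biological samples only) and
#'   `dropped_features`.
#' @export
control_normalise <- function(pm, min_controls = 3L) {
  validate_peak_matrix(pm)
  sm <- pm$sample_meta
  bio <- which(sm$sample_type == "biological")
  if (!length(bio)) stop("control_normalise: no biological samples")
  strata <- unique(sm[bio, c("batch", "duration")])
  x <- pm$intensities
  rel <- x[, bio, drop = FALSE]
  ok_feature <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(strata))) {
    b <- strata$batch[i]; d <- strata$duration[i]
    ctl <- which(sm$sample_type == "control" & sm$batch == b & sm$duration == d)
    if (length(ctl) < min_controls) {
      stop("control_normalise: stratum batch ", b, " / ", d,
           " h has ", length(ctl), " controls (< ", min_controls, ")")
    }
    med <- row_median(x[, ctl, drop = FALSE])
    bad <- is.na(med) | med == 0
    ok_feature <- ok_feature & !bad
    cols <- which(sm$batch[bio] == b & sm$duration[bio] == d)
    rel[, cols] <- x[, bio[cols], drop = FALSE] / med
  }
  out <- peak_matrix(
    rel[ok_feature, , drop = FALSE],
    pm$feature_meta[ok_feature, , drop = FALSE],
    sm[bio, , drop = FALSE])
  list(pm = out,
       dropped_features = pm$feature_meta$feature_id[!ok_feature])
}

#' Run the full preprocessing pipeline on one assay matrix
#'
#' Applies, in the contracted order: blank removal, xenobiotic-feature
#' removal, QC-based drift correction, QC RSD and detection filters, then
#' per analysis branch either (univariate) log2 transform of the filtered
#' intensities, or (multivariate) control normalisation, log2, KNN
#' imputation and vector normalisation. The applied order and parameters
#' are recorded in the returned provenance.
#'
#' @param pm A `PeakMatrix`.
#' @param branch `"multivariate"` (control-normalised responses for model
#'   training) or `"univariate"` (filtered log2 intensities; comparisons are
#'   made against matched controls downstream).
#' @param xeno_features Feature ids to remove as xenobiotic-related.
#' @param config A `PreprocessConfig`.
#' @param drift_correct Apply QC-RSC (default TRUE; disable for matrices
#'   without meaningful injection-order structure).
#' @return List with `pm` (processed matrix), `reports` (per-step logs) and
#'   `provenance` (ordered record of applied steps and parameters).
#' @export
preprocess_pipeline <- function(pm, branch = c("multivariate", "univariate"),
                                xeno_features = character(0),
                                config = preprocess_config(),
                                drift_correct = TRUE) {
  branch <- match.arg(branch)
  steps <- list(); reports <- list()
  bf <- blank_filter(pm, config$blank_fold_min)
  pm <- bf$pm
  reports$blank_filter <- bf$removed
  steps <- c(steps, list(list(step = "blank_filter",
                              blank_fold_min = config$blank_fold_min)))
  if (length(xeno_features)) {
    keep <- setdiff(pm$feature_meta$feature_id, xeno_features)
    pm <- subset_peak_matrix(pm, features = feature_id %in% keep)
    steps <- c(steps, list(list(step = "xenobiotic_feature_removal",
                                n_removed = length(xeno_features))))
  }
  if (drift_correct) {
    dc <- qc_rsc(pm, config$qc_min_count)
    pm <- dc$pm
    reports$qc_rsc <- dc$report
    steps <- c(steps, list(list(step = "qc_rsc",
                                qc_min_count = config$qc_min_count)))
  }
  rf <- qc_rsd_filter(pm, config$qc_rsd_max)
  pm <- rf$pm
  reports$qc_rsd_filter <- rf$removed
  steps <- c(steps, list(list(step = "qc_rsd_filter",
                              qc_rsd_max = config$qc_rsd_max)))
  df <- detection_filter(pm, config$detection_rate_min)
  pm <- df$pm
  reports$detection_filter <- df$removed
  steps <- c(steps, list(list(step = "detection_filter",
                              detection_rate_min = config$detection_rate_min)))
  if (branch == "multivariate") {
    cn <- control_normalise(pm)
    pm <- cn$pm
    reports$control_normalise <- cn$dropped_features
    im <- impute_knn(pm, config$knn_k)
    # log2 happens inside transform_normalise; imputation operates on log2
    # values internally, preserving the contracted order
    pm <- transform_normalise(im$pm)
    reports$impute_knn <- im$fallback_samples
    steps <- c(steps, list(list(step = "control_normalise"),
                           list(step = "log2_knn_impute", k = config$knn_k),
                           list(step = "vector_normalise")))
  } else {
    keep <- pm$sample_meta$sample_type %in% c("biological", "control")
    keep_ids <- pm$sample_meta$sample_id[keep]
    pm <- subset_peak_matrix(pm, samples = sample_id %in% keep_ids)
    x <- pm$intensities
    if (any(x <= 0, na.rm = TRUE)) stop("non-positive intensity before log2")
    pm$intensities <- log2(x)
    pm <- structure(pm, class = "PeakMatrix", normalised = TRUE)
    steps <- c(steps, list(list(step = "log2")))
  }
  list(pm = pm, reports = reports, provenance = steps)
}
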