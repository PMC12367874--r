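#' Welch's two-sample t-test
#'
#' Two-tailed Welch test (unequal variances, Satterthwaite degrees of
#' freedom). Groups with fewer than 2 observed values, or zero variance in
#' both groups, are flagged untestable rather than erroring.
#'
#' @param a,b Numeric vectors (`NA` dropped).
#' @return List with `t`, `df`, `p`, `testable`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, testable = FALSE))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, testable = FALSE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, testable = TRUE)
}

#' Signed log2 fold change of medians
#'
#' `log2(median(exposed) / median(control))` on raw (pre-log) intensities.
#'
#' @param exposed,control Numeric vectors of raw intensities (`NA` dropped).
#' @return List with `l2fc` and `computable`.
#' @export
log2_fc <- function(exposed, control) {
  me <- stats::median(exposed, na.rm = TRUE)
  mc <- stats::median(control, na.rm = TRUE)
  if (is.na(me) || is.na(mc) || me <= 0 || mc <= 0) {
    return(list(l2fc = NA_real_, computable = FALSE))
  }
  list(l2fc = log2(me / mc), computable = TRUE)
}

#' Condition-wise univariate scan against matched controls
#'
#' For every exposure condition (xenobiotic x concentration level x
#' duration), Welch-tests each feature's log2 intensities in the exposed
#' samples against the batch- and duration-matched controls, and computes
#' the log2 fold change of raw-intensity medians. Returns the tidy result
#' table plus per-condition counts of features significant at p < 0.01 (no
#' multiple-testing correction in the counts; a Benjamini-Hochberg column is
#' emitted alongside for reference) and the signed log2 fold-change matrix
#' thresholded at p < 0.05.
#'
#' @param pm A `PeakMatrix` whose intensities are log2 values (univariate
#'   preprocessing branch); raw intensities for fold changes are recovered
#'   as `2^x`.
#' @param design A `StudyDesign`.
#' @return List with `results` (per feature x condition), `counts` (per
#'   condition: n significant at p < 0.01), `fc_matrix` (features x
#'   conditions, log2 FC where p < 0.05, else `NA`), `skipped`.
#' @export
condition_scan <- function(pm, design) {
  validate_peak_matrix(pm)
  validate_study_design(design)
  sm <- pm$sample_meta
  x <- pm$intensities
  raw <- 2^x
  conds <- enumerate_conditions(design)
  n_f <- nrow(x)
  res <- list(); skipped <- NULL
  fc_mat <- matrix(NA_real_, n_f, nrow(conds),
                   dimnames = list(pm$feature_meta$feature_id,
                                   paste(conds$xenobiotic,
                                         conds$concentration_level,
                                         conds$duration, sep = "_")))
  counts <- data.frame(conds, n_sig_p01 = NA_integer_, n_testable = NA_integer_)
  for (ci in seq_len(nrow(conds))) {
    cc <- conds[ci, ]
    exposed <- which(sm$sample_type == "biological" &
                       sm$xenobiotic == cc$xenobiotic &
                       sm$concentration_level == cc$concentration_level &
                       sm$duration == cc$duration)
    control <- which(sm$sample_type == "control" &
                       sm$batch == cc$batch & sm$duration == cc$duration)
    if (length(exposed) < 2L || length(control) < 2L) {
      skipped <- rbind(skipped, data.frame(
        cc, reason = "missing exposed or control stratum"))
      next
    }
    t_v <- df_v <- p_v <- fc_v <- rep(NA_real_, n_f)
    testable <- rep(FALSE, n_f)
    for (f in seq_len(n_f)) {
      wt <- welch_t(x[f, exposed], x[f, control])
      testable[f] <- wt$testable
      if (wt$testable) {
        t_v[f] <- wt$t; df_v[f] <- wt$df; p_v[f] <- wt$p
      }
      fc <- log2_fc(raw[f, exposed], raw[f, control])
      if (fc$computable) fc_v[f] <- fc$l2fc
    }
    counts$n_sig_p01[ci] <- sum(p_v < 0.01, na.rm = TRUE)
    counts$n_testable[ci] <- sum(testable)
    fc_mat[, ci] <- ifelse(!is.na(p_v) & p_v < 0.05, fc_v, NA_real_)
    res[[ci]] <- data.frame(
      feature_id = pm$feature_meta$feature_id,
      xenobiotic = cc$xenobiotic,
      concentration_level = cc$concentration_level,
      duration = cc$duration, is_sct = cc$is_sct,
      t = t_v, df = df_v, p = p_v,
      p_bh = stats::p.adjust(p_v, method = "BH"),
      l2fc = fc_v, testable = testable,
      n_exposed = length(exposed), n_control = length(control),
      stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, res), counts = counts,
       fc_matrix = fc_mat, skipped = skipped)
}

#' Perturbations conserved across structural cardiotoxins
#'
#' Features significant (p < 0.05) with a consistent fold-change direction
#' in at least `m_min` distinct structural cardiotoxins (at 48 or 72 h, any
#' concentration), and in zero non-cardiotoxins.
#'
#' @param results Result table from [condition_scan()].
#' @param design A `StudyDesign`.
#' @param m_min Minimum number of cardiotoxins sharing the change.
#' @return data.frame with `feature_id`, `direction`, `n_sct`.
#' @export
conserved_perturbations <- function(results, design, m_min = 4L) {
  validate_study_design(design)
  r <- results[!is.na(results$p) & results$p < 0.05 &
                 results$duration %in% c(48, 72) & !is.na(results$l2fc), ,
               drop = FALSE]
  any_sig <- results[!is.na(results$p) & results$p < 0.05, , drop = FALSE]
  out <- NULL
  for (fid in unique(r$feature_id)) {
    d <- r[r$feature_id == fid, , drop = FALSE]
    if (any(!any_sig$is_sct[any_sig$feature_id == fid])) next
    for (dir in c(-1, 1)) {
      dd <- d[d$is_sct & sign(d$l2fc) == dir, , drop = FALSE]
      n_sct <- length(unique(dd$xenobiotic))
      if (n_sct >= m_min) {
        out <- rbind(out, data.frame(feature_id = fid, direction = dir,
                                     n_sct = n_sct, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), direction = numeric(0),
                      n_sct = integer(0), stringsAsFactors = FALSE)
  }
  out
}
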