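#' Fit a weighted calibration curve with iterative standard exclusion
#'
#' Weighted least squares (weights `1/x^2`, x = nominal concentration) of
#' response on concentration, linear (default) or quadratic. Standards whose
#' back-calculated concentration deviates from nominal by more than
#' `max_deviation_pct` are excluded one at a time (worst first) and the
#' curve refit, until all included standards pass or fewer than
#' `min_levels` distinct levels remain (an error carrying the exclusion
#' trail).
#'
#' @param standards data.frame with columns `nominal` (uM) and `response`.
#' @param form `"linear"` or `"quadratic"`.
#' @param max_deviation_pct Acceptance limit on |back-calculated - nominal| /
#'   nominal * 100 (default 40).
#' @param min_levels Minimum surviving distinct concentration levels
#'   (default 5).
#' @return A `CalibrationCurve`: list with `form`, `coefficients`
#'   (intercept, slope[, quad]), `r_squared` (weighted, of the final fit),
#'   `standards` (per-standard nominal, response, back-calculated, deviation
#'   %, included flag), `lloq`, `uloq`, `exclusion_trail`.
#' @export
fit_calibration <- function(standards, form = c("linear", "quadratic"),
                            max_deviation_pct = 40, min_levels = 5L) {
  form <- match.arg(form)
  stopifnot(all(c("nominal", "response") %in% names(standards)))
  st <- data.frame(nominal = as.numeric(standards$nominal),
                   response = as.numeric(standards$response))
  if (any(st$nominal <= 0)) stop("non-positive nominal concentration")
  if (length(unique(st$nominal)) < min_levels) {
    stop("need >= ", min_levels, " distinct concentration levels")
  }
  st$included <- TRUE
  trail <- character(0)
  repeat {
    inc <- which(st$included)
    if (length(unique(st$nominal[inc])) < min_levels) {
      stop("calibration failed: fewer than ", min_levels,
           " levels survive exclusion (trail: ",
           paste(trail, collapse = " -> "), ")")
    }
    fit <- fit_wls(st$nominal[inc], st$response[inc], form)
    back <- vapply(st$response, function(r) {
      invert_curve_numeric(fit, r, range(st$nominal[inc]))
    }, numeric(1))
    st$back_calculated <- back
    st$deviation_pct <- abs(back - st$nominal) / st$nominal * 100
    # a standard whose response cannot be inverted (non-monotone quadratic
    # over the range) can never be accepted
    st$deviation_pct[is.na(st$deviation_pct)] <- Inf
    bad <- inc[st$deviation_pct[inc] > max_deviation_pct]
    if (!length(bad)) break
    worst <- bad[which.max(st$deviation_pct[bad])]
    st$included[worst] <- FALSE
    trail <- c(trail, sprintf("excluded standard %d (nominal %.4g, %.1f%%)",
                              worst, st$nominal[worst], st$deviation_pct[worst]))
  }
  inc <- which(st$included)
  curve <- structure(
    list(form = form, coefficients = fit$coefficients,
         r_squared = fit$r_squared, standards = st,
         lloq = min(st$nominal[inc]), uloq = max(st$nominal[inc]),
         exclusion_trail = trail, weighting = "1/x^2"),
    class = "CalibrationCurve")
  curve
}

fit_wls <- function(conc, resp, form) {
  w <- 1 / conc^2
  df <- data.frame(conc = conc, resp = resp)
  fml <- if (form == "quadratic") resp ~ conc + I(conc^2) else resp ~ conc
  m <- stats::lm(fml, data = df, weights = w)
  fitted <- stats::fitted(m)
  ss_res <- sum(w * (resp - fitted)^2)
  ss_tot <- sum(w * (resp - stats::weighted.mean(resp, w))^2)
  list(coefficients = unname(stats::coef(m)),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       form = form)
}

predict_response <- function(curve, conc) {
  co <- curve$coefficients
  if (identical(curve$form, "quadratic") ||
      (is.list(curve) && length(co) == 3L)) {
    co[1] + co[2] * conc + co[3] * conc^2
  } else {
    co[1] + co[2] * conc
  }
}

invert_curve_numeric <- function(fit, response, conc_range) {
  co <- fit$coefficients
  if (fit$form == "linear") {
    if (co[2] == 0) return(NA_real_)
    return((response - co[1]) / co[2])
  }
  roots <- quadratic_roots(co[3], co[2], co[1] - response)
  if (!length(roots)) return(NA_real_)
  in_range <- roots[roots >= conc_range[1] * 0.5 & roots <= conc_range[2] * 2]
  if (length(in_range) == 1L) return(in_range)
  if (length(in_range) > 1L) return(NA_real_)  # ambiguous inversion
  roots[which.min(abs(roots - mean(conc_range)))]
}

quadratic_roots <- function(a, b, c) {
  if (a == 0) return(if (b == 0) numeric(0) else -c / b)
  disc <- b^2 - 4 * a * c
  if (disc < 0) return(numeric(0))
  (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
}

#' Back-calculate a concentration from a response
#'
#' Inverts the fitted calibration function. Responses at or inside the
#' response range spanned by the accepted standards give a numeric
#' concentration (the LLOQ boundary is inclusive); responses below/above
#' give flags; missing responses are `not_detected`. A quadratic curve
#' whose inversion is ambiguous inside the calibrated range gives the
#' `quantitation_ambiguous` flag.
#'
#' @param curve A `CalibrationCurve`.
#' @param response Numeric vector of responses (`NA` = not detected).
#' @return data.frame with `response`, `concentration` (uM or `NA`), `flag`
#'   (`""`, `"not_detected"`, `"below_lloq"`, `"above_uloq"`,
#'   `"quantitation_ambiguous"`).
#' @export
back_calculate <- function(curve, response) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  f_lloq <- predict_response(curve, curve$lloq)
  f_uloq <- predict_response(curve, curve$uloq)
  out <- data.frame(response = response, concentration = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_along(response)) {
    r <- response[i]
    if (is.na(r)) { out$flag[i] <- "not_detected"; next }
    if (r < f_lloq) { out$flag[i] <- "below_lloq"; next }
    if (r > f_uloq) { out$flag[i] <- "above_uloq"; next }
    conc <- invert_curve_numeric(curve, r, c(curve$lloq, curve$uloq))
    if (is.na(conc)) { out$flag[i] <- "quantitation_ambiguous"; next }
    out$concentration[i] <- conc
  }
  out
}

#' Accuracy and precision from quant-QC standards
#'
#' Accuracy is the mean back-calculated concentration relative to nominal
#' (percent) over accepted quant-QCs; precision is the mean, over nominal
#' levels, of the RSD across the duplicate quant-QC measurements of that
#' level. Quant-QCs deviating from nominal by more than
#' `max_deviation_pct` are excluded and reported.
#'
#' @param curve A `CalibrationCurve`.
#' @param quant_qcs data.frame with `nominal` and `response` columns.
#' @param max_deviation_pct Acceptance limit (default 40).
#' @return List with `accuracy_pct`, `precision_rsd_pct`, `per_level`
#'   (nominal, n accepted, accuracy, rsd), `rejected` (rows excluded),
#'   `status` (`"ok"` or `"run_failed"` when every quant-QC is rejected).
#' @export
evaluate_quant_qc <- function(curve, quant_qcs, max_deviation_pct = 40) {
  stopifnot(all(c("nominal", "response") %in% names(quant_qcs)))
  bc <- back_calculate(curve, quant_qcs$response)
  q <- cbind(quant_qcs, bc[, c("concentration", "flag")])
  q$calc <- ifelse(q$flag == "", q$concentration, NA_real_)
  q$deviation_pct <- abs(q$calc - q$nominal) / q$nominal * 100
  q$accepted <- !is.na(q$calc) & q$deviation_pct <= max_deviation_pct
  acc <- q[q$accepted, , drop = FALSE]
  if (!nrow(acc)) {
    return(list(accuracy_pct = NA_real_, precision_rsd_pct = NA_real_,
                per_level = NULL, rejected = q[!q$accepted, , drop = FALSE],
                status = "run_failed"))
  }
  per_level <- do.call(rbind, lapply(split(acc, acc$nominal), function(d) {
    data.frame(nominal = d$nominal[1], n = nrow(d),
               accuracy_pct = mean(d$calc / d$nominal) * 100,
               rsd_pct = if (nrow(d) >= 2)
                 stats::sd(d$calc) / mean(d$calc) * 100 else NA_real_)
  }))
  rownames(per_level) <- NULL
  list(accuracy_pct = mean(acc$calc / acc$nominal) * 100,
       precision_rsd_pct = mean(per_level$rsd_pct, na.rm = TRUE),
       per_level = per_level,
       rejected = q[!q$accepted, , drop = FALSE],
       status = "ok")
}

#' Compare measured free concentrations across durations and against nominal
#'
#' Two families of two-sided t-tests per xenobiotic x concentration level,
#' each Holm-corrected within its family: (a) pairwise Welch comparisons of
#' measured concentrations between exposure durations; (b) one-sample tests
#' of the pooled (all durations combined) measured concentrations against
#' the nominal value. A biological versus stability-control Welch contrast
#' (pooled over durations) is reported alongside when stability controls
#' are present.
#'
#' @param measured data.frame with columns `xenobiotic`,
#'   `concentration_level`, `duration`, `sample_type`, `concentration`
#'   (back-calculated uM; `NA` rows are dropped).
#' @param design A `StudyDesign` providing nominal concentrations.
#' @return List of data.frames `between_durations`, `vs_nominal`,
#'   `bio_vs_stability`, plus `skipped` (comparisons with < 2 values).
#' @export
compare_concentrations <- function(measured, design) {
  validate_study_design(design)
  m <- measured[!is.na(measured$concentration), , drop = FALSE]
  bio <- m[m$sample_type == "biological", , drop = FALSE]
  durs <- NULL; noms <- NULL; stab <- NULL; skipped <- NULL
  for (xeno in unique(bio$xenobiotic)) {
    i <- match(xeno, design$xenobiotic)
    for (lev in c("low", "high")) {
      d <- bio[bio$xenobiotic == xeno & bio$concentration_level == lev, ]
      if (!nrow(d)) next
      # (a) pairwise between durations, Holm within this family
      ds <- sort(unique(d$duration))
      pr <- utils::combn(ds, 2, simplify = FALSE)
      fam <- NULL
      for (p in pr) {
        a <- d$concentration[d$duration == p[1]]
        b <- d$concentration[d$duration == p[2]]
        if (length(a) < 2 || length(b) < 2) {
          skipped <- rbind(skipped, data.frame(
            xenobiotic = xeno, concentration_level = lev,
            comparison = paste0(p[1], "h_vs_", p[2], "h"),
            reason = "fewer than 2 values in a group"))
          next
        }
        tt <- stats::t.test(a, b)
        fam <- rbind(fam, data.frame(
          xenobiotic = xeno, concentration_level = lev,
          duration_a = p[1], duration_b = p[2],
          mean_a = mean(a), mean_b = mean(b),
          t = unname(tt$statistic), p = tt$p.value))
      }
      if (!is.null(fam)) {
        fam$p_holm <- stats::p.adjust(fam$p, method = "holm")
        durs <- rbind(durs, fam)
      }
      # (b) pooled vs nominal (collected across levels; adjusted below)
      nominal <- if (lev == "high") design$nominal_high[i] else design$nominal_low[i]
      if (nrow(d) >= 2 && stats::sd(d$concentration) > 0) {
        tt <- stats::t.test(d$concentration, mu = nominal)
        noms <- rbind(noms, data.frame(
          xenobiotic = xeno, concentration_level = lev, nominal = nominal,
          mean_measured = mean(d$concentration),
          t = unname(tt$statistic), p = tt$p.value))
      } else {
        skipped <- rbind(skipped, data.frame(
          xenobiotic = xeno, concentration_level = lev,
          comparison = "vs_nominal", reason = "fewer than 2 values or zero variance"))
      }
      # biological vs stability control, pooled over durations
      s <- m[m$sample_type == "stability_control" & m$xenobiotic == xeno, ]
      if (nrow(s) >= 2 && nrow(d) >= 2 && lev == "high") {
        tt <- stats::t.test(d$concentration, s$concentration)
        stab <- rbind(stab, data.frame(
          xenobiotic = xeno, mean_biological = mean(d$concentration),
          mean_stability = mean(s$concentration),
          t = unname(tt$statistic), p = tt$p.value))
      }
    }
  }
  if (!is.null(noms)) noms$p_holm <- stats::p.adjust(noms$p, method = "holm")
  list(between_durations = durs, vs_nominal = noms,
       bio_vs_stability = stab, skipped = skipped)
}
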