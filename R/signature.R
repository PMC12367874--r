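#' Prepare the assay x duration model matrix for OPLS-DA
#'
#' Extracts the biological samples of one exposure duration from a
#' multivariate-branch processed matrix (control-normalised, log2, imputed,
#' vector-normalised) and builds the samples x features matrix with the
#' 0/1 structural-cardiotoxicity class vector.
#'
#' @param pm Processed `PeakMatrix` (multivariate branch).
#' @param design A `StudyDesign`.
#' @param duration Exposure duration in hours.
#' @return List with `X` (samples x features), `y` (0/1), `sample_ids`.
#' @export
model_dataset <- function(pm, design, duration) {
  validate_peak_matrix(pm)
  validate_study_design(design)
  sm <- pm$sample_meta
  sel <- sm$sample_type == "biological" & sm$duration == duration
  if (!any(sel)) stop("no biological samples at duration ", duration)
  X <- t(pm$intensities[, sel, drop = FALSE])
  y <- as.numeric(design$is_sct[match(sm$xenobiotic[sel], design$xenobiotic)])
  if (anyNA(y)) stop("samples with xenobiotic absent from the design")
  list(X = X, y = y, sample_ids = sm$sample_id[sel])
}

#' Build the predictive-signature table
#'
#' Joins the per-duration VIP scores of the refined models with the
#' significant (p < 0.05) log2 fold changes from the univariate scan and the
#' compound annotations. Only features with VIP >= `vip_min` in at least
#' one refined model appear; entries are sorted by their maximum VIP.
#'
#' @param vip_by_duration Named list (duration -> named VIP vector from the
#'   refined model of that duration).
#' @param scan Result of [condition_scan()] (uses `fc_matrix`).
#' @param annotations Optional annotation table with `feature_id` and
#'   `compound` (best-rank rows are used); may include `function_group`.
#' @param vip_min Inclusion threshold (default 1).
#' @return A `SignatureTable` data.frame: `feature_id`, `compound`,
#'   `function_group`, one `vip_<duration>h` column per duration,
#'   `max_vip`, `n_sig_conditions`, `direction_consistent`,
#'   `mean_sig_l2fc`.
#' @export
build_signature <- function(vip_by_duration, scan, annotations = NULL,
                            vip_min = 1) {
  stopifnot(is.list(vip_by_duration), length(vip_by_duration) >= 1L)
  all_ids <- unique(unlist(lapply(vip_by_duration, names)))
  if (is.null(all_ids)) stop("VIP vectors must be named by feature_id")
  vmat <- sapply(vip_by_duration, function(v) v[all_ids])
  rownames(vmat) <- all_ids
  keep <- apply(vmat, 1L, function(r) any(!is.na(r) & r >= vip_min))
  ids <- all_ids[keep]
  if (!length(ids)) {
    return(data.frame(feature_id = character(0)))
  }
  fc <- scan$fc_matrix
  orphan <- setdiff(ids, rownames(fc))
  if (length(orphan)) {
    stop("signature features absent from the univariate results: ",
         toString(utils::head(orphan, 5)),
         if (length(orphan) > 5) " ...")
  }
  fc <- fc[ids, , drop = FALSE]
  n_sig <- rowSums(!is.na(fc))
  dir_consistent <- apply(fc, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && (all(r > 0) || all(r < 0))
  })
  mean_fc <- rowMeans(fc, na.rm = TRUE)
  mean_fc[n_sig == 0L] <- NA_real_
  out <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations)) {
    best <- annotations[!duplicated(annotations$feature_id), , drop = FALSE]
    i <- match(ids, best$feature_id)
    out$compound <- best$compound[i]
    out$function_group <- if ("function_group" %in% names(best))
      best$function_group[i] else NA_character_
  } else {
    out$compound <- NA_character_
    out$function_group <- NA_character_
  }
  out$compound[is.na(out$compound)] <- "unannotated"
  out$function_group[is.na(out$function_group)] <- "unannotated"
  vdf <- as.data.frame(vmat[ids, , drop = FALSE])
  names(vdf) <- paste0("vip_", names(vip_by_duration), "h")
  out <- cbind(out, vdf)
  out$max_vip <- apply(vmat[ids, , drop = FALSE], 1L, max, na.rm = TRUE)
  out$n_sig_conditions <- n_sig
  out$direction_consistent <- dir_consistent
  out$mean_sig_l2fc <- mean_fc
  out <- out[order(-out$max_vip), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SignatureTable", "data.frame")
  out
}

#' Render a grouped markdown report of the signature
#'
#' Groups the signature entries by biochemical function and writes a
#' deterministic markdown summary with per-entry evidence lines (VIP by
#' duration, univariate direction), plus the machine-readable table.
#'
#' @param signature A `SignatureTable` from [build_signature()].
#' @param path Optional file to write the markdown to.
#' @return The markdown text (character vector of lines), invisibly when
#'   `path` is given.
#' @export
render_report <- function(signature, path = NULL) {
  stopifnot(inherits(signature, "SignatureTable"))
  if (!nrow(signature)) stop("empty signature table")
  vip_cols <- grep("^vip_", names(signature), value = TRUE)
  lines <- c("# Predictive signature of structural cardiotoxicity", "")
  groups <- split(signature, signature$function_group)
  groups <- groups[order(names(groups))]
  for (g in names(groups)) {
    d <- groups[[g]]
    d <- d[order(-d$max_vip), , drop = FALSE]
    lines <- c(lines, paste0("## ", g), "")
    for (i in seq_len(nrow(d))) {
      vips <- vapply(vip_cols, function(cn) {
        v <- d[[cn]][i]
        if (is.na(v)) "-" else sprintf("%.2f", v)
      }, "")
      dirn <- if (is.na(d$mean_sig_l2fc[i])) "no significant univariate change"
        else if (d$mean_sig_l2fc[i] < 0) "reduced in cardiotoxin exposures"
        else "increased in cardiotoxin exposures"
      lines <- c(lines, sprintf(
        "- **%s** (`%s`): VIP %s; %s%s",
        d$compound[i], d$feature_id[i],
        paste(sub("^vip_", "", vip_cols), vips, sep = "=", collapse = ", "),
        dirn,
        if (isTRUE(d$direction_consistent[i])) " (direction consistent)" else ""))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
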