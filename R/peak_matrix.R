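#' Construct a PeakMatrix
#'
#' A `PeakMatrix` is the universal currency between pipeline stages: a
#' features x samples intensity matrix (non-negative, `NA` marks a missing
#' peak) with a per-feature metadata table and a per-sample metadata table.
#'
#' @param intensities Numeric matrix, features in rows, samples in columns.
#'   Missing peaks are `NA`; zeros are legal intensities and are *not*
#'   treated as missing.
#' @param feature_meta data.frame with at least `feature_id` and `mz`
#'   columns; optional `rt` (seconds; `NA` for direct-infusion assays),
#'   `polarity`, `assay_id`.
#' @param sample_meta data.frame with at least `sample_id`, `batch`,
#'   `xenobiotic`, `concentration_level`, `duration`, `replicate`,
#'   `sample_type`, `injection_order`.
#' @return An object of class `PeakMatrix`.
#' @export
peak_matrix <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- feature_meta$feature_id
  colnames(intensities) <- sample_meta$sample_id
  pm <- structure(
    list(intensities = intensities,
         feature_meta = as.data.frame(feature_meta),
         sample_meta = as.data.frame(sample_meta)),
    class = "PeakMatrix"
  )
  validate_peak_matrix(pm)
  pm
}

SAMPLE_TYPES <- c("biological", "control", "qc", "blank",
                  "calibration_standard", "quant_qc", "stability_control")

#' Validate a PeakMatrix against its invariants
#'
#' Checks id uniqueness and agreement between the intensity matrix and the
#' metadata tables, non-negativity of observed intensities, uniqueness of
#' injection orders, and legal sample types.
#'
#' @param pm A `PeakMatrix`.
#' @return `pm`, invisibly; stops with a descriptive error on violation.
#' @export
validate_peak_matrix <- function(pm) {
  stopifnot(inherits(pm, "PeakMatrix"))
  fm <- pm$feature_meta; sm <- pm$sample_meta; x <- pm$intensities
  req_f <- c("feature_id", "mz")
  req_s <- c("sample_id", "sample_type")
  miss <- setdiff(req_f, names(fm))
  if (length(miss)) stop("feature_meta lacks column(s): ", toString(miss))
  miss <- setdiff(req_s, names(sm))
  if (length(miss)) stop("sample_meta lacks column(s): ", toString(miss))
  if (anyDuplicated(fm$feature_id)) {
    stop("duplicate feature_id: ",
         toString(unique(fm$feature_id[duplicated(fm$feature_id)])))
  }
  if (anyDuplicated(sm$sample_id)) {
    stop("duplicate sample_id: ",
         toString(unique(sm$sample_id[duplicated(sm$sample_id)])))
  }
  if (nrow(x) != nrow(fm)) {
    stop("intensity rows (", nrow(x), ") != feature_meta rows (", nrow(fm), ")")
  }
  if (ncol(x) != nrow(sm)) {
    stop("intensity columns (", ncol(x), ") != sample_meta rows (", nrow(sm), ")")
  }
  if (!is.null(rownames(x)) && nrow(x) &&
      !identical(rownames(x), as.character(fm$feature_id))) {
    stop("intensity rownames disagree with feature_meta$feature_id")
  }
  if (!is.null(colnames(x)) && ncol(x) &&
      !identical(colnames(x), as.character(sm$sample_id))) {
    stop("intensity colnames disagree with sample_meta$sample_id")
  }
  if (!isTRUE(attr(pm, "normalised")) && any(x < 0, na.rm = TRUE)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at feature '", rownames(x)[bad[1]],
         "', sample '", colnames(x)[bad[2]], "'")
  }
  if (!all(sm$sample_type %in% SAMPLE_TYPES)) {
    stop("unknown sample_type: ",
         toString(setdiff(unique(sm$sample_type), SAMPLE_TYPES)))
  }
  if ("injection_order" %in% names(sm) && nrow(sm)) {
    io <- sm$injection_order[!is.na(sm$injection_order)]
    if (anyDuplicated(io)) stop("injection_order values are not unique")
    if (length(io) && any(io <= 0)) stop("injection_order must be positive")
  }
  invisible(pm)
}

#' @export
dim.PeakMatrix <- function(x) dim(x$intensities)

#' @export
print.PeakMatrix <- function(x, ...) {
  cat("PeakMatrix:", nrow(x$intensities), "features x",
      ncol(x$intensities), "samples\n")
  tt <- table(x$sample_meta$sample_type)
  cat("  sample types:",
      paste(names(tt), as.integer(tt), sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' Subset a PeakMatrix by sample and/or feature predicates
#'
#' Predicates are expressions evaluated inside the metadata tables, e.g.
#' `subset_peak_matrix(pm, samples = sample_type == "qc")`. Order is
#' preserved. Referencing an unknown metadata column is an error; an empty
#' result is allowed but raises a warning.
#'
#' @param pm A `PeakMatrix`.
#' @param samples Expression over `sample_meta` columns (optional).
#' @param features Expression over `feature_meta` columns (optional).
#' @return The subset `PeakMatrix`.
#' @export
subset_peak_matrix <- function(pm, samples = NULL, features = NULL) {
  stopifnot(inherits(pm, "PeakMatrix"))
  s_expr <- substitute(samples)
  f_expr <- substitute(features)
  keep_s <- rep(TRUE, nrow(pm$sample_meta))
  keep_f <- rep(TRUE, nrow(pm$feature_meta))
  if (!is.null(s_expr) && !identical(s_expr, quote(NULL))) {
    keep_s <- eval_predicate(s_expr, pm$sample_meta, parent.frame(), "sample_meta")
  }
  if (!is.null(f_expr) && !identical(f_expr, quote(NULL))) {
    keep_f <- eval_predicate(f_expr, pm$feature_meta, parent.frame(), "feature_meta")
  }
  out <- structure(
    list(intensities = pm$intensities[keep_f, keep_s, drop = FALSE],
         feature_meta = pm$feature_meta[keep_f, , drop = FALSE],
         sample_meta = pm$sample_meta[keep_s, , drop = FALSE]),
    class = "PeakMatrix"
  )
  rownames(out$feature_meta) <- NULL
  rownames(out$sample_meta) <- NULL
  if (ncol(out$intensities) == 0L || nrow(out$intensities) == 0L) {
    warning("subset_peak_matrix: empty result")
  }
  validate_peak_matrix(out)
}

eval_predicate <- function(expr, meta, enclos, what) {
  vars <- all.vars(expr)
  unknown <- setdiff(vars, c(names(meta), ls(enclos, all.names = TRUE)))
  unknown <- setdiff(unknown, c("TRUE", "FALSE", "T", "F"))
  # variables resolvable in the calling environment are allowed
  unknown <- Filter(function(v) !exists(v, envir = enclos), unknown)
  if (length(unknown)) {
    stop("predicate references unknown ", what, " field(s): ",
         toString(unknown))
  }
  keep <- eval(expr, meta, enclos)
  if (!is.logical(keep) || length(keep) != nrow(meta)) {
    stop("predicate must evaluate to a logical vector over ", what)
  }
  keep & !is.na(keep)
}

#' Write a PeakMatrix to a directory of delimited text files
#'
#' Layout: `intensities.tsv` (features x samples, tab-delimited, missing
#' cells encoded as empty fields, never as zeros), `feature_meta.tsv`,
#' `sample_meta.tsv` and a `manifest.json` recording the file names and
#' shape. Lossless for text-representable values (full double precision).
#'
#' @param pm A valid `PeakMatrix`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(pm, path) {
  validate_peak_matrix(pm)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory '", path, "'")
  x <- pm$intensities
  con <- file(file.path(path, "intensities.tsv"), "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  if (nrow(x)) {
    body <- apply(x, 1L, function(r) {
      paste(ifelse(is.na(r), "", formatC(r, digits = 17, format = "g")),
            collapse = "\t")
    })
    writeLines(paste(pm$feature_meta$feature_id, body, sep = "\t"), con)
  }
  utils::write.table(pm$feature_meta, file.path(path, "feature_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(pm$sample_meta, file.path(path, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  manifest <- list(format = "cardiotoxsig-peak-matrix", version = 1L,
                   intensities = "intensities.tsv",
                   feature_meta = "feature_meta.tsv",
                   sample_meta = "sample_meta.tsv",
                   n_features = nrow(x), n_samples = ncol(x))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a PeakMatrix bundle written by [write_peak_matrix()]
#'
#' @param path Directory containing the bundle.
#' @return A validated `PeakMatrix`.
#' @export
read_peak_matrix <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json under '", path, "'")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  read_tsv <- function(f) {
    utils::read.delim(file.path(path, f), sep = "\t", header = TRUE,
                      na.strings = "", check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  ints <- read_tsv(man$intensities)
  fm <- read_tsv(man$feature_meta)
  sm <- read_tsv(man$sample_meta)
  if (!"feature_id" %in% names(ints)) {
    stop("intensities table lacks a feature_id column")
  }
  ids <- as.character(ints$feature_id)
  x <- as.matrix(ints[, setdiff(names(ints), "feature_id"), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  if (!setequal(colnames(x), sm$sample_id) ||
      ncol(x) != nrow(sm)) {
    missing_ids <- setdiff(colnames(x), sm$sample_id)
    extra_ids <- setdiff(sm$sample_id, colnames(x))
    stop("sample ids disagree between intensities and sample_meta",
         if (length(missing_ids)) paste0("; absent from sample_meta: ",
                                         toString(missing_ids)),
         if (length(extra_ids)) paste0("; absent from intensities: ",
                                       toString(extra_ids)))
  }
  if (!setequal(ids, fm$feature_id) || nrow(x) != nrow(fm)) {
    stop("feature ids disagree between intensities and feature_meta")
  }
  fm <- fm[match(ids, fm$feature_id), , drop = FALSE]
  sm <- sm[match(colnames(x), sm$sample_id), , drop = FALSE]
  rownames(fm) <- NULL; rownames(sm) <- NULL
  peak_matrix(x, fm, sm)
}
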