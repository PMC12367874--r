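#' Default cardiac-microtissue exposure design
#'
#' Twelve xenobiotics across four exposure batches (A-D); each batch pairs
#' two structural cardiotoxins with one non-cardiotoxin. Each xenobiotic is
#' dosed at a nominal low and high concentration (low is a half-log dilution
#' of high), for 6, 48 and 72 h, with duration-matched 0.1% DMSO controls
#' per batch.
#'
#' @param durations Exposure durations in hours.
#' @param replicates Replicates per exposure group (footprint assay default).
#' @return A `StudyDesign`: data.frame with one row per xenobiotic
#'   (`xenobiotic`, `batch`, `is_sct`, `nominal_low`, `nominal_high`,
#'   `rationale`, `formula`) and attributes `durations`, `replicates`.
#' @export
default_study_design <- function(durations = c(6, 48, 72), replicates = 6L) {
  d <- data.frame(
    xenobiotic = c("acyclovir", "clozapine", "sorafenib",
                   "buspirone", "doxorubicin", "lapatinib",
                   "erlotinib", "idarubicin", "sunitinib",
                   "mebendazole", "dasatinib", "fluorouracil"),
    batch = rep(c("A", "B", "C", "D"), each = 3L),
    is_sct = c(FALSE, TRUE, TRUE,
               FALSE, TRUE, TRUE,
               FALSE, TRUE, TRUE,
               FALSE, TRUE, TRUE),
    nominal_low = c(15.8, 2.23, 1.18,
                    0.14, 0.11, 1.75,
                    14.2, 0.095, 1.12,
                    9.63, 3.42, 15.8),
    nominal_high = c(99.9, 7.05, 3.74,
                     0.45, 0.36, 5.53,
                     45.0, 0.30, 3.53,
                     30.5, 10.8, 69.2),
    rationale = c("15xCmax", "15xCmax", "IC30",
                  "15xCmax", "IC30", "IC30",
                  "15xCmax", "lowest_investigated", "IC30",
                  "15xCmax", "15xCmax", "15xCmax"),
    formula = c("C8H11N5O3", "C18H19ClN4", "C21H16ClF3N4O3",
                "C21H31N5O2", "C27H29NO11", "C29H26ClFN4O4S",
                "C22H23N3O4", "C26H27NO9", "C22H27FN4O2",
                "C16H13N3O3", "C22H26ClN7O2S", "C4H3FN2O2"),
    stringsAsFactors = FALSE
  )
  structure(d, durations = durations, replicates = as.integer(replicates),
            class = c("StudyDesign", "data.frame"))
}

#' Validate a StudyDesign
#'
#' Checks that high > low per xenobiotic and that every batch contains at
#' least one cardiotoxin and one non-cardiotoxin.
#'
#' @param design A `StudyDesign`.
#' @return `design` invisibly; stops on violation.
#' @export
validate_study_design <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  if (any(design$nominal_high <= design$nominal_low)) {
    bad <- design$xenobiotic[design$nominal_high <= design$nominal_low]
    stop("nominal_high <= nominal_low for: ", toString(bad))
  }
  for (b in unique(design$batch)) {
    sct <- design$is_sct[design$batch == b]
    if (!any(sct) || !any(!sct)) {
      stop("batch ", b, " must contain >=1 cardiotoxin and >=1 non-cardiotoxin")
    }
  }
  if (anyDuplicated(design$xenobiotic)) stop("duplicate xenobiotic in design")
  invisible(design)
}

#' Enumerate the exposure conditions of a design
#'
#' A condition is a (xenobiotic, concentration level, duration) triple; the
#' default design yields 12 x 2 x 3 = 72 conditions.
#'
#' @param design A `StudyDesign`.
#' @return data.frame with columns `xenobiotic`, `batch`, `is_sct`,
#'   `concentration_level`, `duration`.
#' @export
enumerate_conditions <- function(design) {
  validate_study_design(design)
  durations <- attr(design, "durations")
  out <- expand.grid(xenobiotic = design$xenobiotic,
                     concentration_level = c("low", "high"),
                     duration = durations,
                     stringsAsFactors = FALSE)
  i <- match(out$xenobiotic, design$xenobiotic)
  out$batch <- design$batch[i]
  out$is_sct <- design$is_sct[i]
  out[order(out$xenobiotic, out$concentration_level, out$duration),
      c("xenobiotic", "batch", "is_sct", "concentration_level", "duration")]
}

#' Default analytical assays of the hybrid-metabolomics study
#'
#' Four intracellular direct-infusion (DIMS) fingerprint assays (polar and
#' lipids, both polarities; no retention time) and two extracellular HILIC
#' UHPLC-MS footprint assays (both polarities, with retention time).
#'
#' @return data.frame with `assay_id`, `compartment`, `polarity`, `has_rt`,
#'   `qc_interval` (QC injected after every this-many study samples).
#' @export
default_assays <- function() {
  data.frame(
    assay_id = c("dims_polar_pos", "dims_polar_neg",
                 "dims_lipids_pos", "dims_lipids_neg",
                 "hilic_pos", "hilic_neg"),
    compartment = c(rep("intracellular", 4L), rep("footprint", 2L)),
    polarity = c("positive", "negative", "positive", "negative",
                 "positive", "negative"),
    has_rt = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    qc_interval = c(8L, 8L, 8L, 8L, 6L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the assay x duration model datasets of a study
#'
#' One supervised model is trained per analytical assay and exposure
#' duration; the default study yields 6 x 3 = 18 datasets.
#'
#' @param design A `StudyDesign`.
#' @param assays Assay table as from [default_assays()].
#' @return data.frame with `assay_id` and `duration`.
#' @export
enumerate_model_datasets <- function(design, assays = default_assays()) {
  validate_study_design(design)
  expand.grid(assay_id = assays$assay_id,
              duration = attr(design, "durations"),
              stringsAsFactors = FALSE)
}

#' Check that low concentrations are half-log dilutions of high
#'
#' Computes the high/low ratio per xenobiotic and flags any deviating from
#' `10^0.5` (~3.162) by more than `tol` relative.
#'
#' @param design A `StudyDesign`.
#' @param tol Relative tolerance (default 0.05).
#' @return data.frame with `xenobiotic`, `ratio`, `flagged`.
#' @export
half_log_check <- function(design, tol = 0.05) {
  validate_study_design(design)
  ratio <- design$nominal_high / design$nominal_low
  data.frame(xenobiotic = design$xenobiotic,
             ratio = ratio,
             flagged = abs(ratio / 10^0.5 - 1) > tol,
             stringsAsFactors = FALSE)
}

#' Mass-tolerance and grouping configuration
#'
#' @param ppm_dims Mass window for direct-infusion assays (ppm, default 2).
#' @param ppm_lc Mass window for LC-MS assays (ppm, default 5).
#' @param rt_group_tol Retention-time grouping tolerance in seconds (default 5).
#' @param corr_r_min Minimum Pearson r for feature grouping (default 0.7).
#' @param corr_p_max Maximum correlation p-value for grouping (default 0.01).
#' @return A `ToleranceConfig` list.
#' @export
tolerance_config <- function(ppm_dims = 2, ppm_lc = 5, rt_group_tol = 5,
                             corr_r_min = 0.7, corr_p_max = 0.01) {
  stopifnot(ppm_dims > 0, ppm_lc > 0, rt_group_tol > 0,
            corr_r_min > 0, corr_r_min <= 1, corr_p_max > 0)
  structure(list(ppm_dims = ppm_dims, ppm_lc = ppm_lc,
                 rt_group_tol = rt_group_tol, corr_r_min = corr_r_min,
                 corr_p_max = corr_p_max),
            class = "ToleranceConfig")
}
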