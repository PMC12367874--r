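#' Group co-eluting, correlated features
#'
#' Builds a graph with an edge between two features iff their retention
#' times differ by at most `rt_tol` seconds AND their intensities across QC
#' and biological samples correlate with Pearson r >= `r_min` at p <=
#' `p_max` (exact t-transform of r with n - 2 df, pairwise-complete
#' observations, at least `min_pairs` pairs). Groups are the connected
#' components; singletons are allowed. Matrices without retention time
#' (direct-infusion assays) are grouped on correlation only, with a warning.
#'
#' @param pm A `PeakMatrix`.
#' @param tol A `ToleranceConfig` (uses `rt_group_tol`, `corr_r_min`,
#'   `corr_p_max`).
#' @param min_pairs Minimum paired observations per correlation (default 5).
#' @return data.frame with `feature_id` and integer `group_id`.
#' @export
group_features <- function(pm, tol = tolerance_config(), min_pairs = 5L) {
  validate_peak_matrix(pm)
  use <- pm$sample_meta$sample_type %in% c("qc", "biological")
  x <- pm$intensities[, use, drop = FALSE]
  n_f <- nrow(x)
  rt <- pm$feature_meta$rt
  has_rt <- !is.null(rt) && !all(is.na(rt))
  if (!has_rt) {
    warning("no retention time: correlation-only grouping")
  }
  edges <- NULL
  for (i in seq_len(max(0L, n_f - 1L))) {
    for (j in (i + 1L):n_f) {
      if (has_rt && (is.na(rt[i]) || is.na(rt[j]) ||
                     abs(rt[i] - rt[j]) > tol$rt_group_tol)) next
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      n <- sum(ok)
      if (n < min_pairs) next
      a <- x[i, ok]; b <- x[j, ok]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(a, b)
      p <- pearson_p(r, n)
      if (r >= tol$corr_r_min && p <= tol$corr_p_max) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n = n_f, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  data.frame(feature_id = pm$feature_meta$feature_id,
             group_id = as.integer(comp), stringsAsFactors = FALSE)
}

#' Two-sided p-value of a Pearson correlation via the exact t-transform
#' @keywords internal
pearson_p <- function(r, n) {
  if (n < 3) return(NA_real_)
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Table of intra-group mass differences between ion forms
#'
#' Differences between adducts of the same polarity and charge, plus the
#' 13C isotopologue spacing, used to relate co-eluting features.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame with `label_low`, `label_high`, `mass_diff` (Da,
#'   higher minus lower m/z), `kind`.
#' @export
mass_difference_table <- function(polarity) {
  tab <- adduct_table()
  tab <- tab[tab$polarity == polarity & abs(tab$charge) == 1L, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(tab))) {
      d <- tab$mass_delta[j] - tab$mass_delta[i]
      if (d <= 0) next
      out <- rbind(out, data.frame(
        label_low = tab$adduct[i], label_high = tab$adduct[j],
        mass_diff = d, kind = "adduct_pair", stringsAsFactors = FALSE))
    }
  }
  rbind(out, data.frame(label_low = "M", label_high = "M+1 (13C)",
                        mass_diff = C13_SPACING, kind = "isotopologue",
                        stringsAsFactors = FALSE))
}

#' Annotate ion forms within feature groups by exact mass differences
#'
#' Within each group, all feature pairs are tested against the packaged
#' mass-difference table at the ppm tolerance (applied to the larger m/z).
#' Consistent assignments propagate a single implied neutral mass per
#' group (the mean of the per-feature implied masses); conflicting
#' assignments leave the features unlabelled with a conflict note.
#' Singleton groups get the polarity's default ion form (`[M+H]+` /
#' `[M-H]-`), flagged as assumed. Isotopologue relations always point from
#' the lower to the higher m/z.
#'
#' @param pm A `PeakMatrix`.
#' @param groups Grouping from [group_features()].
#' @param ppm Mass tolerance in ppm.
#' @return data.frame with `feature_id`, `group_id`, `ion_form`,
#'   `neutral_mass`, `assumed`, `note`.
#' @export
annotate_ion_forms <- function(pm, groups, ppm) {
  validate_peak_matrix(pm)
  pol <- pm$feature_meta$polarity[1]
  difft <- mass_difference_table(pol)
  default_form <- if (pol == "positive") "[M+H]+" else "[M-H]-"
  fm <- merge(pm$feature_meta, groups, by = "feature_id", sort = FALSE)
  out <- data.frame(feature_id = fm$feature_id, group_id = fm$group_id,
                    ion_form = NA_character_, neutral_mass = NA_real_,
                    assumed = FALSE, note = "", stringsAsFactors = FALSE)
  for (gid in unique(fm$group_id)) {
    idx <- which(fm$group_id == gid)
    if (length(idx) == 1L) {
      out$ion_form[idx] <- default_form
      out$neutral_mass[idx] <- implied_neutral_mass(fm$mz[idx], default_form)
      out$assumed[idx] <- TRUE
      next
    }
    labels <- stats::setNames(vector("list", length(idx)),
                              fm$feature_id[idx])
    iso_of <- rep(NA_integer_, length(idx))
    o <- order(fm$mz[idx])
    for (a in seq_along(o)[-length(o)]) {
      for (b in (a + 1L):length(o)) {
        i <- idx[o[a]]; j <- idx[o[b]]
        d <- fm$mz[j] - fm$mz[i]
        tol_da <- ppm * 1e-6 * fm$mz[j]
        hit <- which(abs(difft$mass_diff - d) <= tol_da)
        for (h in hit) {
          if (difft$kind[h] == "isotopologue") {
            iso_of[o[b]] <- o[a]
          } else {
            labels[[o[a]]] <- c(labels[[o[a]]], difft$label_low[h])
            labels[[o[b]]] <- c(labels[[o[b]]], difft$label_high[h])
          }
        }
      }
    }
    masses <- rep(NA_real_, length(idx))
    for (k in seq_along(idx)) {
      if (!is.na(iso_of[k])) {
        out$ion_form[idx[k]] <- "M+1 (13C)"
        next
      }
      lab <- unique(labels[[k]])
      if (length(lab) == 1L) {
        out$ion_form[idx[k]] <- lab
        masses[k] <- implied_neutral_mass(fm$mz[idx[k]], lab)
      } else if (length(lab) > 1L) {
        out$note[idx[k]] <- paste("conflicting ion forms:",
                                  paste(lab, collapse = ", "))
      }
    }
    known <- masses[!is.na(masses)]
    if (length(known)) {
      spread_ppm <- (max(known) - min(known)) / mean(known) * 1e6
      if (spread_ppm <= 2 * ppm) {
        out$neutral_mass[idx][!is.na(masses)] <- mean(known)
      } else {
        out$neutral_mass[idx][!is.na(masses)] <- masses[!is.na(masses)]
        out$note[idx][!is.na(masses)] <-
          "group neutral masses inconsistent; per-feature masses kept"
      }
    }
  }
  out
}

#' Match implied neutral masses against a compound library
#'
#' Every library compound within the ppm window is returned, ranked by
#' absolute ppm error (ties all reported). Mass-only matches are MSI level
#' 3; an additional retention-time match within `rt_tol` seconds upgrades
#' to level 2; features without any match are level 4. Spectral matching
#' (level 1) is out of scope here.
#'
#' @param features data.frame with `feature_id`, `neutral_mass`, optionally
#'   `rt`.
#' @param library Compound library data.frame with `compound` and
#'   `monoisotopic_mass` (or `formula`), optionally `rt_seconds`,
#'   `function_group`.
#' @param ppm Mass window (ppm).
#' @param rt_tol RT tolerance in seconds for the level upgrade (default 10).
#' @return data.frame of `AnnotationRecord` rows: `feature_id`,
#'   `compound`, `library_mass`, `ppm_error`, `rt_match`, `msi_level`,
#'   `rank`; unmatched features appear once with `msi_level = 4`.
#' @export
match_library <- function(features, library, ppm, rt_tol = 10) {
  if (is.null(library) || !nrow(library)) stop("empty compound library")
  if (!"monoisotopic_mass" %in% names(library)) {
    library$monoisotopic_mass <- vapply(library$formula, monoisotopic_mass,
                                        numeric(1))
  }
  has_lib_rt <- "rt_seconds" %in% names(library)
  out <- NULL
  for (i in seq_len(nrow(features))) {
    m <- features$neutral_mass[i]
    if (is.na(m)) {
      out <- rbind(out, annotation_row(features$feature_id[i]))
      next
    }
    err <- ppm_error(m, library$monoisotopic_mass)
    sel <- which(abs(err) <= ppm)
    if (!length(sel)) {
      out <- rbind(out, annotation_row(features$feature_id[i]))
      next
    }
    rt_match <- rep(FALSE, length(sel))
    if (has_lib_rt && "rt" %in% names(features) && !is.na(features$rt[i])) {
      rt_match <- !is.na(library$rt_seconds[sel]) &
        abs(library$rt_seconds[sel] - features$rt[i]) <= rt_tol
    }
    d <- data.frame(feature_id = features$feature_id[i],
                    compound = library$compound[sel],
                    library_mass = library$monoisotopic_mass[sel],
                    ppm_error = err[sel],
                    rt_match = rt_match,
                    msi_level = ifelse(rt_match, 2L, 3L),
                    stringsAsFactors = FALSE)
    d <- d[order(abs(d$ppm_error)), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    out <- rbind(out, d)
  }
  rownames(out) <- NULL
  out
}

annotation_row <- function(fid) {
  data.frame(feature_id = fid, compound = NA_character_,
             library_mass = NA_real_, ppm_error = NA_real_,
             rt_match = FALSE, msi_level = 4L, rank = 1L,
             stringsAsFactors = FALSE)
}

#' Molecular formula of a ceramide from shorthand carbon/double-bond counts
#'
#' `Cer C:D;On` shorthand: total acyl+base carbons `C`, `D` carbon-carbon
#' double bonds, `n` hydroxyl oxygens (the amide oxygen is additional).
#'
#' @param carbons,double_bonds,hydroxyls Integers.
#' @return Formula string.
#' @export
ceramide_formula <- function(carbons, double_bonds, hydroxyls = 2L) {
  h <- 2L * carbons + 1L - 2L * double_bonds
  sprintf("C%dH%dNO%d", carbons, h, hydroxyls + 1L)
}

#' Packaged reference compound library
#'
#' A small curated table of cardiac-microtissue metabolites and lipids:
#' energy metabolism and purine nucleotides, glutathione forms,
#' extracellular markers, and a panel of ceramide species, grouped by broad
#' biochemical function. Sufficient for annotation of synthetic fixtures;
#' users may supply larger libraries in the same schema (`compound`,
#' `formula` or `monoisotopic_mass`, optional `rt_seconds`,
#' `function_group`).
#'
#' @return data.frame with `compound`, `formula`, `monoisotopic_mass`,
#'   `rt_seconds`, `function_group`.
#' @export
default_compound_library <- function() {
  base <- data.frame(
    compound = c("creatine", "phosphocreatine", "AMP", "ADP", "ATP",
                 "cyclic AMP", "GMP", "cyclic GMP", "adenosine",
                 "deoxyadenosine", "deoxyguanosine", "inosine", "xanthine",
                 "hypoxanthine", "L-glutamine", "pantothenic acid",
                 "glutathione (reduced)", "glutathione (oxidised)",
                 "lactic acid", "thymidine", "deoxycytidine", "L-alanine",
                 "N-acetylaspartic acid", "cytosine",
                 "sn-glycero-3-phosphoethanolamine", "taurine", "carnitine",
                 "glucose", "L-glutamic acid", "creatinine",
                 "nicotinamide", "succinic acid", "citric acid",
                 "fumaric acid", "malic acid", "pyruvic acid",
                 "uridine", "cytidine", "guanosine", "uric acid"),
    formula = c("C4H9N3O2", "C4H10N3O5P", "C10H14N5O7P", "C10H15N5O10P2",
                "C10H16N5O13P3", "C10H12N5O6P", "C10H14N5O8P",
                "C10H12N5O7P", "C10H13N5O4", "C10H13N5O3", "C10H13N5O4",
                "C10H12N4O5", "C5H4N4O2", "C5H4N4O", "C5H10N2O3",
                "C9H17NO5", "C10H17N3O6S", "C20H32N6O12S2", "C3H6O3",
                "C10H14N2O5", "C9H13N3O4", "C3H7NO2", "C6H9NO5",
                "C4H5N3O", "C5H14NO6P", "C2H7NO3S", "C7H15NO3",
                "C6H12O6", "C5H9NO4", "C4H7N3O", "C6H6N2O", "C4H6O4",
                "C6H8O7", "C4H4O4", "C4H6O5", "C3H4O3", "C9H12N2O6",
                "C9H13N3O5", "C10H13N5O5", "C5H4N4O3"),
    function_group = c(rep("energy metabolism", 2L),
                       rep("purine metabolism", 12L),
                       "amino acid", "energy metabolism",
                       rep("oxidative stress", 2L),
                       rep("extracellular marker", 6L),
                       "glycerophospholipid metabolism",
                       rep("amino acid", 2L),
                       rep("energy metabolism", 9L),
                       rep("purine metabolism", 4L)),
    stringsAsFactors = FALSE
  )
  cer <- data.frame(
    carbons = c(32, 33, 34, 34, 34, 35, 36, 36, 37, 38, 38, 39, 40, 40,
                41, 41, 41, 41, 42, 42, 42, 42, 42, 42, 43, 43),
    db = c(1, 1, 0, 1, 2, 1, 1, 2, 1, 1, 2, 1, 1, 2,
           1, 1, 2, 3, 1, 1, 2, 2, 3, 4, 2, 3),
    ox = c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2,
           2, 3, 2, 2, 2, 3, 2, 3, 2, 2, 2, 2))
  cer_df <- data.frame(
    compound = sprintf("Cer %d:%d;O%d", cer$carbons, cer$db, cer$ox),
    formula = mapply(ceramide_formula, cer$carbons, cer$db, cer$ox),
    function_group = "ceramide signalling",
    stringsAsFactors = FALSE
  )
  lib <- rbind(base, cer_df)
  lib$monoisotopic_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1))
  lib$rt_seconds <- NA_real_
  rownames(lib) <- NULL
  lib[, c("compound", "formula", "monoisotopic_mass", "rt_seconds",
          "function_group")]
}
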