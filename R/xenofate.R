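#' Default biotransformation rule table
#'
#' Twelve phase I rules (oxidative, hydrolytic and dealkylation chemistry)
#' and four phase II conjugations. Monoisotopic mass shifts are computed
#' from the elemental change at load time, so they are consistent with the
#' element mass table by construction.
#'
#' @return data.frame with `name`, `change` (signed elemental change, e.g.
#'   `"+O"`, `"-CH2"`), `mass_shift` (Da), `phase` (`"I"` or `"II"`).
#' @export
default_btp_rules <- function() {
  rules <- data.frame(
    name = c("hydroxylation", "dioxidation", "dehydrogenation", "hydrogenation",
             "demethylation", "deethylation", "depropylation", "hydrolysis",
             "decarboxylation", "deamination", "defluorination_to_oh",
             "oxidative_dechlorination",
             "glucuronidation", "sulfation", "acetylation",
             "glutathione_conjugation"),
    change = c("+O", "+O2", "-H2", "+H2",
               "-CH2", "-C2H4", "-C3H6", "+H2O",
               "-CO2", "-NH3+H2O", "-F+OH", "-Cl+OH",
               "+C6H8O6", "+SO3", "+C2H2O", "+C10H15N3O6S"),
    phase = c(rep("I", 12L), rep("II", 4L)),
    stringsAsFactors = FALSE
  )
  rules$mass_shift <- vapply(rules$change, elemental_change_mass, numeric(1))
  rules[, c("name", "change", "mass_shift", "phase")]
}

#' Mass of a signed elemental change such as "-NH3+O"
#' @keywords internal
elemental_change_mass <- function(change) {
  parts <- regmatches(change, gregexpr("[+-][A-Za-z0-9]+", change))[[1]]
  if (!length(parts)) parts <- paste0("+", change)
  sum(vapply(parts, function(p) {
    sign <- if (substr(p, 1, 1) == "-") -1 else 1
    sign * monoisotopic_mass(substring(p, 2))
  }, numeric(1)))
}

#' Signed element-count delta of a change string
#' @keywords internal
elemental_change_counts <- function(change) {
  parts <- regmatches(change, gregexpr("[+-][A-Za-z0-9]+", change))[[1]]
  if (!length(parts)) parts <- paste0("+", change)
  out <- integer(0)
  for (p in parts) {
    sign <- if (substr(p, 1, 1) == "-") -1L else 1L
    cnt <- parse_formula(substring(p, 2))
    for (el in names(cnt)) {
      out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + sign * cnt[[el]]
    }
  }
  out
}

#' Discover xenobiotic-related features by intensity filters
#'
#' Returns the features that are (a) detected in at least `detect_fraction`
#' of the exposed samples of the given xenobiotic (any concentration or
#' duration), (b) at least `fold_x`-fold more intense (median over exposed
#' samples, absent as 0) than in the matched controls and in the blanks
#' (absent medians replaced by a pseudo-floor), and (c) not passing the same
#' detection-and-fold test for any other xenobiotic's exposed samples
#' (specificity).
#'
#' @param pm A `PeakMatrix` containing exposed, control and blank samples.
#' @param xenobiotic Xenobiotic name present in the sample metadata.
#' @param fold_x Fold threshold over controls and blanks (default 10).
#' @param detect_fraction Required detection rate in exposed samples
#'   (default 2/3).
#' @param pseudo_floor Stand-in for an absent control/blank median; defaults
#'   to 1% of the median observed intensity of the matrix, so that "10-fold
#'   over nothing" still demands a clearly measurable signal.
#' @return Character vector of feature ids.
#' @export
discover_xenobiotic_features <- function(pm, xenobiotic, fold_x = 10,
                                         detect_fraction = 2 / 3,
                                         pseudo_floor = NULL) {
  pass <- xenobiotic_pass_matrix(pm, fold_x, detect_fraction, pseudo_floor)
  if (!xenobiotic %in% colnames(pass)) {
    stop("xenobiotic '", xenobiotic, "' absent from the sample metadata")
  }
  specific <- pass[, xenobiotic] &
    rowSums(pass[, setdiff(colnames(pass), xenobiotic), drop = FALSE]) == 0L
  pm$feature_meta$feature_id[specific]
}

#' Discover xenobiotic-related features for every xenobiotic at once
#'
#' Same rules as [discover_xenobiotic_features()], computed in one pass.
#'
#' @inheritParams discover_xenobiotic_features
#' @return Named list of feature-id vectors, one per xenobiotic.
#' @export
discover_all_xenobiotic_features <- function(pm, fold_x = 10,
                                             detect_fraction = 2 / 3,
                                             pseudo_floor = NULL) {
  pass <- xenobiotic_pass_matrix(pm, fold_x, detect_fraction, pseudo_floor)
  out <- lapply(colnames(pass), function(xeno) {
    specific <- pass[, xeno] &
      rowSums(pass[, setdiff(colnames(pass), xeno), drop = FALSE]) == 0L
    pm$feature_meta$feature_id[specific]
  })
  stats::setNames(out, colnames(pass))
}

xenobiotic_pass_matrix <- function(pm, fold_x, detect_fraction, pseudo_floor) {
  validate_peak_matrix(pm)
  sm <- pm$sample_meta
  x <- pm$intensities
  if (is.null(pseudo_floor)) {
    pseudo_floor <- stats::median(x, na.rm = TRUE) / 100
  }
  x0 <- x; x0[is.na(x0)] <- 0
  is_blank <- sm$sample_type == "blank"
  med_blank <- if (any(is_blank))
    apply(x0[, is_blank, drop = FALSE], 1L, stats::median) else
      rep(0, nrow(x))
  med_blank <- pmax(med_blank, pseudo_floor)
  xenos <- setdiff(unique(sm$xenobiotic[sm$sample_type == "biological"]),
                   "none")
  pass <- matrix(FALSE, nrow(x), length(xenos),
                 dimnames = list(NULL, xenos))
  for (xeno in xenos) {
    exposed <- sm$sample_type == "biological" & sm$xenobiotic == xeno
    batches <- unique(sm$batch[exposed])
    ctl <- sm$sample_type == "control" & sm$batch %in% batches
    det <- rowMeans(!is.na(x[, exposed, drop = FALSE]))
    med_exp <- apply(x0[, exposed, drop = FALSE], 1L, stats::median)
    med_ctl <- pmax(apply(x0[, ctl, drop = FALSE], 1L, stats::median),
                    pseudo_floor)
    pass[, xeno] <- det >= detect_fraction & med_exp >= fold_x * med_ctl &
      med_exp >= fold_x * med_blank
  }
  pass
}

#' Match features against the expected ion forms of a parent xenobiotic
#'
#' @param features data.frame with `feature_id` and `mz` (subset of a
#'   feature_meta table).
#' @param formula Molecular formula of the parent.
#' @param ppm Mass tolerance (ppm).
#' @param polarity `"positive"`, `"negative"` or `"both"` — restricts the
#'   adduct hypotheses tried.
#' @return data.frame of hits: `feature_id`, `mz`, `adduct`, `expected_mz`,
#'   `ppm_error`.
#' @export
match_parent <- function(features, formula, ppm, polarity = "both") {
  M <- monoisotopic_mass(formula)
  tab <- adduct_table()
  if (polarity != "both") tab <- tab[tab$polarity == polarity, , drop = FALSE]
  hits <- NULL
  for (i in seq_len(nrow(tab))) {
    expected <- (M + tab$mass_delta[i]) / abs(tab$charge[i])
    err <- ppm_error(features$mz, expected)
    sel <- which(abs(err) <= ppm)
    if (length(sel)) {
      hits <- rbind(hits, data.frame(
        feature_id = features$feature_id[sel], mz = features$mz[sel],
        adduct = tab$adduct[i], expected_mz = expected,
        ppm_error = err[sel], stringsAsFactors = FALSE))
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(feature_id = character(0), mz = numeric(0),
                       adduct = character(0), expected_mz = numeric(0),
                       ppm_error = numeric(0), stringsAsFactors = FALSE)
  }
  hits
}

#' Enumerate biotransformation-product candidate masses
#'
#' Breadth-first application of the rule table to the parent, up to
#' `max_steps` sequential steps. When the parent formula is known, element
#' bookkeeping excludes impossible losses (a rule removing CH2 cannot apply
#' to a moiety without it). Duplicate candidate masses (within 1e-9 Da) are
#' merged, keeping every generating path; a candidate is phase II if any
#' step on its path is phase II.
#'
#' @param parent Parent formula (character) or monoisotopic neutral mass.
#' @param rules Rule table as from [default_btp_rules()].
#' @param max_steps Maximum number of sequential biotransformation steps.
#' @return data.frame: `mass` (Da), `path` (rule names, " > "-separated),
#'   `n_steps`, `phase`.
#' @export
enumerate_btps <- function(parent, rules = default_btp_rules(), max_steps = 2L) {
  if (max_steps < 0L) stop("max_steps must be >= 0")
  if (!nrow(rules)) {
    warning("empty rule table: parent-only candidate set")
    return(data.frame(mass = numeric(0), path = character(0),
                      n_steps = integer(0), phase = character(0)))
  }
  has_formula <- is.character(parent)
  parent_counts <- if (has_formula) parse_formula(parent) else NULL
  parent_mass <- if (has_formula) monoisotopic_mass(parent) else as.numeric(parent)
  deltas <- lapply(rules$change, elemental_change_counts)
  frontier <- list(list(mass = parent_mass, counts = parent_counts,
                        path = character(0), phase = "I"))
  out <- list()
  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (node in frontier) {
      for (r in seq_len(nrow(rules))) {
        counts <- node$counts
        if (has_formula) {
          counts <- apply_delta(node$counts, deltas[[r]])
          if (is.null(counts)) next  # impossible elemental loss
        }
        child <- list(mass = node$mass + rules$mass_shift[r],
                      counts = counts,
                      path = c(node$path, rules$name[r]),
                      phase = if (rules$phase[r] == "II" ||
                                  node$phase == "II") "II" else "I")
        nxt[[length(nxt) + 1L]] <- child
        out[[length(out) + 1L]] <- child
      }
    }
    frontier <- nxt
  }
  if (!length(out)) {
    return(data.frame(mass = numeric(0), path = character(0),
                      n_steps = integer(0), phase = character(0)))
  }
  cand <- data.frame(
    mass = vapply(out, `[[`, numeric(1), "mass"),
    path = vapply(out, function(n) paste(n$path, collapse = " > "), ""),
    n_steps = vapply(out, function(n) length(n$path), integer(1)),
    phase = vapply(out, `[[`, character(1), "phase"),
    stringsAsFactors = FALSE)
  # merge duplicate masses, keeping all generating paths
  key <- round(cand$mass, 9)
  merged <- do.call(rbind, lapply(split(cand, key), function(d) {
    d <- d[order(d$n_steps), , drop = FALSE]
    data.frame(mass = d$mass[1],
               path = paste(unique(d$path), collapse = " | "),
               n_steps = d$n_steps[1],
               phase = if (any(d$phase == "II")) "II" else "I",
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged[order(merged$mass), , drop = FALSE]
}

apply_delta <- function(counts, delta) {
  for (el in names(delta)) {
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + delta[[el]]
  }
  if (any(counts < 0L)) return(NULL)
  counts
}

#' Match features against biotransformation-product candidates
#'
#' Each feature's implied neutral mass, under every adduct hypothesis of
#' the assay polarity, is compared to the candidate masses at the ppm
#' tolerance. Features may carry multiple annotations, ranked by |ppm
#' error|; the shortest rule path wins ties.
#'
#' @param features data.frame with `feature_id` and `mz`.
#' @param candidates Candidate table from [enumerate_btps()].
#' @param ppm Mass tolerance (ppm, on the implied neutral mass versus the
#'   candidate mass).
#' @param polarity Adduct polarity restriction (default `"both"`).
#' @param source_artifact_caveat Flag every hit as potentially an in-source
#'   artifact (set for assays without retention time, where analytical and
#'   biological transformation products cannot be distinguished).
#' @return data.frame of `BtpCandidate` rows: `feature_id`, `mz`, `adduct`,
#'   `candidate_mass`, `path`, `n_steps`, `phase`, `ppm_error`, `rank`,
#'   `source_artifact_caveat`.
#' @export
match_btps <- function(features, candidates, ppm, polarity = "both",
                       source_artifact_caveat = FALSE) {
  tab <- adduct_table()
  if (polarity != "both") tab <- tab[tab$polarity == polarity, , drop = FALSE]
  hits <- NULL
  for (i in seq_len(nrow(features))) {
    fhits <- NULL
    for (a in seq_len(nrow(tab))) {
      neutral <- features$mz[i] * abs(tab$charge[a]) - tab$mass_delta[a]
      err <- ppm_error(neutral, candidates$mass)
      sel <- which(abs(err) <= ppm)
      if (length(sel)) {
        fhits <- rbind(fhits, data.frame(
          feature_id = features$feature_id[i], mz = features$mz[i],
          adduct = tab$adduct[a], candidate_mass = candidates$mass[sel],
          path = candidates$path[sel], n_steps = candidates$n_steps[sel],
          phase = candidates$phase[sel], ppm_error = err[sel],
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(fhits)) {
      fhits <- fhits[order(abs(fhits$ppm_error), fhits$n_steps), , drop = FALSE]
      fhits$rank <- seq_len(nrow(fhits))
      hits <- rbind(hits, fhits)
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(feature_id = character(0), mz = numeric(0),
                       adduct = character(0), candidate_mass = numeric(0),
                       path = character(0), n_steps = integer(0),
                       phase = character(0), ppm_error = numeric(0),
                       rank = integer(0), stringsAsFactors = FALSE)
  }
  hits$source_artifact_caveat <- source_artifact_caveat
  rownames(hits) <- NULL
  hits
}

#' Summarise the fate of the exposure xenobiotics
#'
#' Per xenobiotic and compartment: whether the parent was detected, the
#' number of distinct biotransformation-product features, the phase I
#' fraction, and the set of rule paths seen in both compartments.
#'
#' @param fate_tables Named list (by compartment) of lists with elements
#'   `parents` (per-xenobiotic parent-hit data.frames) and `btps`
#'   (per-xenobiotic `BtpCandidate` tables, best-rank rows used).
#' @return List with `summary` (data.frame) and `overlap` (per-xenobiotic
#'   rule paths discovered in every compartment).
#' @export
summarize_fate <- function(fate_tables) {
  rows <- NULL
  paths <- list()
  for (comp in names(fate_tables)) {
    ft <- fate_tables[[comp]]
    xenos <- union(names(ft$parents), names(ft$btps))
    for (xeno in xenos) {
      p <- ft$parents[[xeno]]
      b <- ft$btps[[xeno]]
      if (!is.null(b) && nrow(b)) b <- b[b$rank == 1L, , drop = FALSE]
      n_btp <- if (is.null(b)) 0L else length(unique(b$feature_id))
      phase1 <- if (is.null(b) || !nrow(b)) NA_real_ else
        mean(b$phase[!duplicated(b$feature_id)] == "I")
      rows <- rbind(rows, data.frame(
        compartment = comp, xenobiotic = xeno,
        parent_detected = !is.null(p) && nrow(p) > 0,
        n_btp = n_btp, phase1_fraction = phase1,
        stringsAsFactors = FALSE))
      paths[[xeno]][[comp]] <- if (is.null(b)) character(0) else unique(b$path)
    }
  }
  overlap <- lapply(paths, function(pl) {
    if (length(pl) < 2L) return(character(0))
    Reduce(intersect, pl)
  })
  list(summary = rows, overlap = overlap)
}
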