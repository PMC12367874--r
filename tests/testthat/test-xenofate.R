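test_that("rule mass shifts are consistent with their elemental changes", {
  rules <- default_btp_rules()
  # spot values from monoisotopic element masses
  expect_equal(rules$mass_shift[rules$name == "hydroxylation"], 15.9949146,
               tolerance = 1e-4)
  expect_equal(rules$mass_shift[rules$name == "demethylation"], -14.0156500,
               tolerance = 1e-4)
  expect_equal(rules$mass_shift[rules$name == "glucuronidation"], 176.0320880,
               tolerance = 1e-4)
  expect_equal(rules$mass_shift[rules$name == "sulfation"], 79.9568146,
               tolerance = 1e-4)
  # every shift agrees with an independent recomputation from element masses
  for (i in seq_len(nrow(rules))) {
    expect_equal(rules$mass_shift[i],
                 cardiotoxsig:::elemental_change_mass(rules$change[i]),
                 tolerance = 1e-10)
  }
  expect_identical(sum(rules$phase == "I"), 12L)
  expect_identical(sum(rules$phase == "II"), 4L)
})

test_that("two-step enumeration produces exactly the hand-enumerated masses", {
  rules <- data.frame(name = c("ox", "deme"), change = c("+O", "-CH2"),
                      mass_shift = c(15.9949, -14.0157),
                      phase = c("I", "I"), stringsAsFactors = FALSE)
  cand <- enumerate_btps(300.0000, rules, max_steps = 2)
  expect_setequal(round(cand$mass, 4),
                  c(315.9949, 285.9843, 331.9898, 301.9792, 271.9686))
  # duplicate masses merged: +O then -CH2 equals -CH2 then +O
  both <- cand[round(cand$mass, 4) == 301.9792, ]
  expect_identical(nrow(both), 1L)
  expect_match(both$path, "\\|")
  # combinatorial bound: <= R + R^2 candidates at 2 steps
  expect_lte(nrow(cand), 2 + 4)
  # zero steps -> empty set
  expect_identical(nrow(enumerate_btps(300, rules, max_steps = 0)), 0L)
})

test_that("element bookkeeping blocks impossible losses", {
  rules <- default_btp_rules()
  # fluorouracil C4H3FN2O2 has no CH2 to lose once defluorinated etc.;
  # a molecule without F can never undergo defluorination
  cand <- enumerate_btps("C8H11N5O3", rules, max_steps = 1)  # acyclovir
  expect_false(any(grepl("defluorination", cand$path)))
  # with fluorine present the rule applies
  cand_f <- enumerate_btps("C22H27FN4O2", rules, max_steps = 1)  # sunitinib
  expect_true(any(grepl("defluorination", cand_f$path)))
  # phase label: any phase II step on the path makes the candidate phase II
  cand2 <- enumerate_btps("C8H11N5O3", rules, max_steps = 2)
  gluc <- cand2[grepl("glucuronidation", cand2$path), ]
  expect_true(all(gluc$phase == "II"))
  # empty rule table warns and returns nothing
  expect_warning(none <- enumerate_btps("C8H11N5O3", rules[0, ], 2),
                 "empty rule table")
  expect_identical(nrow(none), 0L)
})

test_that("parent matching respects adducts and the ppm window", {
  M <- monoisotopic_mass("C8H11N5O3")  # acyclovir
  feats <- data.frame(
    feature_id = c("hit_h", "hit_na", "off"),
    mz = c(expected_ion_mz(M, "[M+H]+"),
           expected_ion_mz(M, "[M+Na]+"),
           expected_ion_mz(M, "[M+H]+") * (1 + 10e-6)),  # 10 ppm away
    stringsAsFactors = FALSE)
  hits <- match_parent(feats, "C8H11N5O3", ppm = 5, polarity = "positive")
  expect_setequal(hits$feature_id, c("hit_h", "hit_na"))
  expect_identical(hits$adduct[hits$feature_id == "hit_na"], "[M+Na]+")
  expect_true(all(abs(hits$ppm_error) < 0.01))
})

test_that("BTP matching annotates rule paths, phases and ranks ties", {
  M <- 400.0
  rules <- default_btp_rules()
  cand <- enumerate_btps(M, rules, max_steps = 2)
  feats <- data.frame(
    feature_id = c("ox1", "gluc", "far"),
    mz = c(expected_ion_mz(M + 15.9949146, "[M+H]+"),
           expected_ion_mz(M + 176.0320880, "[M+H]+"),
           # a fractional mass offset no rule combination can produce
           expected_ion_mz(M + 0.35, "[M+H]+")),
    stringsAsFactors = FALSE)
  hits <- match_btps(feats, cand, ppm = 5, polarity = "positive")
  ox <- hits[hits$feature_id == "ox1" & hits$rank == 1, ]
  expect_match(ox$path, "hydroxylation")
  expect_identical(ox$phase, "I")
  expect_identical(ox$n_steps, 1L)
  gl <- hits[hits$feature_id == "gluc" & hits$rank == 1, ]
  expect_match(gl$path, "glucuronidation")
  expect_identical(gl$phase, "II")
  expect_false("far" %in% hits$feature_id)
})

test_that("xenobiotic feature discovery recovers planted features specifically", {
  study <- default_recovery_study()
  pm <- study$matrices$hilic_pos
  truth <- study$truth$hilic_pos
  found <- discover_all_xenobiotic_features(pm)
  planted_ids <- c(truth$parents$feature_id[truth$parents$detectable],
                   truth$btps$feature_id)
  all_found <- unlist(found)
  expect_true(all(planted_ids %in% all_found))
  # nothing endogenous is called xenobiotic-related
  expect_length(setdiff(all_found, c(truth$parents$feature_id,
                                     truth$btps$feature_id)), 0L)
  # per-xenobiotic assignment is correct
  for (xeno in names(found)) {
    expected <- c(truth$parents$feature_id[truth$parents$xenobiotic == xeno &
                                             truth$parents$detectable],
                  truth$btps$feature_id[truth$btps$xenobiotic == xeno])
    expect_setequal(found[[xeno]], expected)
  }
  # the undetectable parent (doxorubicin, below the floor) is not discovered
  expect_false(any(truth$parents$feature_id[!truth$parents$detectable] %in%
                     all_found))
  # unknown xenobiotic errors
  expect_error(discover_xenobiotic_features(pm, "aspirin"), "aspirin")
})

test_that("end-to-end fate: parents and one-step products annotated", {
  study <- default_recovery_study()
  pm <- study$matrices$hilic_pos
  truth <- study$truth$hilic_pos
  design <- study$design
  found <- discover_all_xenobiotic_features(pm)
  rules <- default_btp_rules()
  parents <- list(); btps <- list()
  for (xeno in design$xenobiotic) {
    ids <- found[[xeno]]
    if (is.null(ids) || !length(ids)) next
    feats <- pm$feature_meta[pm$feature_meta$feature_id %in% ids, ]
    ph <- match_parent(feats, design$formula[design$xenobiotic == xeno],
                       ppm = 5, polarity = "positive")
    cand <- enumerate_btps(design$formula[design$xenobiotic == xeno],
                           rules, max_steps = 2)
    rest <- feats[!feats$feature_id %in% ph$feature_id, ]
    bh <- match_btps(rest, cand, ppm = 5, polarity = "positive")
    parents[[xeno]] <- ph; btps[[xeno]] <- bh
  }
  det <- truth$parents$xenobiotic[truth$parents$detectable]
  expect_setequal(names(Filter(nrow, parents)), det)
  # >= 90% of planted one-step products recovered with the right rule
  n_ok <- 0L
  for (i in seq_len(nrow(truth$btps))) {
    b <- btps[[truth$btps$xenobiotic[i]]]
    hit <- b[b$feature_id == truth$btps$feature_id[i] & b$rank == 1, ]
    if (nrow(hit) && grepl(truth$btps$rule[i], hit$path)) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / nrow(truth$btps), 0.9)
  # fate summary: phase I fraction reflects the planted mix
  fate <- summarize_fate(list(footprint = list(parents = parents, btps = btps)))
  expect_true(all(fate$summary$parent_detected[
    fate$summary$xenobiotic %in% det]))
  planted_phase1 <- mean(truth$btps$phase == "I")
  overall <- sum(fate$summary$n_btp * fate$summary$phase1_fraction,
                 na.rm = TRUE) / sum(fate$summary$n_btp, na.rm = TRUE)
  expect_equal(overall, planted_phase1, tolerance = 0.15)
})

test_that("fate summary handles fixtures and empty inputs", {
  # 9 phase I + 1 phase II planted products -> phase I fraction 0.9
  btp_tab <- data.frame(
    feature_id = sprintf("b%d", 1:10),
    path = c(rep("hydroxylation", 9), "glucuronidation"),
    phase = c(rep("I", 9), "II"), rank = 1L, stringsAsFactors = FALSE)
  fate <- summarize_fate(list(
    intracellular = list(parents = list(drugx = data.frame(feature_id = "p1")),
                         btps = list(drugx = btp_tab))))
  expect_equal(fate$summary$phase1_fraction, 0.9)
  expect_identical(fate$summary$n_btp, 10L)
  # no products at all: empty rows, no failure
  fate2 <- summarize_fate(list(
    footprint = list(parents = list(drugy = data.frame(feature_id = "p2")),
                     btps = list())))
  expect_identical(fate2$summary$n_btp, 0L)
  # a product found in both compartments appears in the overlap
  fate3 <- summarize_fate(list(
    footprint = list(parents = list(), btps = list(drugx = btp_tab[1, ])),
    intracellular = list(parents = list(), btps = list(drugx = btp_tab[1, ]))))
  expect_identical(fate3$overlap$drugx, "hydroxylation")
})
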