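# Shared fixtures, all built in code.

# A tiny hand-built peak matrix with every sample type used by the filters.
tiny_peak_matrix <- function() {
  fm <- data.frame(
    feature_id = c("F1", "F2", "F3"),
    mz = c(100.05, 200.10, 300.15),
    rt = c(120, 125, 400),
    polarity = "positive",
    assay_id = "toy",
    stringsAsFactors = FALSE
  )
  sm <- data.frame(
    sample_id = c("b1", "b2", "c1", "c2", "q1", "k1"),
    batch = c("A", "A", "A", "A", "none", "none"),
    xenobiotic = c("drugx", "drugx", "none", "none", "none", "none"),
    concentration_level = c("high", "high", "none", "none", "none", "none"),
    duration = c(48, 48, 48, 48, NA, NA),
    replicate = c(1L, 2L, 1L, 2L, 1L, 1L),
    sample_type = c("biological", "biological", "control", "control",
                    "qc", "blank"),
    injection_order = 1:6,
    stringsAsFactors = FALSE
  )
  x <- matrix(c(100, 110, 90, 95, 100, 2,
                500, 520, 480, 510, 500, NA,
                10, NA, 12, 11, 10, 9),
              nrow = 3, byrow = TRUE)
  peak_matrix(x, fm, sm)
}

# Scaled-down simulation used by most pipeline tests: full design, one
# footprint assay, fewer features.
small_sim_config <- function(seed = 11, ...) {
  simulation_config(assays = default_assays()[5, ],
                    n_features = 200L, n_signature = 10L, n_signature_up = 3L,
                    n_contaminants = 5L, seed = seed, ...)
}

# The documented default synthetic study for recovery checks (memoised).
.study_cache <- new.env(parent = emptyenv())

default_recovery_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- simulation_config(assays = default_assays()[5, ], seed = 20260922)
    .study_cache$study <- generate_study(cfg)
  }
  .study_cache$study
}
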