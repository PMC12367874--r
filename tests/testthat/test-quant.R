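test_that("an exact line is recovered with no exclusions", {
  st <- data.frame(nominal = c(1, 2, 5, 10, 50), response = 2 * c(1, 2, 5, 10, 50))
  cc <- fit_calibration(st)
  expect_equal(cc$coefficients[2], 2, tolerance = 1e-12)
  expect_equal(cc$coefficients[1], 0, tolerance = 1e-12)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)
  expect_true(all(cc$standards$included))
  expect_identical(cc$lloq, 1)
  expect_identical(cc$uloq, 50)
})

test_that("a grossly deviating standard is excluded on the first iteration", {
  nominal <- c(1, 2, 5, 10, 20, 50)
  response <- 3 * nominal
  response[3] <- 3 * 5 * 1.6  # back-calculates ~60% high
  cc <- fit_calibration(data.frame(nominal = nominal, response = response))
  expect_false(cc$standards$included[3])
  expect_true(all(cc$standards$included[-3]))
  expect_length(cc$exclusion_trail, 1L)
  expect_equal(cc$coefficients[2], 3, tolerance = 1e-6)
})

test_that("exclusion terminates and errors when too few levels survive", {
  nominal <- c(1, 2, 5, 10, 20)
  response <- 3 * nominal
  response[5] <- 100 * 20
  expect_error(fit_calibration(data.frame(nominal = nominal,
                                          response = response)),
               "fewer than 5 levels")
})

test_that("1/x^2 weighting beats unweighted fits at the low end", {
  # constant relative error favours inverse-variance (1/x^2) weighting
  set.seed(42)
  nominal <- c(0.5, 1, 2, 5, 10, 50, 100)
  n_rep <- 200
  err_w <- err_u <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    resp <- 10 * nominal * exp(rnorm(length(nominal), 0, 0.08))
    w_fit <- stats::lm(resp ~ nominal, weights = 1 / nominal^2)
    u_fit <- stats::lm(resp ~ nominal)
    bc_w <- (10 * 0.5 - coef(w_fit)[1]) / coef(w_fit)[2]
    bc_u <- (10 * 0.5 - coef(u_fit)[1]) / coef(u_fit)[2]
    err_w[r] <- abs(bc_w - 0.5) / 0.5
    err_u[r] <- abs(bc_u - 0.5) / 0.5
  }
  expect_lt(mean(err_w), mean(err_u))
  # and the packaged weighted fit agrees with lm's weighted solution
  st <- data.frame(nominal = nominal,
                   response = 10 * nominal * exp(rnorm(7, 0, 0.05)))
  cc <- fit_calibration(st)
  ref <- stats::lm(response ~ nominal, data = st, weights = 1 / st$nominal^2)
  expect_equal(cc$coefficients, unname(coef(ref)), tolerance = 1e-9)
})

test_that("back-calculation inverts, flags and respects the LLOQ boundary", {
  st <- data.frame(nominal = c(1, 2, 5, 10, 50), response = 2 * c(1, 2, 5, 10, 50))
  cc <- fit_calibration(st)
  # slope-2 line: response 7 -> 3.5 uM
  expect_equal(back_calculate(cc, 7)$concentration, 3.5, tolerance = 1e-12)
  # response exactly at f(LLOQ) is quantifiable (inclusive boundary)
  at_lloq <- back_calculate(cc, 2 * 1)
  expect_equal(at_lloq$concentration, 1, tolerance = 1e-12)
  expect_identical(at_lloq$flag, "")
  expect_identical(back_calculate(cc, 1.9)$flag, "below_lloq")
  expect_identical(back_calculate(cc, 101)$flag, "above_uloq")
  expect_identical(back_calculate(cc, NA_real_)$flag, "not_detected")
})

test_that("a quadratic with two in-range roots is flagged ambiguous", {
  # response peaks inside the calibrated range: f(c) = 20c - c^2
  cc <- structure(list(form = "quadratic", coefficients = c(0, 20, -1),
                       lloq = 2, uloq = 12, weighting = "1/x^2"),
                  class = "CalibrationCurve")
  # response 96 is reached at c = 8 and c = 12, both inside the range
  out <- back_calculate(cc, 96)
  expect_identical(out$flag, "quantitation_ambiguous")
  expect_true(is.na(out$concentration))
  # fitting such data errors out: the curve is not invertible over the range
  nominal <- c(2, 5, 8, 12, 16, 18)
  expect_error(fit_calibration(data.frame(nominal = nominal,
                                          response = 20 * nominal - nominal^2),
                               form = "quadratic"),
               "calibration failed")
})

test_that("quant-QC accuracy and precision follow their definitions", {
  st <- data.frame(nominal = c(1, 2, 5, 10, 20), response = 2 * c(1, 2, 5, 10, 20))
  cc <- fit_calibration(st)
  # all calc == nominal -> accuracy 100%, precision 0%
  qq <- data.frame(nominal = c(2, 2, 10, 10), response = 2 * c(2, 2, 10, 10))
  ev <- evaluate_quant_qc(cc, qq)
  expect_equal(ev$accuracy_pct, 100, tolerance = 1e-9)
  expect_equal(ev$precision_rsd_pct, 0, tolerance = 1e-9)
  # duplicates back-calculating to {9, 11} at nominal 10: RSD = sd/mean
  qq2 <- data.frame(nominal = c(10, 10), response = 2 * c(9, 11))
  ev2 <- evaluate_quant_qc(cc, qq2)
  expect_equal(ev2$precision_rsd_pct, stats::sd(c(9, 11)) / 10 * 100,
               tolerance = 1e-9)
  expect_equal(ev2$precision_rsd_pct, 14.1421, tolerance = 1e-4)
  # a quant-QC at 35.2% deviation (7.0 measured vs 10.8 nominal) is accepted
  qq3 <- data.frame(nominal = c(10.8, 10.8), response = 2 * c(7.0, 7.0))
  ev3 <- evaluate_quant_qc(cc, qq3)
  expect_identical(nrow(ev3$rejected), 0L)
  expect_equal(ev3$accuracy_pct, 7.0 / 10.8 * 100, tolerance = 1e-6)
  # beyond 40% deviation every quant-QC is rejected -> run failed
  qq4 <- data.frame(nominal = c(10, 10), response = 2 * c(4, 4.5))
  expect_identical(evaluate_quant_qc(cc, qq4)$status, "run_failed")
})

test_that("scale equivariance: scaling all responses rescales only the slope", {
  st <- data.frame(nominal = c(1, 2, 5, 10, 50),
                   response = 2 * c(1, 2, 5, 10, 50) + 0.5)
  cc1 <- fit_calibration(st)
  st2 <- st; st2$response <- st$response * 7
  cc2 <- fit_calibration(st2)
  expect_equal(cc2$coefficients, cc1$coefficients * 7, tolerance = 1e-9)
  expect_equal(back_calculate(cc2, 7 * 8)$concentration,
               back_calculate(cc1, 8)$concentration, tolerance = 1e-9)
})

test_that("Holm adjustment matches the step-down computation", {
  # single p-value family: Holm is the identity
  expect_identical(stats::p.adjust(0.03, method = "holm"), 0.03)
  # {0.01, 0.04, 0.03} -> {0.03, 0.06, 0.06}
  expect_equal(stats::p.adjust(c(0.01, 0.04, 0.03), method = "holm"),
               c(0.03, 0.06, 0.06), tolerance = 1e-12)
})

test_that("concentration comparisons behave on identical and structured data", {
  design <- default_study_design()
  # identical group means -> all adjusted p = 1
  m <- expand.grid(duration = c(6, 48, 72), replicate = 1:4)
  m$xenobiotic <- "dasatinib"; m$concentration_level <- "high"
  m$sample_type <- "biological"
  set.seed(1)
  base <- rnorm(4, 10, 0.3)
  m$concentration <- rep(base, each = 3)  # same values in every duration
  cmp <- compare_concentrations(m, design)
  expect_true(all(cmp$between_durations$p_holm == 1))
  # measured far below nominal 10.8 -> significant one-sample test
  m2 <- m; m2$concentration <- rnorm(nrow(m2), 5, 0.2)
  cmp2 <- compare_concentrations(m2, design)
  expect_lt(cmp2$vs_nominal$p_holm[1], 0.01)
  expect_equal(cmp2$vs_nominal$nominal[1], 10.8)
  # groups with < 2 values are skipped with a reason
  m3 <- m[m$replicate == 1, ]
  cmp3 <- compare_concentrations(m3, design)
  expect_true(nrow(cmp3$skipped) > 0)
})

test_that("end-to-end quantitation on generated calibration data", {
  study <- default_recovery_study()
  cal <- study$calibration
  ok <- 0L; failed <- character(0)
  for (xeno in study$design$xenobiotic) {
    st <- cal$standards[cal$standards$xenobiotic == xeno, ]
    cc <- fit_calibration(st)
    slope <- cal$truth$slopes[[xeno]]
    expect_equal(cc$coefficients[2], slope, tolerance = 0.1)
    s <- cal$samples[cal$samples$xenobiotic == xeno &
                       cal$samples$sample_type == "biological", ]
    bc <- back_calculate(cc, s$response)
    quantified <- bc$flag == ""
    if (xeno == "doxorubicin") {
      # the doxorubicin path: everything below the quantitation limit
      expect_true(all(bc$flag %in% c("below_lloq", "not_detected")))
      failed <- c(failed, xeno)
    } else {
      expect_gt(mean(quantified), 0.8)
      expect_equal(median(bc$concentration[quantified] /
                            s$true_concentration[quantified]), 1,
                   tolerance = 0.05)
      ok <- ok + 1L
    }
  }
  expect_identical(ok, 11L)
  expect_identical(failed, "doxorubicin")
})
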