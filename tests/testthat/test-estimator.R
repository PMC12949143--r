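test_that("deltas are referenced to breath 0, second one cumulatively", {
  expect_equal(compute_deltas(c(5.0, 5.2, 5.4)),
               list(av_pet = 5.0, delta_pet1 = 0.2, delta_pet2 = 0.4))
  d <- compute_deltas(c(5.0, 5.2, 5.37))
  expect_equal(d$delta_pet2, 0.37)
  expect_error(compute_deltas(c(5.0, 5.2)), "insufficient breaths")
  expect_error(compute_deltas(c(5.0, 4.9, 5.1)), "non-rising")
  # non-strict mode returns the deltas for QC to inspect
  expect_equal(compute_deltas(c(5.0, 4.9, 5.1), strict = FALSE)$delta_pet1,
               -0.1, tolerance = 1e-12)
})

test_that("second-breath weight follows the wash-in kinetics", {
  expect_equal(second_breath_weight(0, 5), 0.5)          # linear limit
  expect_equal(second_breath_weight(0.06, 5.0), 1 / (1 + exp(-0.3)))
  expect_equal(round(second_breath_weight(0.06, 5.0), 2), 0.57)
  expect_equal(second_breath_weight(1e6, 5), 1.0)        # plateau limit
})

test_that("two-breath formula collapses to the single-breath one when linear", {
  # linear kinetics: D2 = 2 D1, w = 0.5 -> ELV = avPet DV / D1
  expect_equal(estimate_elv(5.0, 0.148, 0.2, 0.4, weight = 0.5),
               5.0 * 0.148 / 0.2)
  expect_equal(estimate_elv(5.0, 0.148, 0.2, 0.4, weight = 0.5), 3.7)
  expect_error(estimate_elv(5.0, 0.148, -0.3, 0.1, weight = 0.57),
               "non-rising")
})

test_that("ELV is invariant to the pressure unit", {
  kpa <- estimate_elv(5.0, 0.148, 0.2, 0.37)
  mmhg <- estimate_elv(5.0 * 7.50062, 0.148, 0.2 * 7.50062, 0.37 * 7.50062)
  expect_equal(kpa, mmhg, tolerance = 1e-12)
})

test_that("ELV moves the right way with each input", {
  base <- estimate_elv(5, 0.148, 0.2, 0.37)
  expect_lt(estimate_elv(5, 0.148, 0.25, 0.37), base)  # bigger rise, smaller lung
  expect_lt(estimate_elv(5, 0.148, 0.2, 0.45), base)
  expect_gt(estimate_elv(5.5, 0.148, 0.2, 0.37), base)
  expect_gt(estimate_elv(5, 0.160, 0.2, 0.37), base)
})

test_that("FRC conversion applies the proportionality constant", {
  expect_equal(convert_elv_to_frc(1.0), 0.82)
  expect_equal(convert_elv_to_frc(3.7), 3.034)
  expect_equal(convert_elv_to_frc(2.5, k_constant = 1), 2.5)
  # disease-specific constants pass through
  expect_equal(convert_elv_to_frc(3.0, 0.77), 2.31)
  expect_error(convert_elv_to_frc(-1))
})

test_that("estimate is internally consistent on a zero-noise fixture", {
  tr <- ideal_trace(elv_true = 3.0, rr = 12)
  est <- estimate_rebreathing(tr, weight = "auto")
  # the two printed forms of the estimator agree to machine precision
  expect_equal(est$delta_pet,
               0.5 * (est$delta_pet1 + est$weight_w * est$delta_pet2))
  expect_equal(est$elv, est$av_pet * est$dead_space$volume / est$delta_pet,
               tolerance = 1e-12)
  expect_equal(est$frc, 0.82 * est$elv)
  expect_equal(est$elv, 3.0, tolerance = 1e-9)
})

test_that("exact recovery holds with the analytic weight on segments", {
  p <- ideal_params(elv_true = 3.0, rr = 12)
  tr <- simulate_capnogram(p, 6)
  segs <- segment_breaths(tr)
  w <- second_breath_weight(p$k_rate, 60 / p$rr)
  d <- compute_deltas(segs)
  expect_equal(estimate_elv(d$av_pet, 0.148, d$delta_pet1, d$delta_pet2, w),
               3.0, tolerance = 1e-9)
})

test_that("fixed weight 0.57 is accurate near the typical breathing rate", {
  # zero-noise bias with the fixed weight: bounded by 10% over the clinical
  # RR range, positive (over-estimation) at slow rates, negative at fast,
  # crossing zero near 12-13 breaths/min
  err <- vapply(c(4.6, 8, 11, 12, 14, 16.8), function(rr) {
    est <- estimate_rebreathing(ideal_trace(elv_true = 3, rr = rr),
                                weight = 0.57)
    (est$elv - 3) / 3
  }, 0)
  expect_true(all(abs(err) < 0.10))
  expect_gt(err[1], 0)                 # RR 4.6
  expect_lt(err[6], 0)                 # RR 16.8
  expect_true(any(diff(sign(err)) != 0))
})

test_that("kinetics fit recovers the rate constant", {
  T_b <- 60 / 11
  tt <- (0:7) * T_b
  pet <- 5 + 1.2 * (1 - exp(-0.06 * tt))
  f <- fit_rebreathing_kinetics(pet, tt)
  expect_equal(f$k_rate, 0.06, tolerance = 1e-6)
  expect_equal(f$pet0, 5, tolerance = 1e-6)
  expect_error(fit_rebreathing_kinetics(c(5, 5.2), c(0, 5)), "at least 4")
  expect_error(fit_rebreathing_kinetics(pet[1:4], tt[1:4] / 3), "15 s")
})

test_that("kinetics fit tolerates measurement noise (Monte-Carlo)", {
  T_b <- 60 / 11
  tt <- (0:7) * T_b                    # spans ~38 s
  pet <- 5 + 1.2 * (1 - exp(-0.06 * tt))
  ks <- vapply(1:50, function(i) {
    set.seed(i)
    fit_rebreathing_kinetics(pet + rnorm(8, 0, 0.05), tt)$k_rate
  }, 0)
  expect_lt(abs(stats::median(ks) - 0.06) / 0.06, 0.10)
})

test_that("QC flags the documented failure modes and nothing else", {
  segs <- segment_breaths(ideal_trace())
  # DV/TV outside the operating envelope
  expect_true("dv_tv_low" %in% qc_measurement(segs, 0.148, tv_estimate = 1.7))
  expect_true("dv_tv_high" %in% qc_measurement(segs, 0.148, tv_estimate = 0.5))
  expect_length(qc_measurement(segs, 0.148, tv_estimate = 1.1), 0)
  # equal breath periods: no irregularity
  expect_false("irregular" %in% qc_measurement(segs, 0.148))
  # non-rising Pet pattern
  bad <- segs; bad$pet <- c(5.0, 4.8, 5.1, 5.2, 5.3, 5.4)
  expect_true("leak_suspected" %in% qc_measurement(bad, 0.148))
  bad2 <- segs; bad2$pet <- c(5.0, 5.4, 5.2, 5.5, 5.6, 5.7)
  expect_true("leak_suspected" %in% qc_measurement(bad2, 0.148))
  # too few breaths never throws, it flags
  expect_true("insufficient_breaths" %in%
                qc_measurement(segs[1:2, ], 0.148))
  expect_true("insufficient_breaths" %in% qc_measurement(NULL, 0.148))
})

test_that("leak-injected fixture is flagged, not estimated", {
  tr <- inject_artifacts(ideal_trace(), "leak", 0.5)
  est <- estimate_rebreathing(tr)
  expect_true("leak_suspected" %in% est$qc_flags)
  expect_true(is.na(est$elv))
})

test_that("repeating a noisy measurement shrinks the spread by about sqrt(2)", {
  # two independent measurements of the same subject, averaged
  single <- vapply(1:150, function(i) {
    p <- simulator_params(elv_true = 3, seed = i)
    estimate_rebreathing(simulate_capnogram(p, 6))$elv
  }, 0)
  paired <- (single[seq(1, 149, 2)] + single[seq(2, 150, 2)]) / 2
  ratio <- stats::sd(paired) / stats::sd(single)
  expect_gt(ratio, 1 / sqrt(2) - 0.2)
  expect_lt(ratio, 1 / sqrt(2) + 0.2)
})
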