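test_that("parameter validation refuses unphysical configurations", {
  expect_error(simulator_params(elv_true = -1), "elv_true")
  expect_error(simulator_params(rr = 50), "rr")
  expect_error(simulator_params(dead_space = 0.8, tv = 1.1), "outside")
  expect_error(simulator_params(k_rate = 0), "k_rate")
})

test_that("first-breath rise equals the ideal single-breath increment", {
  # pet0 * DV / ELV = 5 * 0.148 / 3.7 = 0.2 kPa, independent of k
  for (k in c(0.01, 0.06, 0.3)) {
    p <- simulator_params(elv_true = 3.7, pet0 = 5, dead_space = 0.148,
                          k_rate = k)
    gt <- simulate_pet_sequence(p, 4)
    expect_equal(gt$pet_seq[2] - gt$pet_seq[1], 0.2, tolerance = 1e-12)
    expect_equal(gt$per_breath_increment_ideal, 0.2, tolerance = 1e-12)
  }
})

test_that("slow-kinetics limit gives constant per-breath increments", {
  # for k*T <= 0.01 successive increments agree to within 1%
  p <- simulator_params(rr = 12, k_rate = 0.002)  # k*T = 0.01
  gt <- simulate_pet_sequence(p, 8)
  inc <- diff(gt$pet_seq)
  expect_true(all(abs(inc[-1] / inc[-length(inc)] - 1) < 0.01))
})

test_that("Pet approaches but never exceeds the plateau", {
  p <- simulator_params()
  gt <- simulate_pet_sequence(p, 60)
  ceiling_p <- p$pet0 + gt$delta_p_inf
  expect_true(all(gt$pet_seq <= ceiling_p + 1e-12))
  expect_lt(ceiling_p - gt$pet_seq[60], 1e-3)
  expect_true(all(diff(gt$pet_seq) > 0))
})

test_that("continuous-time wash-in reaches 90% of plateau in 30-40 s", {
  # 1 - exp(-k t) = 0.9  =>  t = ln(10)/k
  t90 <- log(10) / 0.06
  expect_gt(t90, 30)
  expect_lt(t90, 40)
})

test_that("waveform synthesis is deterministic given a seed", {
  a <- simulate_capnogram(simulator_params(seed = 11), 5)
  b <- simulate_capnogram(simulator_params(seed = 11), 5)
  expect_identical(a$pco2, b$pco2)
  c <- simulate_capnogram(simulator_params(seed = 12), 5)
  expect_false(identical(a$pco2, c$pco2))
})

test_that("seeded synthesis does not disturb the caller's RNG stream", {
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(simulate_capnogram(simulator_params(seed = 1), 4))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("undistorted waveform reads back the ground-truth Pet", {
  for (rr in c(5, 12, 16.8)) {
    tr <- ideal_trace(rr = rr)
    segs <- segment_breaths(tr)
    expect_lt(max(abs(segs$pet - attr(tr, "ground_truth")$pet_seq)), 1e-6)
  }
})

test_that("extracted Pet stays within noise of ground truth (Monte-Carlo)", {
  maes <- vapply(1:100, function(i) {
    p <- simulator_params(noise_sd = 0.05, analyzer_tau = 0,
                          transport_delay = 0, seed = i)
    tr <- simulate_capnogram(p, 5)
    segs <- segment_breaths(tr)
    gt <- attr(tr, "ground_truth")$pet_seq
    if (nrow(segs) == 5) mean(abs(segs$pet - gt)) else NA_real_
  }, 0)
  expect_lt(mean(maes, na.rm = TRUE), 0.05)
})

test_that("artifact injection: severity limit, modes, and signatures", {
  tr <- ideal_trace()
  expect_error(inject_artifacts(tr, "leak", 0), "severity")
  expect_error(inject_artifacts(tr, "nonsense", 0.5))
  # vanishing severity returns the trace essentially unchanged
  tiny <- inject_artifacts(tr, "irregular_breathing", 1e-9, seed = 5)
  n <- min(length(tiny$pco2), length(tr$pco2))
  expect_lt(max(abs(tiny$pco2[1:n] - tr$pco2[1:n])), 1e-6)
  # leak halves all rebreathing-phase pressures from breath 1 onward
  lk <- inject_artifacts(tr, "leak", 0.5)
  br <- attr(tr, "breaths")
  after <- tr$times >= br$t_exp_start[2]
  expect_equal(lk$pco2[after], tr$pco2[after] * 0.5)
  expect_equal(lk$pco2[!after], tr$pco2[!after])
})

test_that("a small leak biases the volume estimate high", {
  # dead-space CO2 escaping shrinks the apparent Pet rise, inflating ELV;
  # severity must stay below the relative first-breath rise (~5%) for the
  # rise to remain positive at all
  tr <- ideal_trace(elv_true = 3.0)
  est <- estimate_rebreathing(inject_artifacts(tr, "leak", 0.03))
  expect_gt(est$elv, 3.0)
})

test_that("severe irregular breathing is caught by the QC", {
  tr <- inject_artifacts(ideal_trace(), "irregular_breathing", 0.5, seed = 3)
  est <- estimate_rebreathing(tr)
  expect_gt(length(setdiff(est$qc_flags, c("dv_tv_low", "dv_tv_high"))), 0)
})

test_that("simulated trace round-trips through CSV with ground-truth sidecar", {
  tr <- ideal_trace()
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulated_trace(tr, path)
  back <- read_capnogram_csv(path)
  expect_lt(max(abs(back$pco2 - tr$pco2)), 1e-9)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$params$elv_true, 3.0)
  expect_length(side$ground_truth$pet_seq, 6)
})
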