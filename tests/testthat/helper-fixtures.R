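# fixture builders shared across test files

# simulator parameters for an undistorted measurement (no noise, no analyzer
# lag, no transport delay): the exact-recovery oracle conditions
ideal_params <- function(elv_true = 3.0, rr = 12, ...) {
  simulator_params(elv_true = elv_true, rr = rr, noise_sd = 0,
                   analyzer_tau = 0, transport_delay = 0, ...)
}

ideal_trace <- function(elv_true = 3.0, rr = 12, n_breaths = 6, ...) {
  simulate_capnogram(ideal_params(elv_true = elv_true, rr = rr, ...),
                     n_breaths = n_breaths)
}

# pair table for a simulated cohort: known FRC truths, reference = truth,
# method = truth + bias + N(0, noise_sd), n_rep replicates per subject
cohort_pairs <- function(n_subjects = 10, noise_sd = 0.3, bias = 0,
                         n_rep = 1, frc_range = c(2.5, 3.5)) {
  frc <- stats::runif(n_subjects, frc_range[1], frc_range[2])
  measurement_pairs(
    subject_id = rep(sprintf("s%02d", seq_len(n_subjects)), each = n_rep),
    replicate = rep(seq_len(n_rep), n_subjects),
    method_value = pmax(rep(frc, each = n_rep) + bias +
                          stats::rnorm(n_subjects * n_rep, 0, noise_sd), 0.1),
    reference_value = rep(frc, each = n_rep))
}
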