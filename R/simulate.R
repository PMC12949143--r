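#' Simulator parameter set
#'
#' Ground-truth lung and breathing parameters driving synthetic rebreathing
#' capnogram generation. Defaults describe a typical healthy adult breathing
#' through the standard external dead space: effective lung volume 3.7 L
#' (FRC about 3 L at FRC = 0.82 ELV), tidal volume 1.1 L and respiratory
#' rate 11 breaths/min (the study-population means), dead space 0.148 L,
#' baseline end-tidal CO2 5 kPa, wash-in rate constant 0.06 s^-1, and
#' typical sidestream-analyzer figures for noise (SD 0.05 kPa), first-order
#' lag (0.15 s) and transport delay (0.5 s).
#'
#' @param elv_true true effective lung volume, litres.
#' @param frc_true true FRC, litres; defaults to `k_constant * elv_true`.
#' @param k_constant FRC/ELV proportionality used for `frc_true` (0.82).
#' @param tv tidal volume, litres.
#' @param rr respiratory rate, breaths/min (0 < rr <= 40).
#' @param dead_space external dead-space volume DV, litres.
#' @param pet0 baseline end-tidal CO2 pressure, kPa.
#' @param k_rate rebreathing wash-in rate constant, s^-1.
#' @param noise_sd additive Gaussian noise SD, kPa.
#' @param analyzer_tau analyzer first-order lag time constant, s.
#' @param transport_delay sample-transport delay, s.
#' @param sample_rate sampling frequency, Hz.
#' @param seed RNG seed for the noise stream (NULL = use current RNG state).
#' @return an object of class `simulator_params` (named list).
#' @export
simulator_params <- function(elv_true = 3.7, frc_true = NULL, k_constant = 0.82,
                             tv = 1.1, rr = 11, dead_space = 0.148,
                             pet0 = 5.0, k_rate = 0.06, noise_sd = 0.05,
                             analyzer_tau = 0.15, transport_delay = 0.5,
                             sample_rate = 25, seed = NULL) {
  if (is.null(frc_true)) frc_true <- k_constant * elv_true
  p <- list(elv_true = elv_true, frc_true = frc_true, k_constant = k_constant,
            tv = tv, rr = rr, dead_space = dead_space, pet0 = pet0,
            k_rate = k_rate, noise_sd = noise_sd, analyzer_tau = analyzer_tau,
            transport_delay = transport_delay, sample_rate = sample_rate,
            seed = seed)
  if (!(elv_true > 0)) stop("elv_true must be > 0")
  if (!(tv > 0)) stop("tv must be > 0")
  if (!(rr > 0 && rr <= 40)) stop("rr must be in (0, 40] breaths/min")
  if (!(dead_space > 0)) stop("dead_space must be > 0")
  if (!(k_rate > 0)) stop("k_rate must be > 0")
  if (!(pet0 > 0)) stop("pet0 must be > 0")
  r <- dead_space / tv
  if (!(r > 0 && r < 0.5))
    stop(sprintf("dead_space/tv = %.3f is outside (0, 0.5): unphysical configuration", r))
  if (noise_sd < 0 || analyzer_tau < 0 || transport_delay < 0)
    stop("noise_sd, analyzer_tau and transport_delay must be >= 0")
  structure(p, class = "simulator_params")
}

#' Breath-wise end-tidal sequence with known ground truth
#'
#' The end-tidal CO2 during rebreathing follows a single-exponential wash-in
#' toward a plateau. With breath period T = 60/rr and a = exp(-k_rate * T),
#' Pet(n) = pet0 + dp_inf * (1 - a^n) for breath n after rebreathing onset,
#' where breath 0 is the expiration that fills the dead space (Pet(0) =
#' pet0). The plateau rise is parameterised as
#' dp_inf = pet0 * DV / (elv_true * (1 - a)), which makes the first-breath
#' rise exactly the ideal single-breath increment pet0 * DV / ELV, so
#' zero-noise parameter recovery by the two-breath estimator is exact.
#'
#' @param params a [simulator_params] object.
#' @param n_breaths number of breaths to generate (>= 3).
#' @return an object of class `rebreathing_ground_truth`: list with
#'   `pet_seq` (kPa, breaths 0..n-1), `delta_p_inf` (kPa),
#'   `per_breath_increment_ideal` (kPa), `breath_period` (s) and `a`
#'   (per-breath decay factor).
#' @export
simulate_pet_sequence <- function(params, n_breaths) {
  stopifnot(inherits(params, "simulator_params"), n_breaths >= 3)
  T_b <- 60 / params$rr
  a <- exp(-params$k_rate * T_b)
  inc_ideal <- params$pet0 * params$dead_space / params$elv_true
  dp_inf <- inc_ideal / (1 - a)
  n <- seq_len(n_breaths) - 1L
  pet <- params$pet0 + dp_inf * (1 - a^n)
  structure(list(pet_seq = pet, delta_p_inf = dp_inf,
                 per_breath_increment_ideal = inc_ideal,
                 breath_period = T_b, a = a),
            class = "rebreathing_ground_truth")
}

#' Render a ground-truth Pet sequence as a capnogram waveform
#'
#' Each breath is rendered as a sigmoid expiratory upstroke (default rise
#' 0.4 s), an alveolar plateau with positive slope terminating at that
#' breath's end-tidal value (held over the last few samples so the plateau
#' end is on the sample grid), and a sigmoid inspiratory downstroke. During
#' rebreathing the inspiratory trough is the dead-space gas CO2 level -- the
#' previous end-tidal decayed by 20% through fresh-gas-free mixing -- rather
#' than the near-zero level of open-air breathing. The ideal waveform is
#' then passed through a first-order analyzer lag, shifted by the transport
#' delay, and Gaussian noise is added (seeded, so traces are reproducible).
#'
#' @param ground_truth a `rebreathing_ground_truth` from
#'   [simulate_pet_sequence()].
#' @param params the [simulator_params] used to generate it.
#' @param rise_s expiratory upstroke duration, s.
#' @param fall_s inspiratory downstroke duration, s.
#' @param plateau_frac plateau start value as a fraction of that breath's
#'   Pet (default 0.97, i.e. the plateau climbs the last 3%).
#' @param trough_decay fraction of the previous end-tidal retained in the
#'   dead-space gas at the next inspiration (default 0.8).
#' @return a [capnogram_trace] with attributes `ground_truth`, `params` and
#'   `breaths` (ideal per-breath phase boundary times, used by
#'   [inject_artifacts()]).
#' @export
synthesize_waveform <- function(ground_truth, params, rise_s = 0.4,
                                fall_s = 0.3, plateau_frac = 0.97,
                                trough_decay = 0.8) {
  stopifnot(inherits(ground_truth, "rebreathing_ground_truth"),
            inherits(params, "simulator_params"))
  fs <- params$sample_rate
  dt <- 1 / fs
  T_b <- ground_truth$breath_period
  te <- 0.5 * T_b               # expiratory fraction 50%
  ti <- T_b - te
  pet <- ground_truth$pet_seq
  nb <- length(pet)
  lead_in <- 1.0                # pre-measurement inspiration of room air
  tail_s <- 0.5
  hold_s <- max(0.08, 2.5 * dt) # flat plateau end, >= 2 samples on the grid

  onset <- lead_in + (seq_len(nb) - 1L) * T_b   # expiration onsets
  total <- lead_in + nb * T_b + tail_s
  t <- seq(0, total, by = dt)
  # troughs: before breath 0 room air (~0); afterwards decayed dead-space gas
  trough <- c(0, trough_decay * pet)

  ideal <- numeric(length(t))
  ideal[t < onset[1L]] <- trough[1L]
  for (i in seq_len(nb)) {
    t0 <- onset[i]
    sel <- t >= t0 & t < t0 + T_b
    tt <- t[sel] - t0
    r <- min(rise_s, 0.4 * te)
    f <- min(fall_s, 0.4 * ti)
    p_lo <- trough[i]
    p_hi <- pet[i]
    p_pl0 <- plateau_frac * p_hi
    y <- numeric(length(tt))
    up <- tt < r
    y[up] <- p_lo + (p_pl0 - p_lo) * sigmoid01(tt[up] / r)
    pl <- tt >= r & tt < te - hold_s
    y[pl] <- p_pl0 + (p_hi - p_pl0) * (tt[pl] - r) / (te - hold_s - r)
    hd <- tt >= te - hold_s & tt < te
    y[hd] <- p_hi
    dn <- tt >= te & tt < te + f
    y[dn] <- p_hi - (p_hi - trough[i + 1L]) * sigmoid01((tt[dn] - te) / f)
    rest <- tt >= te + f
    y[rest] <- trough[i + 1L]
    ideal[sel] <- y
  }
  ideal[t >= onset[nb] + T_b] <- trough[nb + 1L]

  out <- ideal
  if (params$analyzer_tau > 0) {
    alpha <- 1 - exp(-dt / params$analyzer_tau)
    out <- stats::filter(alpha * ideal, 1 - alpha, method = "recursive",
                         init = ideal[1L])
    out <- as.numeric(out)
  }
  if (params$transport_delay > 0) {
    shift <- as.integer(round(params$transport_delay * fs))
    if (shift > 0) out <- c(rep(out[1L], shift), out)[seq_along(out)]
  }
  if (params$noise_sd > 0) {
    out <- out + with_seed(params$seed, stats::rnorm(length(out), 0, params$noise_sd))
    out <- pmax(out, 0)   # analyzer reports non-negative pressures
  }
  tr <- capnogram_trace(times = t, pco2 = out, sample_rate = fs)
  attr(tr, "ground_truth") <- ground_truth
  attr(tr, "params") <- params
  attr(tr, "breaths") <- data.frame(index = seq_len(nb) - 1L,
                                    t_exp_start = onset,
                                    t_exp_end = onset + te,
                                    t_cycle_end = onset + T_b)
  tr
}

sigmoid01 <- function(u) {
  # smooth 0->1 ramp on [0,1] (logistic clipped and rescaled to hit 0 and 1)
  s <- stats::plogis(12 * (u - 0.5))
  lo <- stats::plogis(-6); hi <- stats::plogis(6)
  (s - lo) / (hi - lo)
}

# evaluate expr with a temporary RNG state when seed is non-NULL
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a complete rebreathing capnogram
#'
#' Convenience wrapper: [simulate_pet_sequence()] followed by
#' [synthesize_waveform()].
#'
#' @inheritParams simulate_pet_sequence
#' @param ... passed to [synthesize_waveform()].
#' @return a [capnogram_trace] with ground-truth attributes.
#' @export
simulate_capnogram <- function(params, n_breaths = 6, ...) {
  gt <- simulate_pet_sequence(params, n_breaths)
  synthesize_waveform(gt, params, ...)
}

#' Inject measurement artifacts into a capnogram
#'
#' Reproduces the two failure modes seen clinically: irregular breathing and
#' leakage at the mouthpiece.
#'
#' `irregular_breathing` jitters each breath cycle's duration and amplitude
#' by independent multiplicative log-normal factors with log-SD equal to
#' `severity` (so severity 0.5 means roughly +/-50% variation); the trace is
#' time-warped cycle by cycle and resampled onto the original uniform grid.
#'
#' `leak` scales all pressures from the start of breath 1 (the first
#' rebreathed inspiration) onward by `1 - severity`, emulating dead-space
#' CO2 escaping at the mouthpiece; the resulting Pet rise is too small, which
#' biases the volume estimate high and is what the QC flags look for.
#'
#' @param trace a [capnogram_trace]; breath boundaries are taken from the
#'   simulator's `breaths` attribute when present, otherwise detected with
#'   [segment_breaths()].
#' @param mode `"irregular_breathing"` or `"leak"`.
#' @param severity artifact severity in (0, 1].
#' @param seed RNG seed for the jitter factors (irregular mode).
#' @return the corrupted [capnogram_trace].
#' @export
inject_artifacts <- function(trace, mode = c("irregular_breathing", "leak"),
                             severity, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "capnogram_trace"))
  if (!(severity > 0 && severity <= 1)) stop("severity must be in (0, 1]")
  br <- attr(trace, "breaths")
  if (is.null(br)) {
    segs <- segment_breaths(trace)
    br <- data.frame(index = segs$index, t_exp_start = segs$t_exp_start,
                     t_exp_end = segs$t_exp_end,
                     t_cycle_end = c(segs$t_exp_start[-1L],
                                     max(trace$times)))
  }
  t <- trace$times
  p <- trace$pco2

  if (mode == "leak") {
    if (nrow(br) < 2L) stop("leak injection needs at least 2 breaths")
    t1 <- br$t_exp_start[2L]
    p2 <- ifelse(t >= t1, p * (1 - severity), p)
    out <- capnogram_trace(times = t, pco2 = p2, sample_rate = trace$sample_rate)
    attr(out, "breaths") <- br
    return(out)
  }

  # irregular breathing: per-cycle duration + amplitude jitter
  nb <- nrow(br)
  fac <- with_seed(seed, list(dur = exp(stats::rnorm(nb, 0, severity)),
                              amp = exp(stats::rnorm(nb, 0, severity))))
  bounds <- c(br$t_exp_start[1L], br$t_cycle_end)  # cycle edges
  # old-time knots: lead-in edge, cycle edges, trace end
  knots_old <- c(min(t), bounds, max(t))
  dur_old <- diff(knots_old)
  scale <- c(1, fac$dur, 1)                        # lead-in and tail unwarped
  dur_new <- dur_old * scale
  knots_new <- cumsum(c(knots_old[1L], dur_new))
  # amplitude scaling on the original samples, per cycle
  amp <- rep(1, length(p))
  for (i in seq_len(nb)) {
    sel <- t >= bounds[i] & t < bounds[i + 1L]
    amp[sel] <- fac$amp[i]
  }
  p_amp <- p * amp
  # map new uniform grid back to old time axis and interpolate
  t_new <- seq(min(t), max(knots_new), by = 1 / trace$sample_rate)
  t_old <- stats::approx(knots_new, knots_old, xout = t_new, rule = 2)$y
  p_new <- stats::approx(t, p_amp, xout = t_old, rule = 2)$y
  capnogram_trace(times = t_new, pco2 = pmax(p_new, 0),
                  sample_rate = trace$sample_rate)
}
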