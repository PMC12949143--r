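#' Construct a capnogram trace
#'
#' A capnogram trace is a uniformly sampled CO2 partial-pressure time series
#' from a (sidestream) CO2 analyzer. Pressures are stored internally in kPa;
#' values supplied in mmHg are converted on construction (1 mmHg =
#' 0.133322 kPa).
#'
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step. May be omitted, in which case a grid
#'   starting at 0 with step `1/sample_rate` is generated.
#' @param pco2 numeric vector of CO2 partial pressures (same length as
#'   `times`), all values non-negative.
#' @param sample_rate sampling frequency in Hz. If `times` is given the two
#'   must agree to within 1e-9 s per step.
#' @param unit `"kpa"` (default) or `"mmhg"`; mmHg input is converted to kPa.
#' @return An object of class `capnogram_trace`: a list with elements
#'   `times` (s), `pco2` (kPa) and `sample_rate` (Hz).
#' @examples
#' tr <- capnogram_trace(pco2 = abs(sin(seq(0, 30, by = 0.04))) * 5,
#'                       sample_rate = 25)
#' @export
capnogram_trace <- function(times = NULL, pco2, sample_rate, unit = c("kpa", "mmhg")) {
  unit <- match.arg(unit)
  pco2 <- as.numeric(pco2)
  if (unit == "mmhg") pco2 <- pco2 * MMHG_TO_KPA
  if (any(!is.finite(pco2))) stop("pco2 contains non-finite values")
  if (any(pco2 < 0)) stop("pco2 values must be >= 0")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  if (is.null(times)) {
    times <- (seq_along(pco2) - 1L) / sample_rate
  } else {
    times <- as.numeric(times)
    if (length(times) != length(pco2))
      stop("times and pco2 must have equal length")
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (any(abs(dt - 1 / sample_rate) > 1e-9))
      stop("times must be uniform with step 1/sample_rate (tolerance 1e-9 s)")
  }
  structure(list(times = times, pco2 = pco2, sample_rate = sample_rate),
            class = "capnogram_trace")
}

#' @export
print.capnogram_trace <- function(x, ...) {
  cat(sprintf("<capnogram_trace> %d samples @ %.6g Hz, %.1f s, pCO2 %.2f-%.2f kPa\n",
              length(x$pco2), x$sample_rate, diff(range(x$times)),
              min(x$pco2), max(x$pco2)))
  invisible(x)
}

# mmHg -> kPa
MMHG_TO_KPA <- 0.133322

#' Extract the end-tidal value from one expiratory window
#'
#' The end-tidal CO2 (Pet) of a breath is taken as the maximum of the
#' median-of-3 smoothed signal over the final fraction (default 25%) of the
#' expiratory phase. The median filter suppresses single-sample spikes;
#' restricting to the final part of the phase targets the alveolar-plateau
#' end value. If two smoothed samples tie for the maximum, the later one is
#' used (closer to true end-expiration).
#'
#' @param pco2 numeric vector of pressures over the expiratory window
#'   (>= 3 samples).
#' @param window_fraction fraction of the window, anchored at its end, over
#'   which the maximum is taken (default 0.25).
#' @return the end-tidal pressure (same unit as input).
#' @export
extract_end_tidal <- function(pco2, window_fraction = 0.25) {
  n <- length(pco2)
  if (n < 3L) stop("unresolvable end-tidal: expiratory window has fewer than 3 samples")
  sm <- median3(pco2)
  start <- max(1L, n - max(1L, ceiling(window_fraction * n)) + 1L)
  tail_sm <- sm[start:n]
  # which.max returns the first maximum; scan from the end for the last one
  idx_rev <- which.max(rev(tail_sm))
  tail_sm[length(tail_sm) - idx_rev + 1L]
}

# running median of 3 with edge replication (monotone sequences unchanged)
median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  xp <- c(x[1L], x, x[n])
  pmin(pmax(pmin(xp[1:n], xp[2:(n + 1L)]), xp[3:(n + 2L)]),
       pmax(xp[1:n], xp[2:(n + 1L)]))
}

#' Segment a capnogram into breaths
#'
#' Detects expiratory phases with an adaptive mid-range threshold: the mean
#' of a running low and high envelope of the signal (20th and 80th
#' percentiles over a sliding window of `window_breaths` nominal breath
#' periods; quantiles rather than the absolute extremes so that the brief
#' near-zero room-air samples at the start of the record cannot drag the
#' threshold below the inspiratory troughs), with hysteresis of 10% of the
#' running range (enter expiration above threshold + 5% of range, leave
#' below threshold - 5%). An adaptive threshold is required during
#' rebreathing because the inspired CO2 level rises breath by breath, so any
#' fixed threshold eventually sits below the inspiratory trough. Phases
#' shorter than `min_phase_s` are merged into their neighbour.
#'
#' @param trace a [capnogram_trace].
#' @param min_phase_s minimum phase duration in seconds (default 0.25).
#' @param window_breaths width of the running min/max window in nominal
#'   breath periods (default 2).
#' @param window_fraction passed to [extract_end_tidal()].
#' @param hysteresis half-width of the hysteresis band as a fraction of the
#'   running range on each side of the threshold (default 0.05, i.e. a full
#'   band of 10% of the range).
#' @return a `breath_segments` data frame with columns `index` (0 = first
#'   expiration into the dead space), `t_exp_start`, `t_exp_end` (s), `pet`
#'   (kPa) and `valid`.
#' @export
segment_breaths <- function(trace, min_phase_s = 0.25, window_breaths = 2,
                            window_fraction = 0.25, hysteresis = 0.05) {
  stopifnot(inherits(trace, "capnogram_trace"), min_phase_s > 0)
  p <- trace$pco2
  t <- trace$times
  fs <- trace$sample_rate

  # trim a flat pre-measurement baseline (analyzer running before the first
  # expiration): a dominant baseline would corrupt the nominal-period
  # estimate and drag the low envelope - and hence the adaptive threshold -
  # below the inspiratory troughs of the first breaths. The first rise above
  # baseline + 25% of range marks breath 0's upstroke; 1 s before it is kept
  # so the onset itself is never clipped.
  thr_low <- min(p) + 0.25 * (max(p) - min(p))
  first_up <- which(p > thr_low)[1L]
  if (!is.na(first_up) && t[first_up] - t[1L] > 1) {
    start_idx <- max(1L, first_up - as.integer(round(1 * fs)))
    p <- p[start_idx:length(p)]
    t <- t[start_idx:length(t)]
  }
  n <- length(p)
  t_nom <- nominal_breath_period(p, t, fs)
  w <- max(3L, min(n, as.integer(round(window_breaths * t_nom * fs))))
  # the envelope varies on the breath-period scale, so evaluating the
  # running quantiles on a decimated grid (about 10 points per nominal
  # breath) and interpolating is equivalent and much cheaper
  by <- max(1L, as.integer(round(t_nom * fs / 10)))
  at <- unique(c(seq(1L, n, by = by), n))
  qwin <- function(i, prob) {
    lo_i <- max(1L, i - w %/% 2L)
    hi_i <- min(n, i + w %/% 2L)
    stats::quantile(p[lo_i:hi_i], prob, names = FALSE)
  }
  rmin <- stats::approx(at, vapply(at, qwin, 0, prob = 0.2), xout = seq_len(n))$y
  rmax <- stats::approx(at, vapply(at, qwin, 0, prob = 0.8), xout = seq_len(n))$y
  rng <- rmax - rmin
  if (max(rng) < 0.2)
    stop("no respiratory signal: running range below 0.2 kPa")
  thr <- (rmin + rmax) / 2
  hi <- thr + hysteresis * rng
  lo <- thr - hysteresis * rng

  # hysteresis state machine: state TRUE = expiratory (high) phase
  state <- logical(n)
  s <- p[1L] > thr[1L]
  for (i in seq_len(n)) {
    if (!s && p[i] > hi[i]) s <- TRUE
    else if (s && p[i] < lo[i]) s <- FALSE
    state[i] <- s
  }

  ph <- rle(state)
  # merge phases shorter than min_phase_s into their (preceding) neighbour
  min_len <- max(1L, as.integer(round(min_phase_s * fs)))
  repeat {
    if (length(ph$lengths) == 1L) break
    short <- which(ph$lengths < min_len)
    if (length(short) == 0L) break
    j <- short[1L]
    k <- if (j > 1L) j - 1L else j + 1L
    ph$lengths[k] <- ph$lengths[k] + ph$lengths[j]
    ph$lengths <- ph$lengths[-j]
    ph$values <- ph$values[-j]
    # collapse neighbours that now share a state
    ph <- rle(inverse.rle(ph))
  }
  ends <- cumsum(ph$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  exp_idx <- which(ph$values)
  # drop a leading expiratory phase already in progress at sample 1: its
  # onset (and usually its rise) is not observed, so its Pet is unreliable
  if (length(exp_idx) > 0L && exp_idx[1L] == 1L && starts[1L] == 1L && ph$values[1L])
    exp_idx <- exp_idx[-1L]
  # hierarchical refinement: when breathing is very uneven, the running
  # envelope can bridge a short inspiration between two expirations (the
  # threshold sits below the local trough) and report one merged phase;
  # re-thresholding each phase on its own range recovers such boundaries
  bounds <- list()
  for (k in exp_idx)
    bounds <- c(bounds, split_phase(p, starts[k], ends[k], min_len, hysteresis))
  if (length(bounds) < 3L)
    stop("insufficient breaths: fewer than 3 expirations detected")

  segs <- lapply(seq_along(bounds), function(k) {
    i0 <- bounds[[k]][1L]
    i1 <- bounds[[k]][2L]
    win <- p[i0:i1]
    pet <- if (length(win) >= 3L) extract_end_tidal(win, window_fraction) else NA_real_
    data.frame(index = k - 1L, t_exp_start = t[i0], t_exp_end = t[i1],
               pet = pet, valid = is.finite(pet))
  })
  out <- do.call(rbind, segs)
  class(out) <- c("breath_segments", "data.frame")
  out
}

# recursively split an expiratory phase [i0, i1] that contains a deep
# interior valley (a merged breath boundary: an inspiration the running
# envelope bridged). Valley depth at sample i is how far the signal sits
# below both its left and right cumulative maxima; a split is accepted when
# the deepest valley reaches 0.4 kPa - twice the no-respiratory-signal
# floor - an absolute criterion, because breath amplitudes can differ so
# much that a genuine inspiration is small relative to the phase's range
# while plateau slope and analyzer noise stay well below it in absolute
# terms. Returns a list of c(start, end) index pairs.
split_phase <- function(p, i0, i1, min_len, hysteresis) {
  sub0 <- p[i0:i1]
  m <- length(sub0)
  if (m < 2L * min_len) return(list(c(i0, i1)))
  # valleys narrower than the minimum phase are noise, not inspirations:
  # evaluate the split on a min_len moving average
  sub <- if (min_len > 1L) zoo::rollmean(sub0, min_len, fill = "extend") else sub0
  rng <- max(sub) - min(sub)
  left_max <- cummax(sub)
  right_max <- rev(cummax(rev(sub)))
  depth <- pmin(left_max, right_max) - sub
  if (max(depth) < 0.4)
    return(list(c(i0, i1)))
  # threshold halfway up the deepest valley, usual hysteresis
  v <- which.max(depth)
  thr <- sub[v] + 0.5 * max(depth)
  hi <- thr + hysteresis * rng
  lo <- thr - hysteresis * rng
  s <- sub[1L] > thr
  state <- logical(m)
  for (i in seq_len(m)) {
    if (!s && sub[i] > hi) s <- TRUE
    else if (s && sub[i] < lo) s <- FALSE
    state[i] <- s
  }
  ph <- rle(state)
  keep <- ph$values & ph$lengths >= min_len
  if (sum(keep) < 2L) return(list(c(i0, i1)))
  ends <- cumsum(ph$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (j in which(keep))
    out <- c(out, split_phase(p, i0 + starts[j] - 1L, i0 + ends[j] - 1L,
                              min_len, hysteresis))
  out
}

# robust global mid-range level (quantile envelope, see segment_breaths)
mid_range_threshold <- function(p) {
  q <- stats::quantile(p, c(0.2, 0.8), names = FALSE)
  (q[1L] + q[2L]) / 2
}

# crude nominal breath period from mid-range threshold crossings of a
# lightly smoothed signal (0.5 s moving average kills noise chatter around
# the threshold); intervals shorter than 0.5 s are discarded as residual
# chatter, not breaths
nominal_breath_period <- function(p, t, fs) {
  k <- max(1L, as.integer(round(0.5 * fs)))
  ps <- if (k > 1L) zoo::rollmean(p, k, fill = "extend", align = "center") else p
  thr <- mid_range_threshold(ps)
  up <- which(diff(ps > thr) == 1L) + 1L
  iv <- diff(t[up])
  iv <- iv[iv >= 0.5]
  if (length(iv) >= 1L) stats::median(iv) else diff(range(t)) / 4
}

#' @export
print.breath_segments <- function(x, ...) {
  pets <- x$pet[is.finite(x$pet)]
  cat(sprintf("<breath_segments> %d breaths%s\n", nrow(x),
              if (length(pets)) sprintf(", Pet %.2f-%.2f kPa",
                                        min(pets), max(pets)) else ""))
  print.data.frame(x, ...)
  invisible(x)
}
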