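#' Dead-space configuration
#'
#' The external rebreathing dead space (mouthpiece + filter + pipe) whose
#' volume must be known precisely; the reference apparatus used 0.148 L,
#' determined to better than 3 mL.
#'
#' @param volume dead-space volume DV, litres.
#' @param volume_tolerance volume determination accuracy, litres (default
#'   0.003).
#' @return an object of class `dead_space_config`.
#' @export
dead_space_config <- function(volume = 0.148, volume_tolerance = 0.003) {
  if (!(volume > 0)) stop("dead-space volume must be > 0")
  if (volume_tolerance < 0) stop("volume_tolerance must be >= 0")
  structure(list(volume = volume, volume_tolerance = volume_tolerance),
            class = "dead_space_config")
}

#' End-tidal differences of the first two rebreathed breaths
#'
#' Breath 0 is the expiration that fills the dead space; its end-tidal value
#' avPet represents the CO2 level of the dead-space gas. The rises are
#' referenced to it, with the second-breath rise taken cumulatively:
#' dPet1 = Pet(1) - Pet(0) and dPet2 = Pet(2) - Pet(0). Only the cumulative
#' convention makes the weighted mean dPet = 0.5 (dPet1 + w dPet2)
#' consistent with the volume formula ELV = 2 avPet DV / (dPet1 + w dPet2).
#'
#' @param segments a `breath_segments` data frame (or a plain numeric Pet
#'   vector ordered by breath index).
#' @param strict if TRUE (default), a non-positive rise raises a
#'   "non-rising Pet" error (leak or mis-segmentation); if FALSE the deltas
#'   are returned for QC to flag.
#' @return list with `av_pet`, `delta_pet1`, `delta_pet2` (kPa).
#' @export
compute_deltas <- function(segments, strict = TRUE) {
  pet <- if (is.data.frame(segments)) segments$pet[segments$valid] else as.numeric(segments)
  if (length(pet) < 3L) stop("insufficient breaths: need breaths 0, 1 and 2")
  d <- list(av_pet = pet[1L],
            delta_pet1 = pet[2L] - pet[1L],
            delta_pet2 = pet[3L] - pet[1L])
  if (strict && (d$delta_pet1 <= 0 || d$delta_pet2 <= 0))
    stop("non-rising Pet: end-tidal values do not increase (leak or mis-segmentation?)")
  d
}

#' Relative weight of the second breath
#'
#' The second breath no longer lies on the linear part of the wash-in curve,
#' so its cumulative rise is down-weighted. Under single-exponential
#' kinetics with rate constant k and breath period T, the cumulative rises
#' satisfy dPet2 = dPet1 (1 + e^(-kT)), so the weight
#' w = 1 / (1 + e^(-kT)) makes 0.5 (dPet1 + w dPet2) = dPet1 exactly: the
#' estimator is unbiased whatever k. At typical kinetics (k = 0.06 s^-1,
#' T = 5 s) w = 0.574, which is where the shipped default of 0.57 comes
#' from; the fixed default is used whenever k or T are not estimated.
#'
#' @param k_rate wash-in rate constant, s^-1 (>= 0).
#' @param breath_period breath period T = 60/RR, s (> 0).
#' @return the dimensionless weight in \[0.5, 1).
#' @export
second_breath_weight <- function(k_rate, breath_period) {
  stopifnot(k_rate >= 0, breath_period > 0)
  1 / (1 + exp(-k_rate * breath_period))
}

#' Effective lung volume from the two-breath estimator
#'
#' ELV = 2 avPet DV / (dPet1 + w dPet2). The result is invariant to the
#' pressure unit since only pressure ratios enter.
#'
#' @param av_pet end-expiratory dead-space CO2 (breath 0), kPa (or any unit,
#'   consistently with the deltas).
#' @param dv a [dead_space_config] or a plain volume in litres.
#' @param delta_pet1,delta_pet2 rises of breaths 1 and 2 over breath 0
#'   (cumulative), same unit as `av_pet`.
#' @param weight second-breath weight (default 0.57).
#' @return effective lung volume, litres.
#' @export
estimate_elv <- function(av_pet, dv, delta_pet1, delta_pet2, weight = 0.57) {
  vol <- if (inherits(dv, "dead_space_config")) dv$volume else as.numeric(dv)
  stopifnot(av_pet > 0, vol > 0)
  den <- delta_pet1 + weight * delta_pet2
  if (!(den > 0)) stop("non-rising Pet: weighted rise is not positive")
  2 * av_pet * vol / den
}

#' FRC from ELV
#'
#' ELV is the volume in which CO2 equilibrates during rebreathing: the gas
#' volume (FRC) plus lung tissue and pulmonary capillary blood. In health
#' FRC = 0.82 ELV; disease-specific constants (e.g. about 0.88 in non-ARDS
#' and 0.77 in severe ARDS mechanically ventilated patients) can be supplied
#' instead.
#'
#' @param elv effective lung volume, litres (> 0).
#' @param k_constant proportionality constant in (0, 1], default 0.82.
#' @return functional residual capacity, litres.
#' @export
convert_elv_to_frc <- function(elv, k_constant = 0.82) {
  stopifnot(all(elv > 0), k_constant > 0, k_constant <= 1)
  k_constant * elv
}

#' Fit wash-in kinetics to a breath-wise Pet sequence
#'
#' Least-squares fit of Pet(t) = pet0 + dp_inf (1 - e^(-k t)) over all
#' available breaths, with t measured from the breath-0 expiration. Used to
#' refine the second-breath weight when a long record exists. Starting
#' values come from the closed-form increment ratio
#' a = (Pet(2)-Pet(1)) / (Pet(1)-Pet(0)).
#'
#' @param pet breath-wise end-tidal values, kPa (>= 4 breaths).
#' @param times end-expiration times of those breaths, s (span >= 15 s).
#' @return list with `k_rate` (s^-1), `delta_p_inf` (kPa), `pet0` (kPa).
#' @export
fit_rebreathing_kinetics <- function(pet, times) {
  if (length(pet) != length(times)) stop("pet and times must have equal length")
  if (length(pet) < 4L) stop("kinetics fit needs at least 4 breaths")
  tt <- times - times[1L]
  if (max(tt) < 15) stop("kinetics fit needs breaths spanning at least 15 s")
  inc <- diff(pet)
  a0 <- if (length(inc) >= 2L && inc[1L] > 0) max(min(inc[2L] / inc[1L], 0.99), 0.01) else 0.7
  T0 <- mean(diff(tt))
  k0 <- -log(a0) / T0
  dp0 <- if (inc[1L] > 0) inc[1L] / (1 - a0) else max(pet) - pet[1L]
  fit <- tryCatch(
    minpack.lm::nlsLM(pet ~ p0 + dp * (1 - exp(-k * tt)),
                      start = list(p0 = pet[1L], dp = dp0, k = k0),
                      lower = c(0, 1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("kinetics fit failed")
  cf <- stats::coef(fit)
  list(k_rate = unname(cf["k"]), delta_p_inf = unname(cf["dp"]),
       pet0 = unname(cf["p0"]))
}

#' Quality-control flags for a rebreathing measurement
#'
#' Never throws; returns a character vector of flags (possibly empty):
#' \describe{
#'   \item{dv_tv_low / dv_tv_high}{DV/TV outside the 0.10-0.25 operating
#'     envelope (only when a tidal-volume estimate is supplied). Too small a
#'     ratio gives a rise comparable to measurement noise; too large
#'     distorts breathing.}
#'   \item{irregular}{coefficient of variation of the breath periods around
#'     the three relevant breaths exceeds `regularity_cv_limit`
#'     (default 0.25).}
#'   \item{leak_suspected}{dPet1 <= 0 or Pet(2) < Pet(1): the rise pattern
#'     expected from dead-space CO2 accumulation is broken.}
#'   \item{insufficient_breaths}{fewer than 3 usable breaths.}
#' }
#'
#' @param segments a `breath_segments` data frame (may be NULL).
#' @param dv a [dead_space_config] or volume in litres.
#' @param tv_estimate tidal volume in litres, or NULL if unknown.
#' @param regularity_cv_limit CV limit for breath-period regularity.
#' @return character vector of flags.
#' @export
qc_measurement <- function(segments, dv, tv_estimate = NULL,
                           regularity_cv_limit = 0.25) {
  flags <- character(0)
  vol <- if (inherits(dv, "dead_space_config")) dv$volume else as.numeric(dv)
  if (!is.null(tv_estimate) && is.finite(tv_estimate) && tv_estimate > 0) {
    r <- vol / tv_estimate
    if (r < 0.10) flags <- c(flags, "dv_tv_low")
    if (r > 0.25) flags <- c(flags, "dv_tv_high")
  }
  if (is.null(segments) || !is.data.frame(segments) || sum(segments$valid) < 3L)
    return(unique(c(flags, "insufficient_breaths")))
  seg <- segments[segments$valid, , drop = FALSE]
  # breath periods spanning the relevant breaths 0..2 (expiration onsets)
  n_per <- min(nrow(seg), 4L)
  per <- diff(seg$t_exp_start[seq_len(n_per)])
  if (length(per) >= 2L) {
    cv <- stats::sd(per) / mean(per)
    if (is.finite(cv) && cv > regularity_cv_limit) flags <- c(flags, "irregular")
  }
  pet <- seg$pet
  if ((pet[2L] - pet[1L]) <= 0 || pet[3L] < pet[2L])
    flags <- c(flags, "leak_suspected")
  unique(flags)
}

#' Estimate ELV and FRC from a rebreathing capnogram
#'
#' The full measurement pipeline: segment the trace into breaths, take the
#' end-tidal values of breaths 0-2, form the weighted two-breath rise and
#' apply ELV = 2 avPet DV / (dPet1 + w dPet2) and FRC = K ELV, with QC
#' gating. QC problems never abort the call: the estimate is returned with
#' `qc_flags` set (and NA volumes when no estimate is computable).
#'
#' @param x a [capnogram_trace] or a `breath_segments` data frame.
#' @param dead_space a [dead_space_config] or DV in litres (default 0.148).
#' @param weight `"default"` (fixed 0.57), `"auto"` (refine from fitted
#'   wash-in kinetics when the record allows, else fall back to 0.57), or a
#'   numeric weight.
#' @param k_constant FRC/ELV constant (default 0.82).
#' @param tv tidal volume in litres for DV/TV QC, or NULL.
#' @param regularity_cv_limit breath-period CV limit for the QC.
#' @param ... passed to [segment_breaths()] when `x` is a trace.
#' @return an object of class `rebreathing_estimate`: list with `av_pet`,
#'   `delta_pet1`, `delta_pet2`, `weight_w`, `delta_pet`, `elv`,
#'   `k_constant`, `frc`, `qc_flags`, `tv_estimate`, `n_breaths`,
#'   `dead_space`.
#' @export
estimate_rebreathing <- function(x, dead_space = dead_space_config(),
                                 weight = "default", k_constant = 0.82,
                                 tv = NULL, regularity_cv_limit = 0.25, ...) {
  dv <- if (inherits(dead_space, "dead_space_config")) dead_space
        else dead_space_config(volume = as.numeric(dead_space))
  segs <- NULL
  if (inherits(x, "capnogram_trace")) {
    segs <- tryCatch(segment_breaths(x, ...), error = function(e) NULL)
  } else if (is.data.frame(x)) {
    segs <- x
  } else stop("x must be a capnogram_trace or breath_segments")

  flags <- qc_measurement(segs, dv, tv_estimate = tv,
                          regularity_cv_limit = regularity_cv_limit)
  est <- list(av_pet = NA_real_, delta_pet1 = NA_real_, delta_pet2 = NA_real_,
              weight_w = NA_real_, delta_pet = NA_real_, elv = NA_real_,
              k_constant = k_constant, frc = NA_real_,
              qc_flags = flags, tv_estimate = tv,
              n_breaths = if (is.null(segs)) 0L else sum(segs$valid),
              dead_space = dv)
  class(est) <- "rebreathing_estimate"
  if ("insufficient_breaths" %in% flags) return(est)

  d <- compute_deltas(segs, strict = FALSE)
  est$av_pet <- d$av_pet
  est$delta_pet1 <- d$delta_pet1
  est$delta_pet2 <- d$delta_pet2

  w <- resolve_weight(weight, segs)
  est$weight_w <- w
  den <- d$delta_pet1 + w * d$delta_pet2
  if (!(den > 0)) {
    est$qc_flags <- unique(c(est$qc_flags, "leak_suspected"))
    return(est)
  }
  est$delta_pet <- 0.5 * den
  est$elv <- estimate_elv(d$av_pet, dv, d$delta_pet1, d$delta_pet2, weight = w)
  est$frc <- convert_elv_to_frc(est$elv, k_constant)
  est
}

# "auto" weight: estimate the per-breath decay ratio rho = exp(-k T) of the
# wash-in directly in breath-index space (Pet(n) = p0 + dp (1 - rho^n)) and
# use w = 1/(1 + rho). Fitting against the breath index rather than the
# detected breath times keeps the weight free of the sample-grid
# quantisation of threshold-crossing times; irregular timing is caught by
# the QC instead. Falls back to the fixed default 0.57 whenever the record
# does not support the fit.
resolve_weight <- function(weight, segs) {
  if (is.numeric(weight)) return(weight)
  weight <- match.arg(weight, c("default", "auto"))
  if (weight == "default") return(0.57)
  pet <- segs$pet[segs$valid]
  if (length(pet) < 3L) return(0.57)
  inc <- diff(pet)
  if (inc[1L] <= 0 || inc[2L] <= 0) return(0.57)
  rho0 <- max(min(inc[2L] / inc[1L], 0.995), 0.005)
  rho <- rho0
  if (length(pet) >= 4L) {
    nidx <- seq_along(pet) - 1
    fit <- tryCatch(
      minpack.lm::nlsLM(pet ~ p0 + dp * (1 - rho^nidx),
                        start = list(p0 = pet[1L], dp = inc[1L] / (1 - rho0),
                                     rho = rho0),
                        lower = c(0, 1e-6, 1e-3), upper = c(Inf, Inf, 0.999),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) rho <- stats::coef(fit)[["rho"]]
  }
  1 / (1 + rho)
}

#' @export
print.rebreathing_estimate <- function(x, ...) {
  cat("<rebreathing_estimate>\n")
  cat(sprintf("  avPet   %.3f kPa   dPet1 %.3f   dPet2 %.3f   w %.3f\n",
              x$av_pet, x$delta_pet1, x$delta_pet2, x$weight_w))
  cat(sprintf("  ELV     %.3f L     FRC %.3f L (K = %.2f)\n",
              x$elv, x$frc, x$k_constant))
  cat(sprintf("  QC      %s\n",
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ") else "clean"))
  invisible(x)
}
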