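#' Build a method-comparison pair table
#'
#' One row per observation: a method value (e.g. FRC from rebreathing) and
#' the reference value for the same subject, with a replicate ordinal for
#' repeated measurements.
#'
#' @param subject_id subject labels.
#' @param method_value method measurements, litres (> 0).
#' @param reference_value reference measurements, litres (> 0).
#' @param replicate replicate ordinal (default 1).
#' @return a `measurement_pairs` data frame.
#' @export
measurement_pairs <- function(subject_id, method_value, reference_value,
                              replicate = 1L) {
  if (any(method_value <= 0) || any(reference_value <= 0))
    stop("method and reference values must be > 0")
  out <- data.frame(subject_id = as.character(subject_id),
                    replicate = as.integer(replicate),
                    method_value = as.numeric(method_value),
                    reference_value = as.numeric(reference_value))
  class(out) <- c("measurement_pairs", "data.frame")
  out
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference (bias), the SD of the differences (n-1
#' denominator), the 95% limits of agreement bias +/- 1.96 SD, and the
#' percentage error PE = 1.96 SD / mean reference value. PE < 0.30 is the
#' exchangeability criterion: a method with PE below that of commonly
#' accepted reference techniques can replace them.
#'
#' @param pairs a `measurement_pairs` data frame (or any data frame with
#'   `method_value` and `reference_value` columns).
#' @param pe_denominator `"reference"` (default: mean of the reference
#'   values) or `"all"` (mean of method and reference values pooled).
#' @param pe_limit exchangeability threshold (default 0.30).
#' @return an object of class `agreement_stats`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `percentage_error`, `exchangeable`.
#' @export
bland_altman <- function(pairs, pe_denominator = c("reference", "all"),
                         pe_limit = 0.30) {
  pe_denominator <- match.arg(pe_denominator)
  m <- pairs$method_value
  r <- pairs$reference_value
  n <- length(m)
  if (n < 2L) stop("insufficient pairs: Bland-Altman needs n >= 2")
  d <- m - r
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  denom <- if (pe_denominator == "reference") mean(r) else mean(c(m, r))
  pe <- 1.96 * sd_diff / denom
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 percentage_error = pe,
                 exchangeable = pe < pe_limit),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d\n", x$n))
  cat(sprintf("  bias %.3f L, SD %.3f L, LoA [%.3f, %.3f] L\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  percentage error %.3f -> %sexchangeable (PE < 0.30)\n",
              x$percentage_error, if (x$exchangeable) "" else "NOT "))
  invisible(x)
}

#' Average replicate method measurements per subject
#'
#' Replaces each subject's replicates by their arithmetic mean method value;
#' the (single) reference value per subject is unchanged. Subjects with one
#' replicate pass through.
#'
#' @param pairs a `measurement_pairs` data frame.
#' @return a `measurement_pairs` data frame with one row per subject.
#' @export
average_replicates <- function(pairs) {
  sp <- split(seq_len(nrow(pairs)), pairs$subject_id)
  rows <- lapply(sp, function(i) {
    data.frame(subject_id = pairs$subject_id[i[1L]],
               replicate = 1L,
               method_value = mean(pairs$method_value[i]),
               reference_value = pairs$reference_value[i[1L]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$subject_id, unique(pairs$subject_id))), ]
  rownames(out) <- NULL
  class(out) <- c("measurement_pairs", "data.frame")
  out
}

#' Paired t-test
#'
#' Student's paired t-test, two-tailed: t = mean(x - y) / (sd(x - y)/sqrt(n))
#' on n - 1 degrees of freedom. Degenerate cases follow the conventions:
#' all differences zero gives t = 0, p = 1; zero variance with a nonzero
#' mean difference gives p = 0.
#'
#' @param x,y paired samples of equal length (n >= 2).
#' @return list with `t`, `p` (two-tailed), `df`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Unpaired (two-sample) t-test
#'
#' Welch's form by default (unequal variances); set `pooled = TRUE` for the
#' classical equal-variance test. Two-tailed. Degenerate zero-variance
#' inputs follow the same conventions as [paired_t_test()].
#'
#' @param x,y samples (each n >= 2).
#' @param pooled use the pooled-variance (Student) form.
#' @return list with `t`, `p` (two-tailed), `df`.
#' @export
unpaired_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 in each group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    df <- length(x) + length(y) - 2L
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Bland-Altman plot
#'
#' Mean of the two methods against their difference, with the bias and the
#' 95% limits of agreement drawn as horizontal lines.
#'
#' @param pairs a `measurement_pairs` data frame.
#' @param stats optional precomputed [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @return the `agreement_stats` used, invisibly.
#' @export
plot_bland_altman <- function(pairs, stats = NULL, ...) {
  if (is.null(stats)) stats <- bland_altman(pairs)
  avg <- (pairs$method_value + pairs$reference_value) / 2
  d <- pairs$method_value - pairs$reference_value
  graphics::plot(avg, d, xlab = "Mean of methods (L)",
                 ylab = "Difference, method - reference (L)",
                 pch = 19, ...)
  graphics::abline(h = stats$bias, lty = 1)
  graphics::abline(h = c(stats$loa_low, stats$loa_high), lty = 2)
  invisible(stats)
}
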