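#' Read a capnogram from delimited text
#'
#' Expects a CSV with header `time_s,pco2_kpa` (or `time_s,pco2_mmhg`, in
#' which case values are converted to kPa by x 0.133322). Lines starting
#' with `#` are comments. Malformed rows are reported with their line
#' numbers.
#'
#' @param path file path.
#' @return a [capnogram_trace] in kPa.
#' @export
read_capnogram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, comment.char = "#",
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty capnogram file: ", path)
  if (!"time_s" %in% names(df))
    stop("missing column time_s in ", path)
  pcol <- intersect(c("pco2_kpa", "pco2_mmhg"), names(df))
  if (length(pcol) == 0L)
    stop("missing column pco2_kpa or pco2_mmhg in ", path)
  if (length(pcol) == 2L)
    stop("mixed units: both pco2_kpa and pco2_mmhg present in ", path)
  tvals <- suppressWarnings(as.numeric(df$time_s))
  pvals <- suppressWarnings(as.numeric(df[[pcol]]))
  bad <- which(!is.finite(tvals) | !is.finite(pvals))
  if (length(bad) > 0L)
    stop("malformed rows (data line ", paste(bad, collapse = ", "),
         ") in ", path)
  if (any(diff(tvals) <= 0)) stop("non-monotone time column in ", path)
  fs <- 1 / stats::median(diff(tvals))
  capnogram_trace(times = tvals, pco2 = pvals, sample_rate = fs,
                  unit = if (pcol == "pco2_mmhg") "mmhg" else "kpa")
}

#' Write a capnogram to CSV
#'
#' @param trace a [capnogram_trace].
#' @param path output file path.
#' @param unit `"kpa"` (default) or `"mmhg"`.
#' @return `path`, invisibly.
#' @export
write_capnogram_csv <- function(trace, path, unit = c("kpa", "mmhg")) {
  unit <- match.arg(unit)
  p <- trace$pco2
  if (unit == "mmhg") p <- p / MMHG_TO_KPA
  df <- data.frame(time_s = trace$times, p = p)
  names(df)[2L] <- paste0("pco2_", unit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected breath segments to CSV
#'
#' Columns: `index,t_exp_start,t_exp_end,pet,valid`.
#'
#' @param segments a `breath_segments` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  utils::write.csv(as.data.frame(segments)[, c("index", "t_exp_start",
                                               "t_exp_end", "pet", "valid")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a method-comparison pair table from CSV
#'
#' Expects columns `subject_id,replicate,method_l,reference_l`.
#'
#' @param path file path.
#' @return a `measurement_pairs` data frame.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "replicate", "method_l", "reference_l")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  measurement_pairs(df$subject_id, df$method_l, df$reference_l, df$replicate)
}

#' Write a simulator trace with its ground-truth sidecar
#'
#' Writes the trace CSV and a JSON sidecar (`<path>.json`) containing the
#' simulator parameters and the breath-wise ground truth. The ground truth
#' exists for testing only; a real measurement has no such sidecar.
#'
#' @param trace a simulated [capnogram_trace] (with `ground_truth` and
#'   `params` attributes).
#' @param path trace CSV path.
#' @return `path`, invisibly.
#' @export
write_simulated_trace <- function(trace, path) {
  write_capnogram_csv(trace, path)
  gt <- attr(trace, "ground_truth")
  pr <- attr(trace, "params")
  side <- list(schema = "rebreathe/simulated-trace/v1",
               note = "ground truth for testing only",
               params = unclass(pr),
               ground_truth = unclass(gt))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialise a rebreathing estimate to JSON
#'
#' @param estimate a `rebreathing_estimate`.
#' @param path output path, or NULL to return the JSON string.
#' @param input name of the input file, recorded as provenance.
#' @return the JSON string, invisibly if written to a file.
#' @export
write_estimate_json <- function(estimate, path = NULL, input = NULL) {
  x <- unclass(estimate)
  x$dead_space <- unclass(x$dead_space)
  x$qc_flags <- as.list(x$qc_flags)
  out <- list(schema = "rebreathe/estimate/v1",
              software = paste0("rebreathe ",
                                as.character(utils::packageVersion("rebreathe"))),
              input = input, estimate = x)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
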