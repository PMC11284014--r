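#' Clinical receptivity report from a single biopsy
#'
#' Turns a predicted hour offset (plus its standard error) for one biopsy
#' into the clinical report: the predicted optimal WOI elapsed time, the
#' displacement relative to the reference timing, and the phase call.
#' A positive displacement means the WOI falls later than the reference
#' (delayed); a negative one earlier (advanced).
#'
#' @param pred Either a one-row data frame from [predict.woi_forest()] or a
#'   numeric offset in hours.
#' @param sampling_time Biopsy time, hours after first progesterone
#'   administration.
#' @param reference_woi Reference WOI center (default 120 h = P+5, the
#'   standard blastocyst transfer timing).
#' @param halfwidth Receptive half-width in hours, shared with
#'   [phase_from_label()] (default 12).
#' @param se_hours Standard error of the offset; taken from `pred` when it
#'   is a prediction data frame.
#' @return An object of class `receptivity_result`: list with `phase`,
#'   `displacement_hours`, `optimal_woi_hours`, `se_hours`,
#'   `sampling_time`.
#' @examples
#' # biopsy at P+5, predicted offset +19 h: WOI delayed, optimum 5 d 19 h
#' report_receptivity(19, sampling_time = 120)
#' @export
report_receptivity <- function(pred, sampling_time, reference_woi = 120,
                               halfwidth = 12, se_hours = NA_real_) {
  if (is.data.frame(pred)) {
    stopifnot(nrow(pred) == 1L)
    if (!is.null(pred$se_hours)) se_hours <- pred$se_hours
    pred <- pred$offset_hours
  }
  stopifnot(is.numeric(pred), length(pred) == 1L, is.finite(pred))
  if (sampling_time < 0) stop("sampling_time must be >= 0", call. = FALSE)
  optimal <- sampling_time + pred
  displacement <- optimal - reference_woi
  structure(
    list(phase = phase_from_label(displacement, halfwidth),
         displacement_hours = displacement,
         optimal_woi_hours = optimal,
         se_hours = se_hours,
         sampling_time = sampling_time,
         reference_woi = reference_woi,
         halfwidth = halfwidth),
    class = "receptivity_result")
}

#' Format an elapsed time as whole days and hours
#' @param hours Nonnegative elapsed hours.
#' @return Character like `"5 d 19 h"`.
#' @export
format_days_hours <- function(hours) {
  d <- floor(hours / 24)
  h <- hours - 24 * d
  sprintf("%d d %g h", d, round(h, 2))
}

#' @export
print.receptivity_result <- function(x, ...) {
  cat("Endometrial receptivity report\n")
  cat("  biopsy at", format_days_hours(x$sampling_time),
      "after first progesterone administration\n")
  cat("  phase:", as.character(x$phase))
  if (x$displacement_hours > x$halfwidth) cat(" (WOI delayed)")
  if (x$displacement_hours < -x$halfwidth) cat(" (WOI advanced)")
  cat("\n")
  cat("  predicted optimal WOI:", format_days_hours(x$optimal_woi_hours),
      sprintf("(displacement %+g h", x$displacement_hours))
  if (is.finite(x$se_hours)) cat(sprintf(", SE %.1f h", x$se_hours))
  cat(")\n")
  invisible(x)
}

#' @export
as.data.frame.receptivity_result <- function(x, ...) {
  data.frame(phase = as.character(x$phase),
             displacement_hours = x$displacement_hours,
             optimal_woi_hours = x$optimal_woi_hours,
             se_hours = x$se_hours,
             sampling_time = x$sampling_time,
             stringsAsFactors = FALSE)
}

#' Write a receptivity report as JSON
#' @param x A `receptivity_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptivity_json <- function(x, path) {
  stopifnot(inherits(x, "receptivity_result"))
  doc <- as.data.frame(x)
  doc <- as.list(doc)
  doc$optimal_woi_formatted <- format_days_hours(x$optimal_woi_hours)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cohort-level receptivity summary
#'
#' @param results A list of `receptivity_result` objects, or a numeric
#'   vector of displacements.
#' @param halfwidth Receptive half-width (used when `results` is numeric).
#' @return Named numeric vector of fractions (`receptive`, `delayed`,
#'   `advanced`); the fractions sum to 1.
#' @export
cohort_receptivity_summary <- function(results, halfwidth = 12) {
  if (is.list(results) && length(results) &&
      inherits(results[[1]], "receptivity_result")) {
    disp <- vapply(results, `[[`, numeric(1), "displacement_hours")
    halfwidth <- results[[1]]$halfwidth
  } else {
    disp <- as.numeric(results)
  }
  if (length(disp) == 0L) stop("no results to summarize", call. = FALSE)
  c(receptive = mean(abs(disp) <= halfwidth),
    delayed = mean(disp > halfwidth),
    advanced = mean(disp < -halfwidth))
}
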