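#' Personalized embryo-transfer schedule
#'
#' Converts a predicted optimal WOI elapsed time (hours between the first
#' progesterone injection and the moment of peak receptivity) into a
#' clinic schedule. The transfer clock hour is held fixed — clinics
#' transfer at a set hour of the day — and the first progesterone
#' injection floats to whatever clock time makes the transfer land exactly
#' on the predicted optimum: `injection_clock = (transfer_clock -
#' optimal_elapsed) mod 24`.
#'
#' @param optimal_elapsed Predicted optimal WOI elapsed time in hours
#'   (> 0), e.g. 139 for "5 d 19 h". Strings like `"5d19h"` are accepted
#'   (see [parse_elapsed()]).
#' @param transfer_clock Clinic transfer hour-of-day in `[0, 24)`,
#'   default 15 (15:00).
#' @return An object of class `transfer_plan`: list with
#'   `injection_clock`, `transfer_day_index` (whole days after the
#'   injection day, injection day = day 0), `transfer_clock`, and
#'   `elapsed_hours` (which always reconstructs the input exactly).
#' @examples
#' plan_transfer("5d19h")   # injection at 20:00, transfer day 6 at 15:00
#' @export
plan_transfer <- function(optimal_elapsed, transfer_clock = 15) {
  if (is.character(optimal_elapsed)) {
    optimal_elapsed <- parse_elapsed(optimal_elapsed)
  }
  stopifnot(length(optimal_elapsed) == 1L, length(transfer_clock) == 1L)
  if (!is.finite(optimal_elapsed) || !is.finite(transfer_clock)) {
    stop("optimal_elapsed and transfer_clock must be finite", call. = FALSE)
  }
  if (optimal_elapsed <= 0) {
    stop("optimal_elapsed must be positive", call. = FALSE)
  }
  if (transfer_clock < 0 || transfer_clock >= 24) {
    stop("transfer_clock must lie in [0, 24)", call. = FALSE)
  }
  injection_clock <- (transfer_clock - optimal_elapsed) %% 24
  day_index <- (injection_clock + optimal_elapsed - transfer_clock) / 24
  stopifnot(abs(day_index - round(day_index)) < 1e-9)
  structure(list(injection_clock = injection_clock,
                 transfer_day_index = as.integer(round(day_index)),
                 transfer_clock = transfer_clock,
                 elapsed_hours = optimal_elapsed),
            class = "transfer_plan")
}

#' Parse an elapsed-time string
#'
#' Accepts `"XdYh"` (e.g. `"5d19h"`), `"Xd"`, `"Yh"`, or a plain decimal
#' hour string.
#'
#' @param x Character scalar.
#' @return Elapsed hours as a number.
#' @export
parse_elapsed <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- tolower(gsub("[[:space:]]", "", x))
  if (grepl("^[0-9.]+$", x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^(?:([0-9.]+)d)?(?:([0-9.]+)h)?$", x))[[1]]
  if (length(m) == 0L || (m[2] == "" && m[3] == "")) {
    stop("cannot parse elapsed time '", x,
         "'; use e.g. \"5d19h\" or decimal hours", call. = FALSE)
  }
  d <- if (m[2] == "") 0 else as.numeric(m[2])
  h <- if (m[3] == "") 0 else as.numeric(m[3])
  24 * d + h
}

format_clock <- function(h) {
  sprintf("%02d:%02d", floor(h) %% 24, round((h - floor(h)) * 60))
}

#' @export
print.transfer_plan <- function(x, ...) {
  cat("Personalized embryo-transfer plan\n")
  cat("  optimal WOI elapsed time:", format_days_hours(x$elapsed_hours), "\n")
  cat("  first progesterone injection:", format_clock(x$injection_clock),
      "on day 0\n")
  cat("  embryo transfer:", format_clock(x$transfer_clock), "on day",
      x$transfer_day_index, "\n")
  invisible(x)
}

#' Injection-time shift relative to the standard schedule
#'
#' How many hours the first progesterone injection moves relative to the
#' clinic's standard injection hour, wrapped to `(-12, +12]`.
#'
#' @param plan A [plan_transfer()] result.
#' @param standard_injection_clock Standard injection hour-of-day,
#'   default 15 (15:00).
#' @return Signed hours in `(-12, 12]`.
#' @export
shift_versus_standard <- function(plan, standard_injection_clock = 15) {
  stopifnot(inherits(plan, "transfer_plan"))
  d <- (plan$injection_clock - standard_injection_clock) %% 24
  if (d > 12) d - 24 else d
}

#' Write a transfer plan as JSON
#' @param plan A `transfer_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "transfer_plan"))
  doc <- unclass(plan)
  doc$injection_clock_formatted <- format_clock(plan$injection_clock)
  doc$transfer_clock_formatted <- format_clock(plan$transfer_clock)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
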