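#' The hourly training-label grid
#'
#' Training labels for the hour-offset regressor live on a fixed signed grid
#' spanning four days either side of the window of implantation.
#'
#' @return Integer vector `c(0, 24, -24, 48, -48, 72, -72, 96, -96)`.
#' @export
hour_label_grid <- function() {
  c(0L, 24L, -24L, 48L, -48L, 72L, -72L, 96L, -96L)
}

#' Hour-offset training label from a successful transfer
#'
#' For a biopsy taken in a cycle whose embryo transfer led to an
#' intrauterine pregnancy, the signed difference
#' `successful_transfer_time - sampling_time` is the sample's offset from
#' the window of implantation: positive means the biopsy preceded the WOI
#' (pre-receptive tissue), negative means it followed it. The raw
#' difference is snapped to the nearest point of [hour_label_grid()], with
#' exact midpoints resolved toward the smaller-magnitude label.
#'
#' @param sampling_time Biopsy time(s), hours after first progesterone
#'   administration.
#' @param successful_transfer_time Transfer time(s) of the pregnancy-
#'   confirmed cycle, same clock. Recycled against `sampling_time`.
#' @return Integer label(s) on the grid.
#' @examples
#' # three-point biopsies at P+3, P+5, P+7 with a successful P+4 transfer
#' label_from_outcome(c(72, 120, 168), 96)   # +24, -24, -72
#' @export
label_from_outcome <- function(sampling_time, successful_transfer_time) {
  if (any(!is.finite(sampling_time)) || any(!is.finite(successful_transfer_time))) {
    stop("times must be finite", call. = FALSE)
  }
  if (any(sampling_time < 0) || any(successful_transfer_time < 0)) {
    stop("times must be nonnegative", call. = FALSE)
  }
  raw <- successful_transfer_time - sampling_time
  if (any(abs(raw) > 108)) {
    stop("offset of ", paste(raw[abs(raw) > 108], collapse = ", "),
         " h is beyond the +/-96 h label grid (snapping range +/-108 h)",
         call. = FALSE)
  }
  grid <- hour_label_grid()
  vapply(raw, function(d) {
    dist <- abs(grid - d)
    cand <- grid[dist == min(dist)]
    cand[which.min(abs(cand))]  # midpoint ties resolve toward 0
  }, integer(1))
}

#' Receptivity phase from an hour offset
#'
#' A sample (or patient) is called receptive when its offset from the WOI
#' center is within `halfwidth` hours; larger positive offsets are
#' pre-receptive (the WOI lies ahead, i.e. is delayed relative to the
#' sample), larger negative offsets post-receptive.
#'
#' @param value Signed hour offset(s); grid labels or continuous hours.
#' @param halfwidth Receptive half-width in hours (> 0). Default 12, half
#'   the 24 h label-grid step.
#' @return Factor with levels `pre-receptive`, `receptive`,
#'   `post-receptive`.
#' @export
phase_from_label <- function(value, halfwidth = 12) {
  stopifnot(is.numeric(value), length(halfwidth) == 1L, halfwidth > 0)
  phase <- ifelse(abs(value) <= halfwidth, "receptive",
                  ifelse(value > halfwidth, "pre-receptive", "post-receptive"))
  factor(phase, levels = c("pre-receptive", "receptive", "post-receptive"))
}

#' Enumerate grid-label triplets consistent with a phase triplet
#'
#' Three-point biopsies at P+3/P+5/P+7 are 48 h apart, so their labels must
#' decrease by exactly 48 across the triplet. Given the qualitative phase
#' call of each biopsy, this returns every label triplet `(l1, l2, l3)` on
#' [hour_label_grid()] with `l1 - l2 == 48`, `l2 - l3 == 48`, and each
#' label's phase (via [phase_from_label()]) matching the input.
#'
#' @param phases Character or factor of length 3, ordered by sampling time;
#'   values among `pre-receptive`, `receptive`, `post-receptive`.
#' @param halfwidth Receptive half-width passed to [phase_from_label()].
#' @return Integer matrix with 3 columns (`l1`, `l2`, `l3`), zero rows if
#'   no consistent triplet exists (a time-inconsistent phase pattern is
#'   flagged with a warning).
#' @examples
#' enumerate_label_combinations(c("pre-receptive", "post-receptive",
#'                                "post-receptive"))  # +24, -24, -72
#' @export
enumerate_label_combinations <- function(phases, halfwidth = 12) {
  stopifnot(length(phases) == 3L)
  phases <- as.character(phases)
  lv <- levels(phase_from_label(0))
  if (!all(phases %in% lv)) {
    stop("phases must be among: ", paste(lv, collapse = ", "), call. = FALSE)
  }
  grid <- hour_label_grid()
  l2 <- grid[(grid + 48L) %in% grid & (grid - 48L) %in% grid]
  trip <- cbind(l1 = l2 + 48L, l2 = l2, l3 = l2 - 48L)
  keep <- vapply(seq_len(nrow(trip)), function(i) {
    all(as.character(phase_from_label(trip[i, ], halfwidth)) == phases)
  }, logical(1))
  out <- trip[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("phase triplet '", paste(phases, collapse = " > "),
            "' is inconsistent with monotone sampling time; no labels",
            call. = FALSE)
  }
  out
}
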