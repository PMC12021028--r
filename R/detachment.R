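#' Binarize movie frames with a per-frame Otsu threshold
#'
#' Each frame is thresholded at the gray level maximizing between-class
#' variance (Otsu, 256 levels over the frame's intensity range), making
#' the result invariant to uniform intensity rescaling. Cells may be
#' darker (`foreground = "dark"`, bright-field default) or brighter
#' than the background.
#'
#' @param stack an [image_stack] (grayscale).
#' @param foreground `"dark"` or `"bright"`: which side of the
#'   threshold is cells.
#' @return An [image_stack] of 0/1 frames; constant frames binarize to
#'   all-background with a warning.
#' @export
binarize_frames <- function(stack, foreground = c("dark", "bright")) {
  foreground <- match.arg(foreground)
  d <- dim(stack$frames)
  out <- array(0, d)
  warned <- FALSE
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    rg <- range(fr)
    if (diff(rg) < 1e-12) {
      warned <- TRUE
      next
    }
    thr <- EBImage::otsu(EBImage::Image(fr), range = rg, levels = 256)
    out[, , t] <- if (foreground == "bright") (fr > thr) + 0 else
      (fr <= thr) + 0
  }
  if (warned)
    warning("binarize_frames: constant frame(s) set to all-background")
  image_stack(out, stack$pixel_size, stack$frame_interval)
}

#' Occupancy detachment curve from a binarized movie
#'
#' The foreground-area fraction of each frame, normalized to frame 0,
#' annotated with the active flow-schedule step.
#'
#' @param binary an [image_stack] of 0/1 frames (see
#'   [binarize_frames]).
#' @param schedule a [flow_schedule] covering the movie.
#' @return Data frame of class `detachment_curve`: `time_s`, `value`
#'   (normalized occupancy), `flow_ml_min`, `step`.
#' @export
detachment_curve <- function(binary, schedule = flow_schedule()) {
  d <- dim(binary$frames)
  occ <- vapply(seq_len(d[3]), function(t) mean(binary$frames[, , t]),
                numeric(1))
  if (occ[1] <= 0)
    stop("detachment_curve: frame-0 occupancy is zero; cannot normalize")
  times <- (seq_len(d[3]) - 1) * binary$frame_interval
  if (max(times) > sum(schedule$duration_s))
    stop("detachment_curve: schedule does not cover the movie")
  step <- schedule_step_at(schedule, times)
  out <- data.frame(time_s = times, value = occ / occ[1],
                    flow_ml_min = schedule$flow_ml_min[step], step = step)
  class(out) <- c("detachment_curve", "data.frame")
  out
}

#' Mean intensity detachment curve (alternative normalization)
#'
#' Raw per-frame mean intensity normalized to frame 0, for comparison
#' with the area-based [detachment_curve].
#'
#' @param stack an [image_stack] (grayscale, cells bright).
#' @param schedule a [flow_schedule].
#' @return Data frame like [detachment_curve].
#' @export
intensity_curve <- function(stack, schedule = flow_schedule()) {
  d <- dim(stack$frames)
  occ <- vapply(seq_len(d[3]), function(t) mean(stack$frames[, , t]),
                numeric(1))
  if (abs(occ[1]) < 1e-12)
    stop("intensity_curve: frame-0 mean intensity is zero")
  times <- (seq_len(d[3]) - 1) * stack$frame_interval
  step <- schedule_step_at(schedule, times)
  out <- data.frame(time_s = times, value = occ / occ[1],
                    flow_ml_min = schedule$flow_ml_min[step], step = step)
  class(out) <- c("detachment_curve", "data.frame")
  out
}
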