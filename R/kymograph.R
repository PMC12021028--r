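#' Build a kymograph along a line ROI
#'
#' Samples intensities by bilinear interpolation at unit-pixel steps
#' along the line from `(x0, y0)` to `(x1, y1)`; across the ROI width,
#' samples are taken on perpendicular offsets and max-projected. Row
#' `t` of the result is the profile at frame `t`.
#'
#' @param stack an [image_stack].
#' @param roi numeric `c(x0, y0, x1, y1)` in pixels.
#' @param width ROI width in pixels (>= 1; odd widths center the
#'   line).
#' @return Object of class `kymograph`: list with `data` (time x
#'   position matrix), `pixel_size` (um per column), `frame_interval`.
#' @export
build_kymograph <- function(stack, roi, width = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (width < 1) stop("build_kymograph: width must be >= 1")
  d <- dim(stack$frames)
  if (any(roi[c(1, 3)] < 1 | roi[c(1, 3)] > d[1]) ||
      any(roi[c(2, 4)] < 1 | roi[c(2, 4)] > d[2]))
    stop("build_kymograph: ROI outside frame bounds")
  v <- c(roi[3] - roi[1], roi[4] - roi[2])
  len <- sqrt(sum(v^2))
  n_pos <- max(2L, floor(len) + 1L)
  u <- v / len
  perp <- c(-u[2], u[1])
  offs <- seq_len(width) - (width + 1) / 2
  base <- cbind(roi[1] + u[1] * (seq_len(n_pos) - 1),
                roi[2] + u[2] * (seq_len(n_pos) - 1))
  kymo <- matrix(0, d[3], n_pos)
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    prof <- rep(-Inf, n_pos)
    for (o in offs) {
      pts <- cbind(base[, 1] + perp[1] * o, base[, 2] + perp[2] * o)
      prof <- pmax(prof, interp2_bilinear(fr, pts))
    }
    kymo[t, ] <- prof
  }
  structure(list(data = kymo, pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval, roi = roi,
                 width = width),
            class = "kymograph")
}

## bilinear interpolation on a matrix; clamps sampling outside to 0
interp2_bilinear <- function(m, pts) {
  d <- dim(m)
  x <- pts[, 1]; y <- pts[, 2]
  x0 <- floor(x); y0 <- floor(y)
  ok <- x >= 1 & y >= 1 & x <= d[1] & y <= d[2]
  x0[x0 >= d[1]] <- d[1] - 1L; y0[y0 >= d[2]] <- d[2] - 1L
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  i <- which(ok)
  if (length(i)) {
    val[i] <- m[cbind(x0[i], y0[i])] * (1 - fx[i]) * (1 - fy[i]) +
      m[cbind(x0[i] + 1, y0[i])] * fx[i] * (1 - fy[i]) +
      m[cbind(x0[i], y0[i] + 1)] * (1 - fx[i]) * fy[i] +
      m[cbind(x0[i] + 1, y0[i] + 1)] * fx[i] * fy[i]
  }
  val
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions (%g um/px, %g s/frame)\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Trace gliding events in a kymograph
#'
#' Per frame, local intensity maxima above `threshold` are detected and
#' linked to the nearest active track within `max_jump` pixels; a track
#' ending (or the movie ending) closes an event. Each track is fitted
#' with a least-squares line position ~ time; the velocity is the
#' absolute slope converted to um/s, and the event distance is
#' `velocity x duration`. Events are reported with an `included` flag
#' implementing the velocity > 0 inclusion rule: zero-velocity
#' (stationary) events are reported but flagged excluded from
#' statistics.
#'
#' @param kymo a [build_kymograph] result.
#' @param threshold detection threshold; default half of the kymograph
#'   maximum.
#' @param max_jump maximum per-frame displacement for linking, pixels.
#' @param min_frames minimum track length in frames.
#' @return Data frame of class `gliding_events`: `start_frame`,
#'   `end_frame`, `velocity_um_s`, `distance_um`, `included`.
#' @export
trace_events <- function(kymo, threshold = NULL, max_jump = 5,
                         min_frames = 5) {
  k <- kymo$data
  if (is.null(threshold)) threshold <- 0.5 * max(k)
  nt <- nrow(k); np <- ncol(k)
  tracks <- list()      # each: list(frames =, pos =)
  active <- list()
  for (t in seq_len(nt)) {
    row <- k[t, ]
    isp <- row > threshold &
      row >= c(-Inf, row[-np]) & row >= c(row[-1], -Inf)
    peaks <- which(isp)
    ## sub-pixel refinement by parabolic interpolation
    pos <- vapply(peaks, function(p) {
      if (p <= 1 || p >= np) return(as.numeric(p))
      y1 <- row[p - 1]; y2 <- row[p]; y3 <- row[p + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) < 1e-12) as.numeric(p) else p + 0.5 * (y1 - y3) / den
    }, numeric(1))
    used <- logical(length(pos))
    next_active <- list()
    for (a in active) {
      pred <- a$pos[length(a$pos)]
      if (length(pos)) {
        dd <- abs(pos - pred)
        j <- which.min(dd)
        if (!used[j] && dd[j] <= max_jump) {
          used[j] <- TRUE
          a$frames <- c(a$frames, t)
          a$pos <- c(a$pos, pos[j])
          next_active[[length(next_active) + 1]] <- a
          next
        }
      }
      tracks[[length(tracks) + 1]] <- a
    }
    for (j in which(!used)) {
      next_active[[length(next_active) + 1]] <-
        list(frames = t, pos = pos[j])
    }
    active <- next_active
  }
  tracks <- c(tracks, active)
  tracks <- Filter(function(a) length(a$frames) >= min_frames, tracks)
  if (!length(tracks)) {
    out <- data.frame(start_frame = integer(), end_frame = integer(),
                      velocity_um_s = numeric(), distance_um = numeric(),
                      included = logical())
    class(out) <- c("gliding_events", "data.frame")
    return(out)
  }
  ev <- do.call(rbind, lapply(tracks, function(a) {
    tt <- (a$frames - 1) * kymo$frame_interval
    fit <- stats::lm.fit(cbind(1, tt), a$pos)
    slope <- fit$coefficients[2]              # px / s
    v <- abs(slope) * kymo$pixel_size          # um / s
    if (v < 1e-9) v <- 0                      # numerically stationary
    dur <- diff(range(tt))
    data.frame(start_frame = min(a$frames), end_frame = max(a$frames),
               velocity_um_s = v, distance_um = v * dur)
  }))
  ev$included <- ev$velocity_um_s > 0
  ev <- ev[order(ev$start_frame), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("gliding_events", "data.frame")
  ev
}
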