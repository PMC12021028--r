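#' Time-lapse image stack with physical calibration
#'
#' @param frames numeric 3D array `dim = c(nx, ny, nt)`.
#' @param pixel_size micrometer per pixel.
#' @param frame_interval seconds per frame.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = 0.16, frame_interval = 0.1) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("image_stack: frames must be a 3D array (x, y, t)")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("image_stack: calibrations must be positive")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d x %d px, %d frames, %g um/px, %g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write an image stack as multi-page TIFF (float32)
#' @param stack an [image_stack].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(t) t(stack$frames[, , t]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#' @param path TIFF file.
#' @param pixel_size,frame_interval calibrations to attach.
#' @return An [image_stack].
#' @export
read_stack <- function(path, pixel_size = 0.16, frame_interval = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vapply(pages, function(p) t(as.matrix(p)),
                   matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  image_stack(frames, pixel_size, frame_interval)
}

#' The stepwise flow schedule of the detachment assay
#'
#' Default values are the pump program used in the adhesion assay:
#' pressure stepped every 30 s (first step 25 s), flow rates from 3.77
#' to 51.94 mL/min, last step open-ended.
#'
#' @param pressure_mbar,flow_ml_min,duration_s equal-length step
#'   vectors; flow rates must be strictly increasing, durations
#'   positive (the last may be `Inf`).
#' @return A data frame of class `flow_schedule`.
#' @export
flow_schedule <- function(pressure_mbar = c(5, 10, 20, 40, 60, 80, 95),
                          flow_ml_min = c(3.77, 7.38, 14.18, 26.28,
                                          36.72, 45.83, 51.94),
                          duration_s = c(25, 30, 30, 30, 30, 30, Inf)) {
  if (length(flow_ml_min) != length(duration_s) ||
      length(flow_ml_min) != length(pressure_mbar))
    stop("flow_schedule: step vectors must have equal length")
  if (any(diff(flow_ml_min) <= 0))
    stop("flow_schedule: flow rates must be strictly increasing")
  if (any(duration_s <= 0))
    stop("flow_schedule: durations must be positive")
  structure(data.frame(pressure_mbar = pressure_mbar,
                       flow_ml_min = flow_ml_min,
                       duration_s = duration_s),
            class = c("flow_schedule", "data.frame"))
}

## active schedule step at each time point (seconds)
schedule_step_at <- function(schedule, times) {
  ends <- cumsum(schedule$duration_s)
  pmin(findInterval(times, c(0, ends[-length(ends)]),
                    rightmost.closed = FALSE), nrow(schedule))
}

#' Specification for gliding / detachment movie phantoms
#'
#' @param shape `c(nx, ny)` frame size in pixels.
#' @param n_frames number of frames.
#' @param pixel_size micrometer per pixel.
#' @param frame_interval seconds per frame (10 fps default).
#' @param events data frame of gliding events: `start_frame`,
#'   `duration_s`, `velocity_um_s`, `x0`, `y0` (pixels); NULL for none.
#' @param cells data frame of adherent cell disks: `x`, `y`, `radius`
#'   (pixels); NULL for none.
#' @param detach_prob per-schedule-step detachment probability for each
#'   cell (vector over steps, values in [0, 1]).
#' @param spot_sigma Gaussian spot sd, pixels.
#' @param fg,bg foreground and background intensities.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return A validated spec of class `motility_phantom_spec`.
#' @export
motility_phantom_spec <- function(shape = c(192, 48), n_frames = 300,
                                  pixel_size = 0.16, frame_interval = 0.1,
                                  events = NULL, cells = NULL,
                                  detach_prob = NULL, spot_sigma = 2,
                                  fg = 1, bg = 0, noise_sigma = 0.05,
                                  seed = 1) {
  if (!is.null(events)) {
    if (any(events$velocity_um_s < 0))
      stop("motility_phantom_spec: velocities must be >= 0")
    if (any(events$start_frame < 1 | events$start_frame > n_frames))
      stop("motility_phantom_spec: event start outside the movie")
  }
  if (!is.null(detach_prob) && any(detach_prob < 0 | detach_prob > 1))
    stop("motility_phantom_spec: detachment probabilities must be in [0, 1]")
  structure(list(shape = as.integer(shape), n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 events = events, cells = cells, detach_prob = detach_prob,
                 spot_sigma = spot_sigma, fg = fg, bg = bg,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "motility_phantom_spec")
}

#' Simulate a gliding movie with known event truth
#'
#' Gaussian spots translate along +x at their stated velocities for
#' their stated durations. Truth velocity and distance per event are
#' returned.
#'
#' @param spec a [motility_phantom_spec] with `events`.
#' @return List: `stack` ([image_stack]), `truth` (data frame with
#'   `start_frame`, `end_frame`, `velocity_um_s`, `distance_um`).
#' @export
simulate_motility_movie <- function(spec) {
  stopifnot(inherits(spec, "motility_phantom_spec"))
  if (is.null(spec$events)) stop("simulate_motility_movie: no events in spec")
  set.seed(spec$seed)
  d <- spec$shape
  ev <- spec$events
  frames <- array(spec$bg, c(d[1], d[2], spec$n_frames))
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  for (i in seq_len(nrow(ev))) {
    nfr <- round(ev$duration_s[i] / spec$frame_interval)
    v_px <- ev$velocity_um_s[i] * spec$frame_interval / spec$pixel_size
    for (f in seq_len(nfr)) {
      t <- ev$start_frame[i] + f - 1L
      if (t > spec$n_frames) break
      cx <- ev$x0[i] + v_px * (f - 1)
      cy <- ev$y0[i]
      if (cx > d[1] - 2) break
      spot <- spec$fg * exp(-outer((xs - cx)^2, (ys - cy)^2, "+") /
                              (2 * spec$spot_sigma^2))
      frames[, , t] <- frames[, , t] + spot
    }
  }
  if (spec$noise_sigma > 0)
    frames <- frames + stats::rnorm(length(frames), 0, spec$noise_sigma)
  dur <- round(ev$duration_s / spec$frame_interval) * spec$frame_interval
  truth <- data.frame(start_frame = ev$start_frame,
                      end_frame = pmin(ev$start_frame +
                                         round(ev$duration_s /
                                                 spec$frame_interval) - 1L,
                                       spec$n_frames),
                      velocity_um_s = ev$velocity_um_s,
                      distance_um = ev$velocity_um_s * dur)
  list(stack = image_stack(frames, spec$pixel_size, spec$frame_interval),
       truth = truth)
}

#' Simulate a flow-detachment movie with known occupancy truth
#'
#' Adherent cells are uniform disks; during each schedule step every
#' still-attached cell detaches with that step's probability, at a
#' uniformly random frame within the step. The truth curve is the
#' fraction of the initial cells still attached at each frame.
#'
#' @param spec a [motility_phantom_spec] with `cells` and
#'   `detach_prob`.
#' @param schedule a [flow_schedule] covering the movie.
#' @return List: `stack` ([image_stack]), `truth` (data frame `time_s`,
#'   `fraction_remaining`), `detach_frame` (per cell; NA = never).
#' @export
simulate_detachment_movie <- function(spec, schedule = flow_schedule()) {
  stopifnot(inherits(spec, "motility_phantom_spec"))
  if (is.null(spec$cells)) stop("simulate_detachment_movie: no cells in spec")
  set.seed(spec$seed)
  d <- spec$shape
  cells <- spec$cells
  nfr <- spec$n_frames
  times <- (seq_len(nfr) - 1) * spec$frame_interval
  step_of_frame <- schedule_step_at(schedule, times)
  if (max(times) > sum(schedule$duration_s))
    stop("simulate_detachment_movie: schedule does not cover the movie")
  p_step <- spec$detach_prob
  if (is.null(p_step)) p_step <- rep(0, nrow(schedule))
  if (length(p_step) != nrow(schedule))
    stop("simulate_detachment_movie: one detachment probability per step required")
  detach_frame <- rep(NA_integer_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    for (s in seq_len(nrow(schedule))) {
      fr <- which(step_of_frame == s)
      if (!length(fr)) next
      if (stats::runif(1) < p_step[s]) {
        detach_frame[i] <- fr[sample.int(length(fr), 1)]
        break
      }
    }
  }
  frames <- array(spec$bg, c(d[1], d[2], nfr))
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  disks <- lapply(seq_len(nrow(cells)), function(i)
    outer((xs - cells$x[i])^2, (ys - cells$y[i])^2, "+") <=
      cells$radius[i]^2)
  for (t in seq_len(nfr)) {
    fr <- matrix(spec$bg, d[1], d[2])
    for (i in seq_len(nrow(cells))) {
      if (!is.na(detach_frame[i]) && t >= detach_frame[i]) next
      fr[disks[[i]]] <- spec$fg
    }
    frames[, , t] <- fr
  }
  if (spec$noise_sigma > 0)
    frames <- frames + stats::rnorm(length(frames), 0, spec$noise_sigma)
  attached <- vapply(seq_len(nfr), function(t)
    sum(is.na(detach_frame) | detach_frame > t), numeric(1))
  truth <- data.frame(time_s = times,
                      fraction_remaining = attached / nrow(cells))
  list(stack = image_stack(frames, spec$pixel_size, spec$frame_interval),
       truth = truth, detach_frame = detach_frame)
}

#' Random non-overlapping cell field for detachment phantoms
#'
#' Dart-throwing placement of equal-radius disks with a minimum
#' separation, so each cell contributes an identical, independent area
#' quantum to the occupancy curve.
#'
#' @param n number of cells.
#' @param shape frame size `c(nx, ny)`, pixels.
#' @param radius disk radius, pixels.
#' @param margin minimum extra separation between disk rims, pixels.
#' @param seed RNG seed.
#' @return Data frame `x`, `y`, `radius`.
#' @export
random_cell_field <- function(n, shape = c(192, 48), radius = 4,
                              margin = 2, seed = 1) {
  set.seed(seed)
  pos <- matrix(NA_real_, 0, 2)
  min_d <- 2 * radius + margin
  tries <- 0L
  while (nrow(pos) < n && tries < 400L * n) {
    tries <- tries + 1L
    p <- c(stats::runif(1, radius + 2, shape[1] - radius - 1),
           stats::runif(1, radius + 2, shape[2] - radius - 1))
    if (nrow(pos) && min(sqrt(colSums((t(pos) - p)^2))) < min_d) next
    pos <- rbind(pos, p)
  }
  if (nrow(pos) < n)
    stop(sprintf("random_cell_field: placed only %d of %d cells", nrow(pos), n))
  data.frame(x = pos[, 1], y = pos[, 2], radius = radius)
}
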