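#' Specification for a coat-bearing tomogram phantom
#'
#' Describes a tubular membrane (a cilium cross-section swept along z)
#' decorated with an outer coat of small asymmetric particles, imaged
#' with additive Gaussian noise and a single-axis missing wedge. All
#' physical lengths are in Angstrom; the membrane surface is the tube
#' radius, and particle centers are placed in the band
#' `[d_in + pad, d_out - pad]` outside it so they always fall inside the
#' matching shell mask.
#'
#' @param shape volume dimensions, voxels (length 3).
#' @param voxel_size Angstrom per voxel.
#' @param centerline data frame with columns `z`, `x`, `y` (voxels) of
#'   tube centerline control points; NULL for a gentle default curve.
#' @param tube_radius membrane radius, Angstrom.
#' @param membrane_thickness FWHM of the membrane density band, Angstrom.
#' @param d_in,d_out coat band offsets outside the membrane, Angstrom
#'   (`d_in < d_out`).
#' @param template particle density as [volume3d] or 3D array; NULL for
#'   the default asymmetric L-shaped blob.
#' @param n_particles number of coat particles to place.
#' @param min_spacing minimum center-to-center spacing, Angstrom.
#' @param noise_sigma additive Gaussian noise sd, as a fraction of the
#'   template peak.
#' @param wedge NULL, or `list(tilt_range =, increment =)` in degrees.
#' @param with_axoneme render 9 axonemal rods inside the tube (visual
#'   realism only; no algorithm uses them).
#' @param seed RNG seed making the phantom reproducible.
#' @return A validated spec of class `tomo_phantom_spec`.
#' @export
tomo_phantom_spec <- function(shape = c(128, 128, 128), voxel_size = 10,
                              centerline = NULL, tube_radius = 250,
                              membrane_thickness = 40,
                              d_in = 50, d_out = 250,
                              template = NULL, n_particles = 50,
                              min_spacing = 180, noise_sigma = 0.3,
                              wedge = list(tilt_range = 60, increment = 2),
                              with_axoneme = TRUE, seed = 1) {
  if (length(shape) != 3L || any(shape < 8)) stop("tomo_phantom_spec: bad shape")
  if (d_in >= d_out) stop("tomo_phantom_spec: d_in must be < d_out")
  if (min_spacing <= 0) stop("tomo_phantom_spec: particle spacing must be > 0")
  if (!is.null(wedge)) {
    if (wedge$tilt_range <= 0 || wedge$tilt_range > 90)
      stop("tomo_phantom_spec: wedge tilt range must be in (0, 90]")
  }
  if (is.null(centerline)) {
    zs <- seq(1, shape[3], length.out = 5)
    centerline <- data.frame(
      z = zs,
      x = shape[1] / 2 + 3 * sin(seq(0, pi, length.out = 5)),
      y = shape[2] / 2 + 3 * cos(seq(0, pi, length.out = 5)))
  }
  if (is.null(template)) template <- default_particle_template(voxel_size)
  template <- as_volume3d(template, voxel_size)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 centerline = centerline, tube_radius = tube_radius,
                 membrane_thickness = membrane_thickness,
                 d_in = d_in, d_out = d_out, template = template,
                 n_particles = as.integer(n_particles),
                 min_spacing = min_spacing, noise_sigma = noise_sigma,
                 wedge = wedge, with_axoneme = isTRUE(with_axoneme),
                 seed = as.integer(seed)),
            class = "tomo_phantom_spec")
}

#' Default coat-particle template: an asymmetric L-shaped blob
#'
#' Three fused Gaussians in a 15^3 box, peak normalized to 1. The shape
#' has no rotational symmetry, so the orientation of a match is
#' identifiable.
#'
#' @param voxel_size Angstrom per voxel of the template grid.
#' @param box box side in voxels (odd).
#' @return A [volume3d].
#' @export
default_particle_template <- function(voxel_size = 10, box = 15) {
  d <- rep(as.integer(box), 3)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  blob <- function(cx, cy, cz, s, a) {
    a * exp(-((g$x - ctr[1] - cx)^2 + (g$y - ctr[2] - cy)^2 +
                (g$z - ctr[3] - cz)^2) / (2 * s^2))
  }
  v <- blob(0, 0, 2.4, 1.9, 1.0) + blob(0, 0, -1.6, 1.7, 0.9) +
    blob(2.9, 0, -1.6, 1.6, 0.85)
  v <- array(v, d)
  volume3d(v / max(v), voxel_size = voxel_size)
}

## continuous centerline (x(z), y(z)) from control points
centerline_funs <- function(centerline) {
  fx <- stats::splinefun(centerline$z, centerline$x, method = "natural")
  fy <- stats::splinefun(centerline$z, centerline$y, method = "natural")
  list(x = fx, y = fy)
}

#' Simulate a coat-bearing tomogram phantom with ground truth
#'
#' Renders membrane tube, optional axonemal rods and `n_particles`
#' copies of the particle template placed on the outer coat band with
#' outward-normal orientations and a minimum spacing, then adds Gaussian
#' noise and applies the missing wedge. The returned ground truth lists
#' the continuous voxel position and ZYZ orientation of every particle.
#'
#' @param spec a [tomo_phantom_spec].
#' @return `list(volume = volume3d, truth = data.frame(x, y, z, rot,
#'   tilt, psi))`.
#' @export
simulate_tomogram <- function(spec) {
  stopifnot(inherits(spec, "tomo_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  vs <- spec$voxel_size
  cl <- centerline_funs(spec$centerline)
  tmpl <- spec$template$data
  nt <- dim(tmpl)
  r_t_vox <- max(nt) / 2                      # template enclosing half-extent
  pad <- r_t_vox * vs * 0.5                   # keep template density in band
  r_mem <- spec$tube_radius / vs
  sig_m <- spec$membrane_thickness / vs / 2.355

  vol <- array(0, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  ax_ang <- 2 * pi * (0:8) / 9
  for (z in seq_len(d[3])) {
    cx <- cl$x(z); cy <- cl$y(z)
    r <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
    sl <- exp(-(r - r_mem)^2 / (2 * sig_m^2))
    if (spec$with_axoneme) {
      ra <- 0.4 * r_mem
      for (a in ax_ang) {
        rx <- cx + ra * cos(a); ry <- cy + ra * sin(a)
        sl <- sl + 0.6 * exp(-outer((xs - rx)^2, (ys - ry)^2, "+") / (2 * 1.5^2))
      }
    }
    vol[, , z] <- sl
  }

  ## particle placement: greedy dart throwing on the coat band
  lo <- spec$d_in + pad
  hi <- spec$d_out - pad
  if (lo >= hi) stop("simulate_tomogram: template too large for the coat band")
  zmargin <- r_t_vox + 1
  pos <- matrix(NA_real_, 0, 3)
  ang <- matrix(NA_real_, 0, 3)
  tries <- 0L
  max_tries <- 400L * spec$n_particles
  min_sp_vox <- spec$min_spacing / vs
  while (nrow(pos) < spec$n_particles && tries < max_tries) {
    tries <- tries + 1L
    z <- stats::runif(1, 1 + zmargin, d[3] - zmargin)
    th <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, lo, hi) / vs
    cx <- cl$x(z); cy <- cl$y(z)
    p <- c(cx + (r_mem + off) * cos(th), cy + (r_mem + off) * sin(th), z)
    if (p[1] < 1 + r_t_vox || p[1] > d[1] - r_t_vox ||
        p[2] < 1 + r_t_vox || p[2] > d[2] - r_t_vox) next
    if (nrow(pos)) {
      dd <- sqrt(colSums((t(pos) - p)^2))
      if (min(dd) < min_sp_vox) next
    }
    pos <- rbind(pos, p)
    ang <- rbind(ang, c(th * 180 / pi, 90, stats::runif(1, 0, 360)))
  }
  if (nrow(pos) < spec$n_particles)
    stop(sprintf(paste0("simulate_tomogram: could only place %d of %d particles",
                        " at spacing %g A"), nrow(pos), spec$n_particles,
                 spec$min_spacing))

  ## render particles: pull-back resampling T(R^-1 (x - p) + c)
  ctr_t <- (nt + 1) / 2
  h <- ceiling(r_t_vox * sqrt(3)) + 1L
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    R <- euler_to_matrix(ang[i, 1], ang[i, 2], ang[i, 3])
    ix <- max(1, floor(p[1]) - h):min(d[1], ceiling(p[1]) + h)
    iy <- max(1, floor(p[2]) - h):min(d[2], ceiling(p[2]) + h)
    iz <- max(1, floor(p[3]) - h):min(d[3], ceiling(p[3]) + h)
    g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    pts <- sweep(g, 2, p) %*% R        # R^-1 (x - p), as row vectors
    pts <- sweep(pts, 2, ctr_t, "+")
    vol[g] <- vol[g] + interp3(tmpl, pts)
  }

  if (spec$noise_sigma > 0)
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sigma * max(tmpl))

  out <- volume3d(vol, voxel_size = vs)
  if (!is.null(spec$wedge))
    out <- apply_missing_wedge(out, spec$wedge$tilt_range,
                               spec$wedge$increment)
  truth <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      rot = ang[, 1], tilt = ang[, 2], psi = ang[, 3])
  rownames(truth) <- NULL
  list(volume = out, truth = truth)
}

#' Apply a single-axis missing wedge in Fourier space
#'
#' Models the unsampled region of a +/- `tilt_range` tilt series (tilt
#' axis y, beam along z): Fourier coefficients whose (kx, kz) direction
#' lies more than `tilt_range` degrees from the kx axis are zeroed. The
#' mask is the continuous envelope of the tilt range; the increment is
#' kept for metadata only, since at fine increments the sampled central
#' slices fuse into the wedge on a finite grid. The operation is
#' idempotent and returns a real volume.
#'
#' @param vol a [volume3d] or 3D array.
#' @param tilt_range half tilt range, degrees, in (0, 90].
#' @param increment tilt increment, degrees (metadata only).
#' @return Same type as the input, wedge-filtered.
#' @export
apply_missing_wedge <- function(vol, tilt_range = 60, increment = 2) {
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("apply_missing_wedge: input must be 3D")
  if (tilt_range <= 0 || tilt_range > 90)
    stop("apply_missing_wedge: tilt_range must be in (0, 90]")
  keep <- missing_wedge_mask(dim(arr), tilt_range)
  f <- stats::fft(arr)
  f[!keep] <- 0
  out <- Re(stats::fft(f, inverse = TRUE)) / length(f)
  if (inherits(vol, "volume3d")) {
    vol$data <- out
    vol
  } else out
}

#' Binary Fourier-domain wedge mask (TRUE = sampled)
#'
#' @param dims volume dimensions.
#' @param tilt_range half tilt range, degrees.
#' @return Logical array: TRUE where the frequency is sampled.
#' @export
missing_wedge_mask <- function(dims, tilt_range = 60) {
  kx <- abs(freq_index(dims[1]))
  kz <- abs(freq_index(dims[3]))
  ang <- atan2(rep(kz, each = length(kx)), rep(kx, times = length(kz)))
  keep2d <- matrix(ang <= deg2rad(tilt_range) + 1e-12,
                   length(kx), length(kz))
  aperm(array(rep(keep2d, times = dims[2]), c(dims[1], dims[3], dims[2])),
        c(1, 3, 2))
}

#' True membrane points of a tomogram phantom
#'
#' Emulates per-slice clicked membrane points from the generator truth:
#' points on the membrane circle (tube radius) around the centerline, at
#' a set of slices. These are the natural input for
#' [fit_shell_from_points].
#'
#' @param spec a [tomo_phantom_spec].
#' @param n_slices number of slices to sample across the z extent.
#' @param n_points points per slice.
#' @param jitter sd of positional jitter in voxels (0 = exact).
#' @return Data frame with columns `slice`, `x`, `y` (voxels).
#' @export
phantom_membrane_points <- function(spec, n_slices = 9, n_points = 24,
                                    jitter = 0) {
  cl <- centerline_funs(spec$centerline)
  r <- spec$tube_radius / spec$voxel_size
  zs <- round(seq(1, spec$shape[3], length.out = n_slices))
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  out <- do.call(rbind, lapply(zs, function(z) {
    data.frame(slice = z,
               x = cl$x(z) + r * cos(th),
               y = cl$y(z) + r * sin(th))
  }))
  if (jitter > 0) {
    out$x <- out$x + stats::rnorm(nrow(out), 0, jitter)
    out$y <- out$y + stats::rnorm(nrow(out), 0, jitter)
  }
  out
}
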