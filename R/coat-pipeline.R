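#' Summary statistics of a mapped particle coat
#'
#' Reports particle count, surface density per square micrometer of
#' membrane at the mean radial offset of the particles, the
#' nearest-neighbor distance distribution and the distribution of angles
#' between each particle's z axis and the outward membrane normal.
#'
#' @param particles a [particle_table].
#' @param tube the [build_tube] model of the membrane (same volume
#'   frame).
#' @param voxel_size Angstrom per voxel.
#' @return A list: `count`, `density_per_um2`, `nn_dist_A` (vector),
#'   `normal_angle_deg` (vector), `mean_radius_A`.
#' @export
coat_statistics <- function(particles, tube, voxel_size = 1) {
  if (nrow(particles) == 0L) {
    return(list(count = 0L, density_per_um2 = 0, nn_dist_A = numeric(),
                normal_angle_deg = numeric(), mean_radius_A = 0))
  }
  p <- as.matrix(particles[, c("x", "y", "z")])
  ## radial offset from the tube centroid path, per particle
  zc <- pmin(pmax(p[, 3], min(tube$slices)), max(tube$slices))
  ctrs <- t(vapply(zc, function(z) tube_center_at(tube, z), numeric(2)))
  radial <- p[, 1:2] - ctrs
  rad <- sqrt(rowSums(radial^2))
  mean_rad_A <- mean(rad) * voxel_size
  ## membrane-band area at the mean particle radius over the z extent
  ## spanned by the particles (perimeter of the offset contour x height)
  zr <- range(p[, 3])
  zs <- seq(max(zr[1], min(tube$slices)), min(zr[2], max(tube$slices)),
            length.out = 16)
  perim <- vapply(zs, function(z) {
    poly <- tube_contour_at(tube, z)
    ctr <- colMeans(poly)
    rel <- sweep(poly, 2, ctr)
    r0 <- sqrt(rowSums(rel^2))
    off <- sweep(rel * (mean(rad) / mean(r0)), 2, ctr, "+")
    sum(sqrt(rowSums((off[c(2:nrow(off), 1), ] - off)^2)))
  }, numeric(1))
  area_A2 <- mean(perim) * voxel_size * max(diff(zr), 1) * voxel_size
  density <- nrow(p) / (area_A2 * 1e-8)          # A^2 -> um^2
  ## nearest neighbors
  nn <- if (nrow(p) > 1) {
    dm <- as.matrix(stats::dist(p))
    diag(dm) <- Inf
    apply(dm, 1, min) * voxel_size
  } else numeric()
  ## orientation vs outward normal
  ang <- vapply(seq_len(nrow(p)), function(i) {
    n <- radial[i, ] / max(rad[i], 1e-9)
    R <- euler_to_matrix(particles$rot[i], particles$tilt[i], particles$psi[i])
    zax <- R %*% c(0, 0, 1)
    acos(min(1, max(-1, sum(zax[1:2] * n)))) * 180 / pi
  }, numeric(1))
  list(count = nrow(p), density_per_um2 = density, nn_dist_A = nn,
       normal_angle_deg = ang, mean_radius_A = mean_rad_A)
}

## local NCC around one candidate at full resolution: searches the given
## orientations (the coarse best plus its grid neighbors) over a +/-
## radius shift box, picks the global best, then localizes the peak to
## sub-voxel precision by separable parabolic interpolation. Same
## normalization as match_template, computed in a small FFT box.
refine_candidate <- function(varr, template, rotations, center, radius = 3L,
                             footprint_radius = NULL, wedge = NULL) {
  nt <- dim(template)
  d <- dim(varr)
  h <- (nt - 1L) %/% 2L
  ## clamp the search box inside the volume so candidates near the
  ## border keep a (possibly off-center) shift range instead of being
  ## dropped
  center <- pmin(pmax(round(center), h + radius + 1L), d - h - radius)
  if (any(center < h + radius + 1L))
    return(list(center = round(center), score = NA_real_, orientation = 1L))
  lo <- center - h - radius
  hi <- center + h + radius
  patch <- varr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  dp <- dim(patch)
  M <- spherical_footprint(nt, footprint_radius)
  n_m <- sum(M)
  fp <- stats::fft(patch)
  fp2 <- stats::fft(patch * patch)
  fM <- Conj(stats::fft(pad_center(array(as.numeric(M), nt), dp)))
  s1 <- cross_correlate_fft(fM, fp)
  s2 <- cross_correlate_fft(fM, fp2)
  den <- sqrt(pmax(s2 - s1 * s1 / n_m, 1e-12))
  wmask <- if (!is.null(wedge)) missing_wedge_mask(nt, wedge$tilt_range)
  ctr_rel <- h + 1L + radius              # position of 'center' in patch
  win <- lapply(1:3, function(k) (ctr_rel[k] - radius):(ctr_rel[k] + radius))
  best <- list(score = -Inf, sub = NULL, orientation = 1L)
  if (is.matrix(rotations)) rotations <- list(rotations)
  for (oi in seq_along(rotations)) {
    tr <- rotate_volume_array(template, rotations[[oi]])
    if (!is.null(wmask)) {
      ft <- stats::fft(tr)
      ft[!wmask] <- 0
      tr <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
    }
    tr <- tr * M
    tr[M] <- tr[M] - mean(tr[M])
    nrm <- sqrt(sum(tr[M]^2))
    if (nrm < 1e-12) next
    tr <- tr / nrm
    num <- cross_correlate_fft(Conj(stats::fft(pad_center(tr, dp))), fp)
    sc <- num / den
    sub <- sc[win[[1]], win[[2]], win[[3]]]
    if (max(sub) > best$score) {
      best <- list(score = max(sub), sub = sub, orientation = oi)
    }
  }
  if (!is.finite(best$score))
    return(list(center = round(center), score = NA_real_, orientation = 1L))
  sub <- best$sub
  bi <- as.integer(arrayInd(which.max(sub), dim(sub)))
  ## sub-voxel peak by per-axis parabola through the 3 scores
  frac <- numeric(3)
  for (ax in 1:3) {
    if (bi[ax] > 1 && bi[ax] < dim(sub)[ax]) {
      idx <- bi
      idx[ax] <- bi[ax] - 1L; y1 <- sub[matrix(idx, 1)]
      y2 <- sub[matrix(bi, 1)]
      idx[ax] <- bi[ax] + 1L; y3 <- sub[matrix(idx, 1)]
      dn <- y1 - 2 * y2 + y3
      if (abs(dn) > 1e-12) frac[ax] <- min(0.5, max(-0.5, 0.5 * (y1 - y3) / dn))
    }
  }
  off <- bi - radius - 1L + frac
  list(center = round(center) + off, score = best$score,
       orientation = best$orientation)
}

#' Map coat particles in a tomogram (full pipeline)
#'
#' Coarse-to-fine template matching: the full rotation grid is searched
#' on a `bin`-times binned copy of the volume (the paper's approach of
#' matching a downscaled map), peaks are extracted, each candidate's
#' position is refined at full resolution by local normalized
#' cross-correlation with its best orientation, and the greedy
#' overlap-exclusion filter removes lower-scoring overlapping particles.
#'
#' @param vol tomogram [volume3d].
#' @param mask [build_shell_mask] result (full-resolution), or NULL.
#' @param template particle template [volume3d].
#' @param angular_step rotation-grid step, degrees.
#' @param threshold minimum coarse NCC score for a peak.
#' @param min_spacing minimum particle spacing, Angstrom.
#' @param bin coarse-search binning factor.
#' @param refine_radius full-resolution local search radius, voxels.
#' @param refine_threshold minimum full-resolution NCC score a refined
#'   candidate must reach to be kept; noise maxima score far below real
#'   particles at full resolution, so this is the main false-positive
#'   control.
#' @param overlap_threshold maximum claimed footprint fraction.
#' @param wedge optional wedge `list(tilt_range=, increment=)` applied
#'   to the rotated template during scoring.
#' @param highpass_sigma Gaussian high-pass sd (voxels) applied to both
#'   volume and template before matching; suppresses smooth large-scale
#'   structures such as the membrane itself, which otherwise produce
#'   spurious correlation peaks. 0 disables.
#' @return A [particle_table] of accepted particles; attribute
#'   `score_map` holds the coarse score map.
#' @export
map_coat <- function(vol, mask, template, angular_step = 20,
                     threshold = 0.2, min_spacing = 180, bin = 2L,
                     refine_radius = 3L, refine_threshold = 0.2,
                     overlap_threshold = 0.2, wedge = NULL,
                     highpass_sigma = 3) {
  grid <- make_rotation_grid(angular_step)
  if (highpass_sigma > 0) {
    vol$data <- highpass_array(vol$data, highpass_sigma)
    template$data <- highpass_array(template$data, highpass_sigma)
  }
  vb <- bin_volume(vol, bin)
  tb <- bin_volume(template, bin)
  mb <- NULL
  if (!is.null(mask)) {
    m <- if (inherits(mask, "shell_mask")) mask$mask else mask
    mv <- bin_volume(volume3d(array(as.numeric(m), dim(m)),
                              vol$voxel_size), bin)
    mb <- mv$data > 0
  }
  sm <- match_template(vb, tb, mask = mb, grid = grid, wedge = wedge)
  min_sp_bvox <- max(1, min_spacing / vol$voxel_size / bin * 0.7)
  peaks <- extract_peaks(sm, min_distance = min_sp_bvox, threshold = threshold)
  if (!nrow(peaks)) {
    out <- particle_table()
    attr(out, "score_map") <- sm
    return(out)
  }
  ## coarse voxel b covers full-res voxels (b-1)*bin + 1 .. b*bin
  d <- dim(vol$data)
  ## orientation neighborhoods on the grid for local angular refinement
  quats <- t(vapply(seq_len(nrow(grid)), function(i)
    ciliacoat_quat(grid$rot[i], grid$tilt[i], grid$psi[i]), numeric(4)))
  cos_nb <- cos(deg2rad(0.75 * attr(grid, "step")) / 2)
  ref <- lapply(seq_len(nrow(peaks)), function(i) {
    nb <- which(abs(quats %*% quats[peaks$orientation[i], ]) > cos_nb)
    rots <- lapply(nb, function(j)
      euler_to_matrix(grid$rot[j], grid$tilt[j], grid$psi[j]))
    c0 <- (c(peaks$x[i], peaks$y[i], peaks$z[i]) - 1) * bin + (bin + 1) / 2
    r <- refine_candidate(vol$data, template$data, rots, c0,
                          radius = as.integer(refine_radius), wedge = wedge)
    r$grid_index <- nb[r$orientation]
    r
  })
  ok <- !vapply(ref, function(r) is.na(r$score), logical(1))
  gi <- vapply(ref, function(r) r$grid_index, integer(1))
  cands <- data.frame(
    x = vapply(ref, function(r) r$center[1], numeric(1)),
    y = vapply(ref, function(r) r$center[2], numeric(1)),
    z = vapply(ref, function(r) r$center[3], numeric(1)),
    rot = grid$rot[gi], tilt = grid$tilt[gi], psi = grid$psi[gi],
    score = vapply(ref, function(r) pmin(r$score, 1), numeric(1)),
    orientation = gi)[ok, , drop = FALSE]
  cands <- cands[cands$score >= refine_threshold, , drop = FALSE]
  out <- overlap_filter(cands, template, overlap_threshold, d)
  attr(out, "score_map") <- sm
  out
}

#' Match detected particles against ground truth
#'
#' Greedy one-to-one assignment: candidate pairs within `max_dist`
#' voxels are matched in order of increasing distance.
#'
#' @param found a [particle_table] (or data frame with x, y, z).
#' @param truth ground-truth data frame with x, y, z.
#' @param max_dist maximum match distance, voxels.
#' @return List: `recall`, `precision`, `fdr`, `n_matched`,
#'   `match_dist` (voxels), `pairs` (found index, truth index).
#' @export
coat_recovery <- function(found, truth, max_dist = 5) {
  nf <- nrow(found); nt <- nrow(truth)
  if (nf == 0L || nt == 0L)
    return(list(recall = 0, precision = if (nf) 0 else NA_real_,
                fdr = if (nf) 1 else NA_real_, n_matched = 0L,
                match_dist = numeric(), pairs = cbind(integer(), integer())))
  fp <- as.matrix(found[, c("x", "y", "z")])
  tp <- as.matrix(truth[, c("x", "y", "z")])
  dmat <- outer(rowSums(fp^2), rep(1, nt)) +
    outer(rep(1, nf), rowSums(tp^2)) - 2 * fp %*% t(tp)
  dmat <- sqrt(pmax(dmat, 0))
  cand <- which(dmat <= max_dist, arr.ind = TRUE)
  ord <- order(dmat[cand])
  cand <- cand[ord, , drop = FALSE]
  used_f <- logical(nf); used_t <- logical(nt)
  pairs <- matrix(integer(), 0, 2)
  dists <- numeric()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_f[i] || used_t[j]) next
    used_f[i] <- TRUE; used_t[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
    dists <- c(dists, dmat[i, j])
  }
  n_m <- nrow(pairs)
  list(recall = n_m / nt, precision = n_m / nf, fdr = 1 - n_m / nf,
       n_matched = n_m, match_dist = dists, pairs = pairs)
}
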