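#' Rotation-searched, locally normalized template matching
#'
#' For every voxel inside the mask, computes the maximum over all grid
#' orientations of the locally normalized cross-correlation (Roseman
#' style) between the volume and the rotated template. Local mean and
#' variance are computed under a rotation-invariant spherical footprint
#' enclosing the template support, so they are evaluated once; the
#' rotated, footprint-masked, mean-subtracted, unit-norm template is
#' correlated against the volume by FFT. Scores are bounded by 1 by
#' Cauchy-Schwarz. If `wedge` is given, the rotated template is wedge
#' filtered before scoring (missing-wedge-aware matching).
#'
#' @param vol a [volume3d] (or 3D array).
#' @param template a [volume3d] (or 3D array) no larger than `vol`, same
#'   voxel size.
#' @param mask logical array of `dim(vol)` (or a `shell_mask`); NULL
#'   scores every voxel.
#' @param grid a [make_rotation_grid] result.
#' @param wedge NULL or `list(tilt_range =, increment =)`.
#' @param footprint_radius radius (voxels) of the spherical
#'   normalization footprint; default half the template box.
#' @return A `score_map`: list with `scores` (array, NA outside mask),
#'   `best_orientation` (integer array indexing `grid`), `grid`,
#'   `voxel_size`.
#' @export
match_template <- function(vol, template, mask = NULL, grid,
                           wedge = NULL, footprint_radius = NULL) {
  v <- if (inherits(vol, "volume3d")) vol$data else vol
  tm <- if (inherits(template, "volume3d")) template$data else template
  if (inherits(vol, "volume3d") && inherits(template, "volume3d") &&
      abs(vol$voxel_size - template$voxel_size) > 1e-6 * vol$voxel_size)
    stop("match_template: voxel size mismatch between volume and template")
  d <- dim(v); nt <- dim(tm)
  if (any(nt > d)) stop("match_template: template larger than volume")
  if (inherits(mask, "shell_mask")) mask <- mask$mask
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("match_template: mask dimensions differ from volume")

  M <- spherical_footprint(nt, footprint_radius)
  n_m <- sum(M)
  f_v <- stats::fft(v)
  f_v2 <- stats::fft(v * v)
  fM_conj <- Conj(stats::fft(pad_center(array(as.numeric(M), nt), d)))
  s1 <- cross_correlate_fft(fM_conj, f_v)
  s2 <- cross_correlate_fft(fM_conj, f_v2)
  denom <- sqrt(pmax(s2 - s1 * s1 / n_m, 0))
  flat <- denom < 1e-9 * max(denom)

  wmask <- if (!is.null(wedge)) missing_wedge_mask(nt, wedge$tilt_range) else NULL
  best <- array(-Inf, d)
  bidx <- array(NA_integer_, d)
  for (i in seq_len(nrow(grid))) {
    R <- euler_to_matrix(grid$rot[i], grid$tilt[i], grid$psi[i])
    tr <- rotate_volume_array(tm, R)
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
    num <- cross_correlate_fft(Conj(stats::fft(pad_center(tr, d))), f_v)
    sc <- num / denom
    sc[flat] <- 0
    upd <- sc > best
    best[upd] <- sc[upd]
    bidx[upd] <- i
  }
  if (!is.null(mask)) {
    best[!mask] <- NA_real_
    bidx[!mask] <- NA_integer_
  }
  structure(list(scores = best, best_orientation = bidx, grid = grid,
                 voxel_size = if (inherits(vol, "volume3d")) vol$voxel_size else 1),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  ok <- !is.na(x$scores)
  cat(sprintf("score_map: %s voxels scored, max %.3f, %d orientations\n",
              format(sum(ok), big.mark = ","),
              if (any(ok)) max(x$scores[ok]) else NA, nrow(x$grid)))
  invisible(x)
}

#' Greedy peak extraction with an exclusion radius
#'
#' Local maxima (26-neighborhood) of the score map above `threshold` are
#' visited in descending score (ties broken by x, then y, then z); each
#' kept peak excludes later peaks closer than `min_distance` voxels.
#'
#' @param scores a `score_map` from [match_template].
#' @param min_distance exclusion radius in voxels (>= 1).
#' @param threshold minimum score.
#' @return A data frame of candidates: `x, y, z` (integer voxels),
#'   `rot, tilt, psi`, `score`, `orientation` (grid row index).
#' @export
extract_peaks <- function(scores, min_distance, threshold) {
  stopifnot(inherits(scores, "score_map"))
  if (min_distance < 1) stop("extract_peaks: min_distance must be >= 1")
  s <- scores$scores
  s[is.na(s)] <- -Inf
  d <- dim(s)
  is_max <- s > threshold
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(offsets != 0) > 0, ]
  shifted <- array(-Inf, d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) + o[k]
      i[i < 1 | i > d[k]] <- NA
      i
    })
    shifted[] <- -Inf
    okx <- !is.na(src[[1]]); oky <- !is.na(src[[2]]); okz <- !is.na(src[[3]])
    shifted[okx, oky, okz] <- s[src[[1]][okx], src[[2]][oky], src[[3]][okz]]
    is_max <- is_max & (s >= shifted)
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      rot = numeric(), tilt = numeric(), psi = numeric(),
                      score = numeric(), orientation = integer()))
  }
  sc <- s[idx]
  oi <- scores$best_orientation[idx]
  ord <- order(-sc, idx[, 1], idx[, 2], idx[, 3], oi)
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]; oi <- oi[ord]
  kept <- integer()
  min_d2 <- min_distance^2
  for (i in seq_len(nrow(idx))) {
    if (length(kept)) {
      d2 <- colSums((t(idx[kept, , drop = FALSE]) - idx[i, ])^2)
      if (min(d2) < min_d2) next
    }
    kept <- c(kept, i)
  }
  g <- scores$grid
  data.frame(x = idx[kept, 1], y = idx[kept, 2], z = idx[kept, 3],
             rot = g$rot[oi[kept]], tilt = g$tilt[oi[kept]],
             psi = g$psi[oi[kept]], score = sc[kept],
             orientation = oi[kept])
}

## binarized rotated-template footprint voxels (absolute, clipped),
## as linear indices into a volume of dim 'd'
candidate_footprint <- function(template, R, center, d, binarize_frac = 0.1) {
  tr <- rotate_volume_array(template, R)
  thr <- binarize_frac * max(template)
  rel <- which(tr >= thr, arr.ind = TRUE)
  ctr <- (dim(template) + 1) / 2
  abs_v <- sweep(rel, 2, ctr) + matrix(round(center), nrow(rel), 3, byrow = TRUE)
  ok <- abs_v[, 1] >= 1 & abs_v[, 1] <= d[1] &
    abs_v[, 2] >= 1 & abs_v[, 2] <= d[2] &
    abs_v[, 3] >= 1 & abs_v[, 3] <= d[3]
  abs_v <- abs_v[ok, , drop = FALSE]
  abs_v[, 1] + d[1] * (abs_v[, 2] - 1) + d[1] * d[2] * (abs_v[, 3] - 1)
}

#' Greedy overlap-exclusion filtering of matched candidates
#'
#' Re-simulates the tomogram occupancy: candidates are visited in
#' descending score (ties by x, y, z, then orientation index); each
#' candidate's binarized rotated-template footprint (>= `binarize_frac`
#' of the template peak) is compared against the voxels already claimed
#' by accepted particles, and the candidate is accepted only if the
#' claimed fraction of its footprint is at most `overlap_threshold`.
#' Accepted footprints are added to the occupancy volume.
#'
#' @param cands data frame from [extract_peaks] (columns x, y, z, rot,
#'   tilt, psi, score; optional orientation).
#' @param template the particle template ([volume3d] or array).
#' @param overlap_threshold maximum claimed footprint fraction in
#'   `[0, 1)`.
#' @param dim volume dimensions (length 3).
#' @param binarize_frac footprint binarization level, fraction of the
#'   template maximum.
#' @return A [particle_table] of accepted particles in visit order, with
#'   attribute `occupancy` (logical array of claimed voxels).
#' @export
overlap_filter <- function(cands, template, overlap_threshold = 0.2, dim,
                           binarize_frac = 0.1) {
  if (overlap_threshold < 0 || overlap_threshold >= 1)
    stop("overlap_filter: overlap_threshold must be in [0, 1)")
  tm <- if (inherits(template, "volume3d")) template$data else template
  oi <- if ("orientation" %in% names(cands)) cands$orientation else
    rep(0L, nrow(cands))
  ord <- order(-cands$score, cands$x, cands$y, cands$z, oi)
  cands <- cands[ord, , drop = FALSE]
  occ <- array(FALSE, dim)
  acc <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    R <- euler_to_matrix(cands$rot[i], cands$tilt[i], cands$psi[i])
    fp <- candidate_footprint(tm, R, c(cands$x[i], cands$y[i], cands$z[i]),
                              dim, binarize_frac)
    if (!length(fp)) next
    if (mean(occ[fp]) <= overlap_threshold) {
      acc[i] <- TRUE
      occ[fp] <- TRUE
    }
  }
  out <- particle_table(x = cands$x[acc], y = cands$y[acc], z = cands$z[acc],
                        rot = cands$rot[acc], tilt = cands$tilt[acc],
                        psi = cands$psi[acc], score = cands$score[acc])
  attr(out, "occupancy") <- occ
  out
}
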