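## ZYZ intrinsic Euler angles, degrees (RELION convention):
## R = Rz(rot) %*% Ry(tilt) %*% Rz(psi), applied to column vectors.

deg2rad <- function(d) d * pi / 180

rot_z <- function(a) {
  a <- deg2rad(a); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- deg2rad(a); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

#' Rotation matrix from ZYZ intrinsic Euler angles (degrees)
#'
#' @param rot,tilt,psi Euler angles in degrees; `R = Rz(rot) Ry(tilt) Rz(psi)`.
#' @return 3 x 3 proper rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
}

## unit quaternion (w,x,y,z) from rotation matrix, for angular distances
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Angular distance between two rotations, degrees
#'
#' @param a,b rotations as ZYZ Euler triples (length-3 numeric) or 3x3
#'   matrices.
#' @return Geodesic angle in degrees, in [0, 180].
#' @export
rotation_distance <- function(a, b) {
  Ra <- if (is.matrix(a)) a else euler_to_matrix(a[1], a[2], a[3])
  Rb <- if (is.matrix(b)) b else euler_to_matrix(b[1], b[2], b[3])
  qa <- matrix_to_quat(Ra); qb <- matrix_to_quat(Rb)
  d <- min(1, abs(sum(qa * qb)))
  2 * acos(d) * 180 / pi
}

#' Near-uniform SO(3) rotation grid
#'
#' Builds a deterministic covering of orientation space at a nominal
#' angular step: tilt rings every `step` degrees, azimuth sampled at
#' `step / sin(tilt)` within each ring, in-plane angle every `step`;
#' near-duplicates (closer than `step / 2`) are then removed greedily in
#' construction order. The identity orientation is always first.
#'
#' @param step nominal angular step in degrees, in (0, 360].
#' @return A data frame of class `rotation_grid` with columns
#'   `rot`, `tilt`, `psi` (degrees) and attribute `step`.
#' @export
make_rotation_grid <- function(step) {
  if (!is.numeric(step) || step <= 0 || step > 360)
    stop("make_rotation_grid: step must be in (0, 360]")
  tilts <- seq(0, 180, by = min(step, 180))
  if (tilts[length(tilts)] != 180) tilts <- c(tilts, 180)
  ang <- do.call(rbind, lapply(tilts, function(th) {
    n_phi <- max(1L, ceiling(360 * sin(deg2rad(th)) / step))
    phis <- seq(0, 360, length.out = n_phi + 1L)[seq_len(n_phi)]
    psis <- seq(0, 360, by = min(step, 360))
    psis <- psis[psis < 360]
    expand.grid(psi = psis, rot = phis, tilt = th)[, c("rot", "tilt", "psi")]
  }))
  ## put identity first, then original order
  id_row <- which(ang$rot == 0 & ang$tilt == 0 & ang$psi == 0)[1]
  ang <- rbind(ang[id_row, ], ang[-id_row, ])
  ## greedy dedup at step/2 via quaternions
  quats <- t(vapply(seq_len(nrow(ang)), function(i)
    matrix_to_quat(euler_to_matrix(ang$rot[i], ang$tilt[i], ang$psi[i])),
    numeric(4)))
  cos_thr <- cos(deg2rad(step / 2) / 2)
  keep <- logical(nrow(ang))
  kept_q <- matrix(0, nrow(ang), 4)
  n_kept <- 0L
  for (i in seq_len(nrow(ang))) {
    if (n_kept == 0L ||
        all(abs(kept_q[seq_len(n_kept), , drop = FALSE] %*% quats[i, ]) < cos_thr)) {
      keep[i] <- TRUE
      n_kept <- n_kept + 1L
      kept_q[n_kept, ] <- quats[i, ]
    }
  }
  out <- ang[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, step = step, class = c("rotation_grid", "data.frame"))
}

#' @export
print.rotation_grid <- function(x, ...) {
  cat(sprintf("rotation_grid: %d orientations at nominal step %g deg\n",
              nrow(x), attr(x, "step")))
  invisible(x)
}

grid_matrices <- function(grid) {
  lapply(seq_len(nrow(grid)), function(i)
    euler_to_matrix(grid$rot[i], grid$tilt[i], grid$psi[i]))
}

## quaternion of a ZYZ orientation (for grid neighborhood queries)
ciliacoat_quat <- function(rot, tilt, psi) {
  matrix_to_quat(euler_to_matrix(rot, tilt, psi))
}
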