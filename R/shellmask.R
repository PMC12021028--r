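## exact Euclidean distance from points to a closed polygon boundary
dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), ]
  best <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  for (i in seq_len(n)) {
    ax <- a[i, 1]; ay <- a[i, 2]
    vx <- b[i, 1] - ax; vy <- b[i, 2] - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- dx * dx + dy * dy
    best <- pmin(best, d2)
  }
  sqrt(best)
}

## one slice of the shell: classify pixels of an nx x ny grid
## returns logical matrix: outside the polygon AND distance in [din, dout]
## (distances in voxels). Uses a distance transform for the bulk and
## exact polygon distances near the two thresholds and near the curve.
shell_slice <- function(poly, nx, ny, din, dout, exact_margin = 2.5) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ext <- if (is.finite(dout)) dout + 2 else max(nx, ny)
  x0 <- max(1L, floor(xr[1] - ext)); x1 <- min(nx, ceiling(xr[2] + ext))
  y0 <- max(1L, floor(yr[1] - ext)); y1 <- min(ny, ceiling(yr[2] + ext))
  out <- matrix(FALSE, nx, ny)
  if (x0 > x1 || y0 > y1) return(out)
  gx <- x0:x1; gy <- y0:y1
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- pracma::inpolygon(G[, 1], G[, 2], poly[, 1], poly[, 2])
  ins_m <- matrix(inside, length(gx), length(gy))
  ## distance of outside pixels to the inside region (approximate)
  dm <- EBImage::distmap(EBImage::Image(1 - ins_m))
  dmv <- as.numeric(dm@.Data)
  cls <- !inside & dmv >= din & dmv <= dout
  ## exact refinement near the thresholds (distmap is pixel-quantized)
  near <- !inside & (abs(dmv - din) <= exact_margin |
                       (is.finite(dout) & abs(dmv - dout) <= exact_margin))
  if (any(near)) {
    de <- dist_to_polygon(G[near, , drop = FALSE], poly)
    cls[near] <- de >= din & de <= dout
  }
  out[gx, gy] <- matrix(cls, length(gx), length(gy))
  out
}

#' Rasterize the coat band between two membrane offsets
#'
#' For each slice in the fitted range of the tube model, the interpolated
#' membrane contour is rasterized and every voxel outside it whose
#' unsigned Euclidean distance to the contour lies in `[d_in, d_out]`
#' (Angstrom) is marked. Voxels inside the membrane contour are never
#' marked. The offset is computed with a distance transform refined by
#' exact point-to-polygon distances near the band edges, so it is robust
#' for concave contours where naive normal displacement self-intersects.
#'
#' @param tube a [build_tube] model (slices along z). A single
#'   `closed_contour` is also accepted and applied to every slice.
#' @param d_in,d_out band offsets in Angstrom, `0 <= d_in < d_out`;
#'   `d_out = Inf` gives the half-space mode (everything beyond `d_in`).
#' @param shape volume dimensions `c(nx, ny, nz)`.
#' @param voxel_size Angstrom per voxel.
#' @return An object of class `shell_mask`: list with `mask` (logical
#'   array), `d_in`, `d_out`, `voxel_size`.
#' @export
build_shell_mask <- function(tube, d_in, d_out, shape, voxel_size = 1) {
  if (d_in < 0 || d_in >= d_out)
    stop("build_shell_mask: need 0 <= d_in < d_out")
  shape <- as.integer(shape)
  din_v <- d_in / voxel_size
  dout_v <- d_out / voxel_size
  mask <- array(FALSE, shape)
  if (inherits(tube, "closed_contour")) {
    poly <- contour_resample(tube, 256L)
    sl <- shell_slice(poly, shape[1], shape[2], din_v, dout_v)
    for (z in seq_len(shape[3])) mask[, , z] <- sl
  } else {
    stopifnot(inherits(tube, "tube_model"))
    z0 <- max(1L, ceiling(min(tube$slices)))
    z1 <- min(shape[3], floor(max(tube$slices)))
    for (z in z0:z1) {
      poly <- tube_contour_at(tube, z)
      mask[, , z] <- shell_slice(poly, shape[1], shape[2], din_v, dout_v)
    }
  }
  structure(list(mask = mask, d_in = d_in, d_out = d_out,
                 voxel_size = voxel_size),
            class = "shell_mask")
}

#' @export
print.shell_mask <- function(x, ...) {
  cat(sprintf("shell_mask: %s voxels in band [%g, %g] A (%g A/voxel)\n",
              format(sum(x$mask), big.mark = ","), x$d_in, x$d_out,
              x$voxel_size))
  invisible(x)
}

#' Fit the shell mask of a tubular phantom from membrane points
#'
#' Convenience wrapper: fits closed contours to per-slice membrane
#' points (data frame with columns `slice`, `x`, `y`), builds the tube
#' and rasterizes the band mask.
#'
#' @param membrane_points data frame with `slice`, `x`, `y` (voxels).
#' @param d_in,d_out band offsets, Angstrom.
#' @param shape volume dimensions.
#' @param voxel_size Angstrom per voxel.
#' @param smoothing spline smoothing passed to [fit_closed_contour].
#' @return A list with `tube` ([build_tube]) and `mask`
#'   ([build_shell_mask]).
#' @export
fit_shell_from_points <- function(membrane_points, d_in, d_out, shape,
                                  voxel_size = 1, smoothing = 0) {
  sp <- split(membrane_points, membrane_points$slice)
  contours <- lapply(sp, function(df)
    fit_closed_contour(cbind(df$x, df$y), smoothing = smoothing,
                       slice = df$slice[1]))
  tube <- build_tube(unname(contours))
  mask <- build_shell_mask(tube, d_in, d_out, shape, voxel_size)
  list(tube = tube, mask = mask)
}
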