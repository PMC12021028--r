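#' Fit a closed periodic spline to membrane points in one slice
#'
#' Points (e.g. clicked membrane positions) are ordered by azimuth about
#' their centroid, optionally smoothed with a circular Gaussian kernel
#' over neighboring points, and interpolated with periodic cubic splines
#' in x and y against normalized arc length. With `smoothing = 0` the
#' curve interpolates the points exactly.
#'
#' @param points n x 2 matrix (x, y) of in-slice voxel coordinates,
#'   n >= 4, not collinear.
#' @param smoothing circular Gaussian kernel sd, in units of point
#'   spacing (0 = interpolate).
#' @param slice optional slice index carried as metadata.
#' @return An object of class `closed_contour`.
#' @export
fit_closed_contour <- function(points, smoothing = 0, slice = NA_integer_) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("fit_closed_contour: need >= 4 points")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  if (svd(cen)$d[2] < 1e-8 * max(svd(cen)$d[1], 1))
    stop("fit_closed_contour: points are collinear")
  ord <- order(atan2(cen[, 2], cen[, 1]))
  p <- points[ord, , drop = FALSE]
  n <- nrow(p)
  if (smoothing > 0) {
    half <- min(n %/% 2, max(1L, ceiling(3 * smoothing)))
    w <- exp(-(seq(-half, half))^2 / (2 * smoothing^2))
    w <- w / sum(w)
    sm <- p
    for (i in seq_len(n)) {
      idx <- ((i - half - 1):(i + half - 1)) %% n + 1L
      sm[i, ] <- colSums(p[idx, , drop = FALSE] * w)
    }
    p <- sm
  }
  structure(list(control = p, centroid = colMeans(p), smoothing = smoothing,
                 slice = slice),
            class = "closed_contour")
}

## periodic spline functions through the control polygon
contour_splines <- function(contour) {
  p <- contour$control
  pc <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  t <- c(0, cumsum(seg)) / sum(seg)
  list(fx = stats::splinefun(t, pc[, 1], method = "periodic"),
       fy = stats::splinefun(t, pc[, 2], method = "periodic"))
}

#' Evaluate a closed contour at arbitrary parameters
#'
#' @param contour a `closed_contour`.
#' @param t parameter values in [0, 1) (periodic).
#' @return length(t) x 2 matrix of (x, y).
#' @export
contour_eval <- function(contour, t) {
  s <- contour_splines(contour)
  t <- t %% 1
  cbind(s$fx(t), s$fy(t))
}

## resample a contour at n points uniformly spaced in arc length,
## starting at azimuth 0 from the centroid, counterclockwise
contour_resample <- function(contour, n = 128L) {
  dense_t <- seq(0, 1, length.out = 2048L + 1L)[-(2048L + 1L)]
  pts <- contour_eval(contour, dense_t)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  ## counterclockwise orientation via the shoelace signed area
  area2 <- sum(pts[, 1] * rel[c(2:nrow(pts), 1), 2] -
                 pts[c(2:nrow(pts), 1), 1] * rel[, 2])
  if (area2 < 0) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    rel <- sweep(pts, 2, ctr)
  }
  az <- atan2(rel[, 2], rel[, 1])
  start <- which.min(abs(az))
  pts <- pts[c(start:nrow(pts), seq_len(start - 1L)), , drop = FALSE]
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  want <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  i <- findInterval(want, arc, rightmost.closed = TRUE)
  frac <- (want - arc[i]) / pmax(seg[i], 1e-12)
  nxt <- i %% nrow(pts) + 1L
  pts[i, ] + (pts[nxt, ] - pts[i, ]) * frac
}

#' Build a tube model from fitted per-slice contours
#'
#' Contours are resampled to a common number of arc-length-uniform
#' points with aligned start points; slices between fitted slices are
#' obtained by linear point-wise interpolation.
#'
#' @param contours list of `closed_contour` with distinct `slice`
#'   indices (>= 2 fitted slices).
#' @param n_points number of resampled points per contour.
#' @return An object of class `tube_model`.
#' @export
build_tube <- function(contours, n_points = 128L) {
  if (length(contours) < 2)
    stop("build_tube: need >= 2 fitted slices; fit and use single contours per slice instead")
  slices <- vapply(contours, function(cc) as.numeric(cc$slice), numeric(1))
  if (any(is.na(slices)) || any(duplicated(slices)))
    stop("build_tube: contours must carry distinct slice indices")
  ord <- order(slices)
  pts <- lapply(contours[ord], contour_resample, n = n_points)
  structure(list(slices = slices[ord], points = pts,
                 n_points = as.integer(n_points)),
            class = "tube_model")
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf("tube_model: %d fitted slices spanning %g..%g, %d points/contour\n",
              length(x$slices), min(x$slices), max(x$slices), x$n_points))
  invisible(x)
}

#' Interpolated contour polygon of a tube model at a slice
#'
#' @param tube a `tube_model`.
#' @param slice slice index within the fitted range.
#' @return n_points x 2 matrix (closed polygon, last->first implicit).
#' @export
tube_contour_at <- function(tube, slice) {
  s <- tube$slices
  if (slice < s[1] || slice > s[length(s)])
    stop("tube_contour_at: slice outside fitted range")
  i <- findInterval(slice, s, rightmost.closed = TRUE)
  if (s[i] == slice) return(tube$points[[i]])
  f <- (slice - s[i]) / (s[i + 1] - s[i])
  tube$points[[i]] * (1 - f) + tube$points[[i + 1]] * f
}

## centroid path of the tube at a slice
tube_center_at <- function(tube, slice) {
  colMeans(tube_contour_at(tube, slice))
}

## brute-force polygon self-intersection test (used by validity checks)
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), ]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}
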