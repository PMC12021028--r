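## FFT cross-correlation helpers shared by the matcher and the simulators.

## fftfreq-style integer frequency index along a dimension of length n
freq_index <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n)
}

## place a small centered box into a zero array of dim 'dim_big' with the
## box center at voxel (1,1,1), wrapped (ifftshift-style), so that FFT
## correlation indexes scores by the template-center position
pad_center <- function(small, dim_big) {
  ds <- dim(small)
  if (any(ds > dim_big)) stop("pad_center: small array larger than target")
  ctr <- (ds + 1L) %/% 2L
  idx <- lapply(1:3, function(k) ((seq_len(ds[k]) - ctr[k]) %% dim_big[k]) + 1L)
  big <- array(0, dim_big)
  big[idx[[1]], idx[[2]], idx[[3]]] <- small
  big
}

## circular cross-correlation: C(p) = sum_m a_centered(m) * b(p + m)
## 'fa_conj' is Conj(fft(pad_center(a, dim(b)))) precomputed by the caller
cross_correlate_fft <- function(fa_conj, fb) {
  Re(stats::fft(fa_conj * fb, inverse = TRUE)) / length(fb)
}

## spherical binary footprint in an odd box matching the template dims
spherical_footprint <- function(dims, radius = NULL) {
  if (is.null(radius)) radius <- min(dims) / 2
  ctr <- (dims + 1) / 2
  x <- seq_len(dims[1]) - ctr[1]
  y <- seq_len(dims[2]) - ctr[2]
  z <- seq_len(dims[3]) - ctr[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(r2 <= radius^2, dims)
}

## trilinear interpolation of a 3D array at continuous points (n x 3,
## 1-based voxel coordinates); zero outside the grid
interp3 <- function(arr, pts) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(pts))
  inside <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
    z0 >= 1 & z0 + 1 <= d[3]
  ## boundary-exact points (e.g. x == d[1]) handled by clamping upper cell
  edge <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] & !inside
  if (any(edge)) {
    x0[edge] <- pmin(x0[edge], d[1] - 1); y0[edge] <- pmin(y0[edge], d[2] - 1)
    z0[edge] <- pmin(z0[edge], d[3] - 1)
    fx[edge] <- x[edge] - x0[edge]; fy[edge] <- y[edge] - y0[edge]
    fz[edge] <- z[edge] - z0[edge]
    inside <- inside | edge
  }
  if (any(inside)) {
    i <- x0[inside]; j <- y0[inside]; k <- z0[inside]
    gx <- fx[inside]; gy <- fy[inside]; gz <- fz[inside]
    at <- function(di, dj, dk)
      arr[cbind(i + di, j + dj, k + dk)]
    val[inside] <-
      at(0, 0, 0) * (1 - gx) * (1 - gy) * (1 - gz) +
      at(1, 0, 0) * gx       * (1 - gy) * (1 - gz) +
      at(0, 1, 0) * (1 - gx) * gy       * (1 - gz) +
      at(1, 1, 0) * gx       * gy       * (1 - gz) +
      at(0, 0, 1) * (1 - gx) * (1 - gy) * gz +
      at(1, 0, 1) * gx       * (1 - gy) * gz +
      at(0, 1, 1) * (1 - gx) * gy       * gz +
      at(1, 1, 1) * gx       * gy       * gz
  }
  val
}

## resample a template under a rotation: out(x) = T(R^-1 (x - c) + c)
rotate_volume_array <- function(arr, R) {
  d <- dim(arr)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  pts <- sweep(g, 2, ctr) %*% R   # (R^-1 v)^T = v^T R for orthonormal R
  pts <- sweep(pts, 2, ctr, "+")
  array(interp3(arr, pts), d)
}

## Gaussian high-pass: subtract a Gaussian-smoothed copy (FFT domain).
## sigma in voxels; sigma = 0 returns the input unchanged.
highpass_array <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  k2 <- outer(outer(freq_index(d[1])^2 / d[1]^2,
                    freq_index(d[2])^2 / d[2]^2, "+"),
              freq_index(d[3])^2 / d[3]^2, "+")
  G <- exp(-2 * pi^2 * sigma^2 * k2)
  arr - Re(stats::fft(stats::fft(arr) * G, inverse = TRUE)) / length(arr)
}
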