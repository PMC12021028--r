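#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' RMSD between paired coordinates, via SVD of the cross-covariance
#' matrix with the standard reflection guard.
#'
#' @param coords_a,coords_b n x 3 matrices of paired points (n >= 3,
#'   not collinear). `coords_b` is rotated onto `coords_a`.
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3; maps centered b onto a as
#'   `a ~ b %*% t(R) + translation`), `rmsd` (Angstrom), `n`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("kabsch_superpose: point sets must be equal-length n x 3")
  if (nrow(A) < 3) stop("kabsch_superpose: need >= 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (max(svd(A0)$d) < 1e-9 || svd(A0)$d[2] < 1e-9 * svd(A0)$d[1])
    stop("kabsch_superpose: degenerate (collinear or coincident) geometry")
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Brot)^2)))
  structure(list(rotation = R, translation = ca - as.numeric(R %*% cb),
                 rmsd = rmsd, n = nrow(A)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, RMSD %.3f A\n", x$n, x$rmsd))
  invisible(x)
}

## RMSD-only fast path (no object construction) used in window scans
kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sv$d
  if (det(sv$v %*% t(sv$u)) < 0) d[3] <- -d[3]
  e <- sum(A0^2) + sum(B0^2) - 2 * sum(d)
  sqrt(max(e, 0) / nrow(A))
}

## trimmed RMSD: one refit on the best 'keep' fraction of pairs
kabsch_rmsd_trimmed <- function(A, B, keep = 0.7) {
  fit <- kabsch_superpose(A, B)
  Brot <- sweep(sweep(B, 2, colMeans(B)) %*% t(fit$rotation), 2,
                colMeans(A), "+")
  dev <- rowSums((A - Brot)^2)
  k <- max(3L, ceiling(keep * nrow(A)))
  idx <- order(dev)[seq_len(k)]
  kabsch_rmsd(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
}
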