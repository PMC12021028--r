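## independent brute-force oracles used across the suite

## greedy non-maximum suppression directly on a score array
oracle_nms <- function(scores, orient, min_distance, threshold) {
  d <- dim(scores)
  cand <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- scores[i, j, k]
    if (is.na(s) || s <= threshold) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      v <- scores[ii, jj, kk]
      if (!is.na(v) && v > s) { ok <- FALSE; break }
    }
    if (ok) cand[[length(cand) + 1]] <- c(i, j, k, s, orient[i, j, k])
  }
  if (!length(cand)) return(matrix(numeric(), 0, 5))
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 4], m[, 1], m[, 2], m[, 3], m[, 5]), , drop = FALSE]
  kept <- matrix(numeric(), 0, 5)
  for (r in seq_len(nrow(m))) {
    if (nrow(kept)) {
      dd <- sqrt(colSums((t(kept[, 1:3, drop = FALSE]) - m[r, 1:3])^2))
      if (min(dd) < min_distance) next
    }
    kept <- rbind(kept, m[r, ])
  }
  kept
}

## literal re-simulation overlap filter: occupancy rebuilt from scratch
## from the accepted list before every candidate is examined
oracle_overlap_filter <- function(cands, template, threshold, dim,
                                  binarize_frac = 0.1) {
  tm <- if (inherits(template, "volume3d")) template$data else template
  oi <- if ("orientation" %in% names(cands)) cands$orientation else
    rep(0L, nrow(cands))
  ord <- order(-cands$score, cands$x, cands$y, cands$z, oi)
  cands <- cands[ord, , drop = FALSE]
  fp_of <- function(i) {
    R <- ciliacoat::euler_to_matrix(cands$rot[i], cands$tilt[i], cands$psi[i])
    ciliacoat:::candidate_footprint(tm, R,
                                    c(cands$x[i], cands$y[i], cands$z[i]),
                                    dim, binarize_frac)
  }
  accepted <- integer()
  for (i in seq_len(nrow(cands))) {
    occ <- array(FALSE, dim)
    for (j in accepted) occ[fp_of(j)] <- TRUE      # from-scratch rebuild
    fp <- fp_of(i)
    if (length(fp) && mean(occ[fp]) <= threshold)
      accepted <- c(accepted, i)
  }
  cands[accepted, , drop = FALSE]
}

## Mann-Whitney two-sided p by enumerating value assignments (not ranks)
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) u_of(pool[idx], pool[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

## exhaustive affine-gap global alignment enumeration: returns the
## optimal score and the set of identities (over alignment length)
## achieved by optimal alignments
oracle_global_align <- function(a, b, sub, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric()
  rec <- function(i, j, score, ident, len, state) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- ident / len
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- unique(c(best$idents, ident / len))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + sub[av[i], bv[j]],
          ident + (av[i] == bv[j]), len + 1, "M")
    }
    if (i <= length(av)) {      # gap in b
      pen <- if (state == "Ix") gap_extend else gap_open + gap_extend
      rec(i + 1, j, score - pen, ident, len + 1, "Ix")
    }
    if (j <= length(bv)) {      # gap in a
      pen <- if (state == "Iy") gap_extend else gap_open + gap_extend
      rec(i, j + 1, score - pen, ident, len + 1, "Iy")
    }
  }
  rec(1, 1, 0, 0, 0, "M")
  list(score = best$score, identities = best$idents * 100)
}

## between-class variance of a 256-bin histogram split, for Otsu checks
oracle_bcv_curve <- function(x, levels = 256) {
  rg <- range(x)
  br <- seq(rg[1], rg[2], length.out = levels + 1)
  h <- hist(x, breaks = br, plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  tot <- sum(cnt)
  vapply(seq_len(levels - 1), function(k) {
    w0 <- sum(cnt[1:k]); w1 <- tot - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    m0 <- sum(cnt[1:k] * mids[1:k]) / w0
    m1 <- sum(cnt[(k + 1):levels] * mids[(k + 1):levels]) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
}

## small tomogram phantom shared by io/coat tests (kept cheap)
small_phantom_spec <- function(seed = 1, noise = 0, wedge = NULL) {
  tomo_phantom_spec(shape = c(64, 64, 64), voxel_size = 10,
                    tube_radius = 100, d_in = 40, d_out = 140,
                    template = default_particle_template(10, 11),
                    n_particles = 6, min_spacing = 140,
                    noise_sigma = noise, wedge = wedge, seed = seed)
}

## thin aliases onto internals used by Monte-Carlo oracles
make_template_fold_pts <- function(n) ciliacoat:::make_template_fold(n)
kabsch_rmsd_mc <- function(A, B) ciliacoat:::kabsch_rmsd(A, B)
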