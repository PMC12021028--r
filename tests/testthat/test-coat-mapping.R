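test_that("rotation grids contain the identity and behave at the extremes", {
  g <- make_rotation_grid(360)
  expect_equal(nrow(g), 1L)
  expect_equal(unlist(g[1, ]), c(rot = 0, tilt = 0, psi = 0))
  expect_error(make_rotation_grid(0), "step")
})

test_that("the 90-degree grid equals the brute-force lattice after dedup", {
  ## oracle: enumerate the full 90-degree ZYZ lattice and remove
  ## duplicate rotations by quaternion distance
  lat <- expand.grid(rot = c(0, 90, 180, 270), tilt = c(0, 90, 180),
                     psi = c(0, 90, 180, 270))
  mats <- lapply(seq_len(nrow(lat)), function(i)
    euler_to_matrix(lat$rot[i], lat$tilt[i], lat$psi[i]))
  uniq <- list()
  for (m in mats) {
    dup <- any(vapply(uniq, function(u) rotation_distance(u, m) < 1e-4,
                      logical(1)))
    if (!dup) uniq[[length(uniq) + 1]] <- m
  }
  g <- make_rotation_grid(90)
  expect_equal(nrow(g), length(uniq))    # the 24 cubic rotations
  expect_equal(nrow(g), 24L)
})

test_that("halving the angular step never decreases the orientation count", {
  steps <- c(180, 90, 45, 22.5)
  counts <- vapply(steps, function(s) nrow(make_rotation_grid(s)), numeric(1))
  expect_true(all(diff(counts) > 0))
  ## grid spacing invariant: no pair closer than step/2
  g <- make_rotation_grid(45)
  n <- nrow(g)
  dmin <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dmin <- min(dmin, rotation_distance(unlist(g[i, ]), unlist(g[j, ])))
  }
  expect_gte(dmin, 45 / 2)
})

test_that("matching finds a planted copy at the exact position and orientation", {
  tmpl <- default_particle_template(10, 11)
  g90 <- make_rotation_grid(90)
  for (ori in c(1L, 9L, 17L)) {
    R <- euler_to_matrix(g90$rot[ori], g90$tilt[ori], g90$psi[ori])
    v <- array(0, c(28, 28, 28))
    v[10:20, 12:22, 8:18] <- ciliacoat:::rotate_volume_array(tmpl$data, R)
    sm <- match_template(volume3d(v, 10), tmpl, grid = g90)
    am <- arrayInd(which.max(sm$scores), dim(sm$scores))
    expect_equal(as.integer(am), c(15L, 17L, 13L))
    expect_gte(max(sm$scores, na.rm = TRUE), 0.999)
    expect_equal(sm$best_orientation[am], ori)
    expect_lte(max(sm$scores, na.rm = TRUE), 1 + 1e-6)
  }
})

test_that("matching validates voxel sizes and template size", {
  tmpl <- default_particle_template(10, 11)
  v <- volume3d(array(0, c(24, 24, 24)), voxel_size = 5)
  expect_error(match_template(v, tmpl, grid = make_rotation_grid(360)),
               "voxel size")
  big <- volume3d(array(0, c(30, 30, 30)), 10)
  small <- volume3d(array(0, c(8, 8, 8)), 10)
  expect_error(match_template(small, big, grid = make_rotation_grid(360)),
               "larger")
})

test_that("masked matching equals unmasked matching restricted to the mask", {
  set.seed(20)
  v <- volume3d(array(rnorm(20^3), c(20, 20, 20)), 10)
  tmpl <- default_particle_template(10, 7)
  g <- make_rotation_grid(120)
  mask <- array(FALSE, c(20, 20, 20))
  mask[5:15, 5:15, 5:15] <- TRUE
  sm_full <- match_template(v, tmpl, grid = g)
  sm_mask <- match_template(v, tmpl, mask = mask, grid = g)
  expect_equal(sm_mask$scores[mask], sm_full$scores[mask])
  expect_true(all(is.na(sm_mask$scores[!mask])))
})

test_that("peak extraction matches the brute-force greedy NMS oracle", {
  set.seed(33)
  for (rep in 1:5) {
    s <- array(runif(16^3), c(16, 16, 16))
    o <- array(sample.int(10, 16^3, replace = TRUE), c(16, 16, 16))
    sm <- structure(list(scores = s, best_orientation = o,
                         grid = make_rotation_grid(90), voxel_size = 1),
                    class = "score_map")
    got <- extract_peaks(sm, min_distance = 3, threshold = 0.7)
    want <- oracle_nms(s, o, 3, 0.7)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(as.matrix(got[, c("x", "y", "z")]),
                   unname(want[, 1:3]), ignore_attr = TRUE)
      expect_equal(got$score, unname(want[, 4]))
    }
  }
})

test_that("close peaks are suppressed and high thresholds empty the list", {
  s <- array(0, c(16, 16, 16))
  s[5, 5, 5] <- 0.9
  s[8, 5, 5] <- 0.8          # 3 voxels away
  sm <- structure(list(scores = s,
                       best_orientation = array(1L, dim(s)),
                       grid = make_rotation_grid(360), voxel_size = 1),
                  class = "score_map")
  pk <- extract_peaks(sm, min_distance = 5, threshold = 0.1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$score, 0.9)
  expect_equal(nrow(extract_peaks(sm, 5, threshold = 0.95)), 0L)
})

test_that("overlap filtering equals the from-scratch re-simulation oracle", {
  set.seed(44)
  tmpl <- default_particle_template(10, 9)
  dimv <- c(24, 24, 24)
  g <- make_rotation_grid(90)
  for (rep in 1:10) {
    n <- 14
    cands <- data.frame(
      x = sample(6:19, n, replace = TRUE),
      y = sample(6:19, n, replace = TRUE),
      z = sample(6:19, n, replace = TRUE),
      orientation = sample.int(nrow(g), n, replace = TRUE),
      score = round(runif(n), 2))     # rounding forces score ties
    cands$rot <- g$rot[cands$orientation]
    cands$tilt <- g$tilt[cands$orientation]
    cands$psi <- g$psi[cands$orientation]
    got <- overlap_filter(cands, tmpl, 0.2, dimv)
    want <- oracle_overlap_filter(cands, tmpl, 0.2, dimv)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$x, want$x)
    expect_equal(got$score, want$score)
  }
})

test_that("overlap filter keeps the best of coincident candidates and all disjoint ones", {
  tmpl <- default_particle_template(10, 9)
  dimv <- c(32, 32, 32)
  co <- data.frame(x = c(10, 10), y = c(10, 10), z = c(10, 10),
                   rot = 0, tilt = 0, psi = 0, score = c(0.9, 0.8))
  out <- overlap_filter(co, tmpl, 0.2, dimv)
  expect_equal(out$score, 0.9)
  far <- data.frame(x = c(6, 16, 26), y = c(6, 16, 26), z = c(6, 16, 26),
                    rot = 0, tilt = 0, psi = 0, score = c(0.1, 0.9, 0.5))
  out2 <- overlap_filter(far, tmpl, 0.0, dimv)
  expect_equal(nrow(out2), 3L)
  expect_equal(out2$score, c(0.9, 0.5, 0.1))   # visit order preserved
  expect_error(overlap_filter(far, tmpl, 1, dimv), "overlap_threshold")
})

test_that("overlap filter output is invariant to input order up to the tie rule", {
  set.seed(55)
  tmpl <- default_particle_template(10, 9)
  dimv <- c(24, 24, 24)
  cands <- data.frame(x = sample(6:19, 12, TRUE), y = sample(6:19, 12, TRUE),
                      z = sample(6:19, 12, TRUE), rot = 0, tilt = 0, psi = 0,
                      score = rep(c(0.8, 0.6, 0.4), each = 4))
  ref <- overlap_filter(cands, tmpl, 0.2, dimv)
  for (rep in 1:5) {
    sh <- cands[sample.int(nrow(cands)), ]
    expect_equal(as.data.frame(overlap_filter(sh, tmpl, 0.2, dimv)),
                 as.data.frame(ref))
  }
})

test_that("accepted particles pairwise overlap at most the threshold", {
  spec <- small_phantom_spec(seed = 12, noise = 0.2,
                             wedge = list(tilt_range = 60, increment = 2))
  ph <- simulate_tomogram(spec)
  sh <- fit_shell_from_points(phantom_membrane_points(spec, 7),
                              spec$d_in, spec$d_out, spec$shape,
                              spec$voxel_size)
  pt <- map_coat(ph$volume, sh$mask, spec$template, angular_step = 40,
                 min_spacing = spec$min_spacing, wedge = spec$wedge)
  expect_gte(nrow(pt), 1)
  thr <- 0.2
  d <- spec$shape
  fps <- lapply(seq_len(nrow(pt)), function(i) {
    R <- euler_to_matrix(pt$rot[i], pt$tilt[i], pt$psi[i])
    ciliacoat:::candidate_footprint(spec$template$data, R,
                                    c(pt$x[i], pt$y[i], pt$z[i]), d)
  })
  if (nrow(pt) > 1) {
    for (i in seq_len(nrow(pt) - 1)) for (j in (i + 1):nrow(pt)) {
      ov <- length(intersect(fps[[i]], fps[[j]])) /
        min(length(fps[[i]]), length(fps[[j]]))
      expect_lte(ov, thr + 1e-9)
    }
  }
})

test_that("coat statistics summarize counts, density and geometry", {
  empty <- particle_table()
  tube <- build_tube(list(
    fit_closed_contour(cbind(32 + 10 * cos(seq(0, 2 * pi, length.out = 17)[-17]),
                             32 + 10 * sin(seq(0, 2 * pi, length.out = 17)[-17])),
                       slice = 1),
    fit_closed_contour(cbind(32 + 10 * cos(seq(0, 2 * pi, length.out = 17)[-17]),
                             32 + 10 * sin(seq(0, 2 * pi, length.out = 17)[-17])),
                       slice = 60)))
  st0 <- coat_statistics(empty, tube, 10)
  expect_equal(st0$count, 0L)
  expect_equal(st0$density_per_um2, 0)

  spec <- small_phantom_spec(seed = 13, noise = 0.1)
  ph <- simulate_tomogram(spec)
  sh <- fit_shell_from_points(phantom_membrane_points(spec, 7),
                              spec$d_in, spec$d_out, spec$shape,
                              spec$voxel_size)
  truth_pt <- particle_table(x = ph$truth$x, y = ph$truth$y, z = ph$truth$z,
                             rot = ph$truth$rot, tilt = ph$truth$tilt,
                             psi = ph$truth$psi,
                             score = rep(1, nrow(ph$truth)))
  st <- coat_statistics(truth_pt, sh$tube, spec$voxel_size)
  expect_equal(st$count, nrow(ph$truth))
  expect_true(all(st$nn_dist_A > 0))
  expect_gt(st$density_per_um2, 0)
  ## phantom orientations point along the outward normal
  expect_lt(max(st$normal_angle_deg), 5)
})
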