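test_that("kymographs render static and moving spots as expected lines", {
  fr <- array(0, c(64, 16, 20))
  fr[30, 8, ] <- 1                        # static bright pixel
  st <- image_stack(fr, 0.16, 0.1)
  ky <- build_kymograph(st, c(1, 8, 64, 8), width = 1)
  expect_true(all(ky$data[, 30] == 1))
  expect_true(all(ky$data[, -30] == 0))

  fr2 <- array(0, c(64, 16, 20))
  for (t in 1:20) fr2[9 + t, 8, t] <- 1   # 1 px / frame
  st2 <- image_stack(fr2, 0.16, 0.1)
  ky2 <- build_kymograph(st2, c(1, 8, 64, 8), width = 1)
  pos <- apply(ky2$data, 1, which.max)
  expect_equal(diff(pos), rep(1, 19))
  expect_error(build_kymograph(st2, c(0, 8, 64, 8)), "ROI")
})

test_that("width projection equals the brute-force per-pixel sampling oracle", {
  set.seed(12)
  fr <- array(runif(48 * 24 * 4), c(48, 24, 4))
  st <- image_stack(fr, 0.16, 0.1)
  roi <- c(4, 12, 44, 12)
  ky <- build_kymograph(st, roi, width = 3)
  for (t in 1:4) {
    for (p in seq_len(ncol(ky$data))) {
      x <- roi[1] + (p - 1)
      want <- max(fr[x, 11:13, t])        # horizontal line: offsets in y
      expect_equal(ky$data[t, p], want)
    }
  }
})

test_that("event tracing recovers planted velocities and distances", {
  truth_v <- c(0.4, 1.2)
  ev <- data.frame(start_frame = c(10, 120),
                   duration_s = c(10, 8),
                   velocity_um_s = truth_v, x0 = c(8, 8), y0 = 24)
  sp <- motility_phantom_spec(shape = c(160, 48), n_frames = 240,
                              events = ev, noise_sigma = 0.03, seed = 2)
  sim <- simulate_motility_movie(sp)
  ky <- build_kymograph(sim$stack, c(2, 24, 158, 24), width = 3)
  tr <- trace_events(ky)
  inc <- tr[tr$included, ]
  expect_equal(nrow(inc), 2L)
  expect_lt(max(abs(sort(inc$velocity_um_s) - sort(truth_v)) / truth_v), 0.05)
  ## distance = velocity x duration for every reported event
  dur <- (tr$end_frame - tr$start_frame) * ky$frame_interval
  expect_equal(tr$distance_um, tr$velocity_um_s * dur, tolerance = 1e-6)
})

test_that("stationary spots are reported but excluded by the velocity rule", {
  ev <- data.frame(start_frame = 5, duration_s = 15, velocity_um_s = 0,
                   x0 = 40, y0 = 16)
  sp <- motility_phantom_spec(shape = c(96, 32), n_frames = 160,
                              events = ev, noise_sigma = 0, seed = 3)
  sim <- simulate_motility_movie(sp)
  tr <- trace_events(build_kymograph(sim$stack, c(2, 16, 94, 16), width = 3))
  expect_equal(nrow(tr), 1L)
  expect_false(tr$included)
  expect_equal(tr$velocity_um_s, 0)
})

test_that("Mann-Whitney separates, sums and matches enumeration oracles", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  ## U_x + U_y = n1 n2 for random samples, with and without ties
  set.seed(4)
  for (rep in 1:10) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 7, replace = TRUE)
    ux <- mann_whitney_u(x, y)$statistic
    uy <- mann_whitney_u(y, x)$statistic
    expect_equal(ux + uy, 35)
  }
  ## exact p equals the value-permutation oracle on tied integer data
  for (rep in 1:10) {
    x <- sample(1:4, 4, replace = TRUE)
    y <- sample(1:4, 4, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_p(x, y))
  }
  ## tie-free exact p agrees with the classical distribution
  set.seed(5)
  x <- rnorm(6); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  expect_error(mann_whitney_u(numeric(), 1:3), "empty")
})

test_that("the normal approximation converges to the exact p at n = 15", {
  set.seed(6)
  x <- rnorm(15); y <- rnorm(15) + 0.6
  approx_p <- mann_whitney_u(x, y)$p_value     # n1 n2 = 225 > 64
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.01)
})

test_that("Otsu binarization maximizes between-class variance", {
  set.seed(7)
  fr <- matrix(c(rnorm(600, 0.2, 0.04), rnorm(200, 0.8, 0.04)), 40, 20)
  st <- image_stack(array(fr, c(40, 20, 1)), 0.16, 1)
  bin <- binarize_frames(st, foreground = "bright")
  thr_fg <- min(fr[bin$frames[, , 1] == 1])
  ## the implied threshold achieves the maximal between-class variance
  bcv <- oracle_bcv_curve(fr)
  rg <- range(fr)
  br <- seq(rg[1], rg[2], length.out = 257)
  k_impl <- findInterval(thr_fg, br, rightmost.closed = TRUE) - 1L
  expect_equal(bcv[k_impl], max(bcv), tolerance = 1e-9)
  ## inversion flips foreground/background consistently
  sti <- image_stack(array(-fr, c(40, 20, 1)), 0.16, 1)
  bini <- binarize_frames(sti, foreground = "dark")
  expect_equal(bini$frames, bin$frames)
  ## constant frames go to background with a warning
  stz <- image_stack(array(0, c(8, 8, 2)), 0.16, 1)
  expect_warning(bz <- binarize_frames(stz), "constant")
  expect_true(all(bz$frames == 0))
})

test_that("detachment curves normalize, step and respect the schedule", {
  ## half the cells vanish at t = 100 s
  fr <- array(1, c(40, 40, 60))
  fr[1:10, 1:40, ] <- 0                       # permanent cells (dark)
  fr[21:30, 1:40, 1:32] <- 0                  # cells leaving at frame 33
  st <- image_stack(fr, 0.16, 3.125)          # frame 33 -> t = 100 s
  bin <- binarize_frames(st, foreground = "dark")
  dc <- detachment_curve(bin)
  expect_equal(dc$value[1], 1)
  expect_equal(dc$value[60], 0.5)
  expect_equal(unique(dc$value), c(1, 0.5))
  ## schedule annotation: t = 0 is step 1, t = 100 s is step 4
  expect_equal(dc$step[1], 1L)
  expect_equal(dc$step[dc$time_s == 100], 4L)
  ## no cells leaving: constant 1
  fr2 <- array(1, c(20, 20, 10)); fr2[1:5, , ] <- 0
  dc2 <- detachment_curve(binarize_frames(image_stack(fr2, 0.16, 1),
                                          foreground = "dark"))
  expect_true(all(dc2$value == 1))
  ## empty first frame cannot be normalized
  fr3 <- array(1, c(20, 20, 5))
  bin3 <- image_stack(array(0, c(20, 20, 5)), 0.16, 1)
  expect_error(detachment_curve(bin3), "frame-0")
})

test_that("detachment curves are invariant to uniform intensity rescaling", {
  cells <- random_cell_field(20, c(128, 48), seed = 8)
  sp <- motility_phantom_spec(shape = c(128, 48), n_frames = 100,
                              frame_interval = 2, cells = cells,
                              detach_prob = c(0.05, 0.1, 0.15, 0.2,
                                              0.25, 0.3, 0.2),
                              fg = 0, bg = 1, noise_sigma = 0.02, seed = 8)
  sim <- simulate_detachment_movie(sp)
  dc1 <- detachment_curve(binarize_frames(sim$stack, "dark"))
  resc <- sim$stack
  resc$frames <- round(resc$frames * 4000) + 100   # rescaled integer movie
  dc2 <- detachment_curve(binarize_frames(resc, "dark"))
  expect_equal(dc2$value, dc1$value)
})

test_that("flow schedule validates its invariants and annotates steps", {
  fs <- flow_schedule()
  expect_equal(nrow(fs), 7L)
  expect_equal(fs$flow_ml_min[c(1, 7)], c(3.77, 51.94))
  expect_equal(fs$duration_s[1], 25)
  expect_error(flow_schedule(flow_ml_min = c(2, 1, 3),
                             pressure_mbar = c(1, 2, 3),
                             duration_s = c(10, 10, 10)), "increasing")
  expect_error(flow_schedule(flow_ml_min = c(1, 2), pressure_mbar = c(1, 2),
                             duration_s = c(0, 10)), "positive")
})

test_that("curve comparison matches the closed-form Student t", {
  a <- list(data.frame(time_s = c(0, 300), value = c(1, 0.84)),
            data.frame(time_s = c(0, 300), value = c(1, 0.80)),
            data.frame(time_s = c(0, 300), value = c(1, 0.88)))
  b <- list(data.frame(time_s = c(0, 300), value = c(1, 0.70)),
            data.frame(time_s = c(0, 300), value = c(1, 0.74)),
            data.frame(time_s = c(0, 300), value = c(1, 0.66)))
  res <- compare_curves(a, b, timepoints = c(150, 200))
  ## closed form at t = 150 s (linear interpolation of each curve)
  va <- vapply(a, function(c_) approx(c_$time_s, c_$value, 150)$y, numeric(1))
  vb <- vapply(b, function(c_) approx(c_$time_s, c_$value, 150)$y, numeric(1))
  sp2 <- ((3 - 1) * var(va) + (3 - 1) * var(vb)) / 4
  t_manual <- (mean(va) - mean(vb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_manual <- 2 * stats::pt(-abs(t_manual), 4)
  expect_equal(res$t[1], t_manual, tolerance = 1e-10)
  expect_equal(res$p_value[1], p_manual, tolerance = 1e-10)
  ## identical groups: t = 0, p = 1; swapping flips the sign only
  same <- compare_curves(a, a, timepoints = 150)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  sw <- compare_curves(b, a, timepoints = 150)
  expect_equal(sw$t[1], -res$t[1])
  expect_equal(sw$p_value[1], res$p_value[1])
  expect_error(compare_curves(a, b, timepoints = 400), "not defined")
  expect_error(compare_curves(a[1], b, 150), "replicates")
})
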