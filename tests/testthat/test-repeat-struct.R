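test_that("Kabsch recovers exact transforms and guards reflections", {
  set.seed(3)
  A <- matrix(rnorm(60), 20, 3)
  fit0 <- kabsch_superpose(A, A)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  R30 <- euler_to_matrix(0, 0, 30)
  B <- A %*% t(R30)
  B <- sweep(B, 2, c(5, -2, 1), "+")
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation %*% R30, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  Bm <- A; Bm[, 1] <- -Bm[, 1]              # mirror image
  fitm <- kabsch_superpose(A, Bm)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0)

  expect_error(kabsch_superpose(A, A[1:10, ]), "equal-length")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch RMSD lower-bounds random rigid probes", {
  set.seed(9)
  A <- matrix(rnorm(45), 15, 3)
  B <- A %*% t(euler_to_matrix(20, 35, 70)) + 0.3 * matrix(rnorm(45), 15, 3)
  best <- kabsch_superpose(A, B)$rmsd
  for (i in 1:25) {
    R <- euler_to_matrix(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360))
    Bp <- sweep(sweep(B, 2, colMeans(B)) %*% t(R), 2, colMeans(A), "+")
    expect_gte(sqrt(mean(rowSums((A - Bp)^2))), best - 1e-9)
  }
})

test_that("synthetic chains segment to the exact count and boundaries", {
  for (k in c(3, 5)) {
    sp <- repeat_chain_spec(n_repeats = k, pairwise_identity = 22,
                            coord_noise = 0.3, seed = k)
    ch <- simulate_repeat_chain(sp)
    seg <- segment_repeats(ch$model)
    expect_equal(nrow(seg), k)
    expect_lte(max(abs(seg$start - ch$boundaries$start)), 5)
    expect_lte(max(abs(seg$end - ch$boundaries$end)), 5)
  }
  ## short chains yield an empty result with a diagnostic
  sp2 <- repeat_chain_spec(n_repeats = 1, template_length = 40,
                           invariant_positions = c(10, 30),
                           pairwise_identity = 50, seed = 1)
  ch2 <- simulate_repeat_chain(sp2)
  seg2 <- segment_repeats(ch2$model, min_len = 90, max_len = 130)
  expect_equal(nrow(seg2), 0L)
  expect_match(attr(seg2, "diagnostic"), "shorter")
})

test_that("segmentation is idempotent under its own seed hint", {
  sp <- repeat_chain_spec(n_repeats = 5, pairwise_identity = 22,
                          coord_noise = 0.4, seed = 17)
  ch <- simulate_repeat_chain(sp)
  seg <- segment_repeats(ch$model)
  seg2 <- segment_repeats(ch$model,
                          seed_hint = c(seg$start[1], seg$end[1]))
  expect_equal(seg2$start, seg$start)
  expect_equal(seg2$end, seg$end)
})

test_that("boundary accuracy does not improve with added coordinate noise", {
  errs <- vapply(c(0, 0.5, 2.5), function(ns) {
    sp <- repeat_chain_spec(n_repeats = 5, pairwise_identity = 22,
                            coord_noise = ns, seed = 21)
    ch <- simulate_repeat_chain(sp)
    seg <- segment_repeats(ch$model)
    if (nrow(seg) != 5) return(Inf)
    max(abs(seg$start - ch$boundaries$start))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("RMSD matrices are symmetric, zero-diagonal and track the noise", {
  sp <- repeat_chain_spec(n_repeats = 5, pairwise_identity = 100,
                          coord_noise = 0, seed = 5)
  ch <- simulate_repeat_chain(sp)
  seg <- segment_repeats(ch$model)
  m <- pairwise_rmsd_matrix(ch$model, seg)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 5))
  expect_lt(max(m), 1e-6)

  ## noise-implied expectation by Monte Carlo on the generator
  sp2 <- repeat_chain_spec(n_repeats = 6, pairwise_identity = 22,
                          coord_noise = 0.5, seed = 6)
  ch2 <- simulate_repeat_chain(sp2)
  seg2 <- segment_repeats(ch2$model)
  m2 <- pairwise_rmsd_matrix(ch2$model, seg2)
  set.seed(100)
  mc <- replicate(40, {
    X <- make_template_fold_pts(110)
    kabsch_rmsd_mc(X + matrix(rnorm(330, 0, 0.5), 110, 3),
                   X + matrix(rnorm(330, 0, 0.5), 110, 3))
  })
  expect_lt(abs(mean(m2[upper.tri(m2)]) - mean(mc)), 0.5)
})

test_that("structure-guided alignment recovers planted conserved columns", {
  sp <- repeat_chain_spec(n_repeats = 6, pairwise_identity = 22,
                          coord_noise = 0.4, seed = 31)
  ch <- simulate_repeat_chain(sp)
  seg <- segment_repeats(ch$model)
  msa <- structure_guided_msa(ch$model, seg)
  expect_equal(nrow(msa$rows), nrow(seg))
  expect_identical(find_conserved_columns(msa, "C", 1), c(60L, 91L))
  ## frequencies sum to one over non-gap letters in occupied columns
  occ <- colSums(msa$rows != "-") > 0
  expect_equal(unname(colSums(msa$frequencies)[occ]),
               rep(1, sum(occ)), tolerance = 1e-9)
  ## min_frequency 0 returns every column containing the residue
  some <- find_conserved_columns(msa, "A", 0)
  expect_true(all(vapply(some, function(j) any(msa$rows[, j] == "A"),
                         logical(1))))
})

test_that("identical noiseless repeats align gap-free", {
  sp <- repeat_chain_spec(n_repeats = 4, pairwise_identity = 100,
                          coord_noise = 0, seed = 41)
  ch <- simulate_repeat_chain(sp)
  seg <- segment_repeats(ch$model)
  msa <- structure_guided_msa(ch$model, seg)
  expect_false(any(msa$rows == "-"))
  expect_true(all(apply(msa$rows, 2, function(col) length(unique(col)) == 1)))
})

test_that("disulfide detection matches the exhaustive greedy oracle", {
  set.seed(51)
  for (rep in 1:6) {
    n <- 12
    resid <- rep("CYS", n)
    ca <- matrix(runif(3 * n, 0, 12), n, 3)
    sg <- ca + matrix(rnorm(3 * n, 0, 0.8), n, 3)
    m <- structure_model("A", resid, ca, sg = sg)
    got <- detect_disulfides(m, cutoff = 2.5)
    ## oracle: all pairs, closest-first, each Cys at most once
    pr <- t(utils::combn(n, 2))
    d <- sqrt(rowSums((sg[pr[, 1], ] - sg[pr[, 2], ])^2))
    keep <- order(d)
    used <- logical(n); bonds <- list()
    for (r in keep) {
      if (d[r] > 2.5) break
      a <- pr[r, 1]; b <- pr[r, 2]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      bonds[[length(bonds) + 1]] <- c(a, b, d[r])
    }
    expect_equal(nrow(got), length(bonds))
    if (length(bonds)) {
      want <- do.call(rbind, bonds)
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got$res_i, as.integer(want[, 1]))
      expect_equal(got$distance, want[, 3])
    }
  }
  ## fixed small cases
  two <- structure_model("A", c("CYS", "CYS"),
                         rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))[1:2, ],
                         sg = rbind(c(0, 0, 0), c(2.05, 0, 0)))
  expect_equal(nrow(detect_disulfides(two, 2.5)), 1L)
  two$sg[2, 1] <- 3.5
  expect_equal(nrow(detect_disulfides(two, 2.5)), 0L)
})

test_that("every simulated repeat carries exactly one internal disulfide", {
  sp <- repeat_chain_spec(n_repeats = 5, pairwise_identity = 22,
                          coord_noise = 0.3, seed = 61)
  ch <- simulate_repeat_chain(sp)
  bonds <- detect_disulfides(ch$model)
  expect_equal(nrow(bonds), 5L)
  b <- ch$boundaries
  for (i in seq_len(5)) {
    inside <- bonds$res_i >= b$start[i] & bonds$res_j <= b$end[i]
    expect_equal(sum(inside), 1L)
  }
})

test_that("global identity handles exact cases and rejects bad symbols", {
  expect_equal(as.numeric(global_identity(strrep("ACDKW", 2),
                                          strrep("ACDKW", 2))), 100)
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHIKV"          # one substitution, alignment stays gap-free
  expect_equal(as.numeric(global_identity(a, b)), 90)
  expect_error(global_identity("ACDX1", "ACD"), "symbol")
  expect_error(global_identity("", "ACD"), "empty")
})

test_that("alignment score and identity agree with exhaustive enumeration", {
  set.seed(71)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62")
  for (rep in 1:6) {
    a <- paste(sample(c("A", "C", "D", "W", "K", "G"),
                      sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "W", "K", "G"),
                      sample(3:6, 1), replace = TRUE), collapse = "")
    got <- global_identity(a, b)
    want <- oracle_global_align(a, b, sub, 10, 0.5)
    expect_equal(attr(got, "score"), want$score, tolerance = 1e-9)
    expect_true(any(abs(want$identities - as.numeric(got)) < 1e-9))
  }
})

test_that("repeat statistics report counts, lengths and identities", {
  sp <- repeat_chain_spec(n_repeats = 5, pairwise_identity = 100,
                          coord_noise = 0, seed = 81)
  ch <- simulate_repeat_chain(sp)
  seg <- segment_repeats(ch$model)
  msa <- structure_guided_msa(ch$model, seg)
  st <- repeat_stats(seg, msa)
  expect_equal(st$count, 5)
  expect_equal(st$mean_length, 110)
  expect_equal(st$sd_length, 0)
  expect_equal(st$mean_pairwise_identity, 100)

  sp2 <- repeat_chain_spec(n_repeats = 6, pairwise_identity = 22,
                           coord_noise = 0.4, seed = 82)
  ch2 <- simulate_repeat_chain(sp2)
  seg2 <- segment_repeats(ch2$model)
  st2 <- repeat_stats(seg2, structure_guided_msa(ch2$model, seg2))
  expect_lt(abs(st2$mean_pairwise_identity - 22), 3)
})
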