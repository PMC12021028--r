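#' Segment a chain model into structural repeats
#'
#' The paper-style repeat count and boundaries are found by a
#' deterministic seed-and-scan procedure: a seed window (user hint, or
#' the window whose trimmed-RMSD matches the most other windows) is
#' slid along the chain, every start position is scored by trimmed
#' Kabsch RMSD against the seed, local minima at or below the cutoff
#' become candidate repeats, and a dynamic program picks the maximal
#' non-overlapping set (ties resolved by total RMSD). All segments
#' share the seed length.
#'
#' @param model a [structure_model].
#' @param seed_hint optional `c(start, end)` residue range to use as
#'   the seed domain.
#' @param min_len,max_len admissible domain lengths; the seed length is
#'   their midpoint when no hint is given.
#' @param rmsd_cutoff acceptance cutoff (Angstrom) on the trimmed RMSD
#'   over at least `keep_frac` of the seed residues.
#' @param keep_frac fraction of seed residues the trimmed RMSD is
#'   computed over.
#' @return Data frame of class `domain_segments` with columns `start`,
#'   `end`, `rmsd_to_seed`; attribute `seed` holds the seed window.
#'   Empty (with attribute `diagnostic`) when no repeats are found.
#' @export
segment_repeats <- function(model, seed_hint = NULL, min_len = 90,
                            max_len = 130, rmsd_cutoff = 3.5,
                            keep_frac = 0.7) {
  ca <- model$ca
  n <- nrow(ca)
  empty <- function(msg) {
    out <- data.frame(start = integer(), end = integer(),
                      rmsd_to_seed = numeric())
    attr(out, "diagnostic") <- msg
    class(out) <- c("domain_segments", "data.frame")
    out
  }
  if (n < min_len) return(empty("chain shorter than min_len"))
  if (!is.null(seed_hint)) {
    seed_start <- seed_hint[1]
    L0 <- seed_hint[2] - seed_hint[1] + 1L
  } else {
    L0 <- as.integer(round((min_len + max_len) / 2))
    if (n < L0) return(empty("chain shorter than the seed window"))
    starts <- seq(1L, n - L0 + 1L, by = 5L)
    support <- vapply(starts, function(s) {
      others <- starts[abs(starts - s) >= L0]
      if (!length(others)) return(0L)
      sum(vapply(others, function(t)
        kabsch_rmsd_trimmed(ca[s:(s + L0 - 1), ], ca[t:(t + L0 - 1), ],
                            keep_frac) <= rmsd_cutoff, logical(1)))
    }, integer(1))
    if (max(support) == 0L)
      return(empty("no self-similar seed window found"))
    seed_start <- starts[which.max(support)]
  }
  seed <- ca[seed_start:(seed_start + L0 - 1L), , drop = FALSE]
  starts_all <- seq_len(n - L0 + 1L)
  r <- vapply(starts_all, function(t)
    kabsch_rmsd_trimmed(seed, ca[t:(t + L0 - 1L), , drop = FALSE],
                        keep_frac), numeric(1))
  ## local minima at or below the cutoff
  is_min <- r <= rmsd_cutoff &
    r <= c(Inf, r[-length(r)]) & r <= c(r[-1], Inf)
  hits <- which(is_min)
  if (!length(hits)) return(empty("no windows within the RMSD cutoff"))
  ## drop plateau duplicates closer than 3 residues
  hits <- hits[c(TRUE, diff(hits) >= 3)]
  ## DP: maximize segment count, then minimize total RMSD
  m <- length(hits)
  best_cnt <- integer(m); best_cost <- numeric(m); prev <- integer(m)
  for (i in seq_len(m)) {
    best_cnt[i] <- 1L; best_cost[i] <- r[hits[i]]; prev[i] <- 0L
    js <- which(hits + L0 <= hits[i])
    if (length(js)) {
      cand_cnt <- best_cnt[js] + 1L
      cand_cost <- best_cost[js] + r[hits[i]]
      o <- order(-cand_cnt, cand_cost)[1]
      best_cnt[i] <- cand_cnt[o]; best_cost[i] <- cand_cost[o]
      prev[i] <- js[o]
    }
  }
  i <- order(-best_cnt, best_cost)[1]
  chain <- integer()
  while (i > 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  out <- data.frame(start = hits[chain],
                    end = hits[chain] + L0 - 1L,
                    rmsd_to_seed = r[hits[chain]])
  rownames(out) <- NULL
  attr(out, "seed") <- c(seed_start, seed_start + L0 - 1L)
  class(out) <- c("domain_segments", "data.frame")
  out
}

segment_coords <- function(model, seg) {
  model$ca[seg[1]:seg[2], , drop = FALSE]
}

## sequence-monotone residue pairing by dynamic programming: maximizes
## the summed (cutoff - distance) over order-respecting pairs closer
## than the cutoff. Returns an integer vector over reference columns
## with the paired segment-residue offset (NA = gap).
monotone_pairing <- function(dmat, cutoff) {
  n <- nrow(dmat); L <- ncol(dmat)
  w <- cutoff - dmat
  w[w <= 0] <- -Inf
  f <- matrix(0, n + 1, L + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      m <- if (is.finite(w[i, j])) f[i, j] + w[i, j] else -Inf
      f[i + 1, j + 1] <- max(f[i, j + 1], f[i + 1, j], m)
    }
  }
  out <- rep(NA_integer_, L)
  i <- n; j <- L
  while (i > 0 && j > 0) {
    if (is.finite(w[i, j]) &&
        abs(f[i + 1, j + 1] - (f[i, j] + w[i, j])) < 1e-12) {
      out[j] <- i
      i <- i - 1; j <- j - 1
    } else if (f[i + 1, j + 1] == f[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  out
}

## per-segment map from reference columns to model residue indices:
## superpose each segment on the reference over the common length, then
## pair residues monotonically by CA distance
segment_column_map <- function(model, segments, reference = 1,
                               max_pair_dist = 5) {
  k <- nrow(segments)
  ref <- as.integer(segments[reference, c("start", "end")])
  ref_ca <- segment_coords(model, ref)
  L <- nrow(ref_ca)
  colmap <- matrix(NA_integer_, k, L)
  failed <- logical(k)
  for (i in seq_len(k)) {
    seg <- as.integer(segments[i, c("start", "end")])
    ca <- segment_coords(model, seg)
    nc <- min(nrow(ca), L)
    fit <- tryCatch(kabsch_superpose(ref_ca[seq_len(nc), ],
                                     ca[seq_len(nc), ]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed[i] <- TRUE
      next
    }
    moved <- sweep(sweep(ca, 2, colMeans(ca[seq_len(nc), ])) %*%
                     t(fit$rotation), 2,
                   colMeans(ref_ca[seq_len(nc), ]), "+")
    d2 <- outer(rowSums(moved^2), rep(1, L)) +
      outer(rep(1, nrow(moved)), rowSums(ref_ca^2)) -
      2 * moved %*% t(ref_ca)
    pair <- monotone_pairing(sqrt(pmax(d2, 0)), max_pair_dist)
    hit <- which(!is.na(pair))
    colmap[i, hit] <- seg[1] + pair[hit] - 1L
  }
  attr(colmap, "failed") <- failed
  colmap
}

#' Structure-guided alignment of repeat segments
#'
#' Each segment is superposed onto the reference segment (Kabsch on the
#' index correspondence over the common length); its residues are then
#' assigned to reference columns by sequence-monotone CA pairing closer
#' than `max_pair_dist` (a dynamic program maximizing summed pairing
#' quality, so the register cannot cross over); unassigned columns are
#' gapped. Columns are numbered 1-based along the reference segment.
#'
#' @param model a [structure_model].
#' @param segments a [segment_repeats] result (or data frame with
#'   `start`, `end`).
#' @param reference index of the reference segment.
#' @param max_pair_dist CA pairing cutoff, Angstrom.
#' @return Object of class `structure_msa`: list with `rows` (k x L
#'   character matrix, `-` for gaps), `frequencies` (20 x L, summing to
#'   1 over non-gap letters per column), `reference`.
#' @export
structure_guided_msa <- function(model, segments, reference = 1,
                                 max_pair_dist = 5) {
  k <- nrow(segments)
  if (k < 1) stop("structure_guided_msa: no segments")
  colmap <- segment_column_map(model, segments, reference, max_pair_dist)
  if (any(attr(colmap, "failed")))
    warning("structure_guided_msa: segment(s) ",
            paste(which(attr(colmap, "failed")), collapse = ", "),
            " failed superposition; all-gap rows")
  L <- ncol(colmap)
  seq1 <- aa321(model$resid)
  rows <- matrix("-", k, L)
  for (i in seq_len(k)) {
    hit <- which(!is.na(colmap[i, ]))
    rows[i, hit] <- seq1[colmap[i, hit]]
  }
  freq <- vapply(seq_len(L), function(j) {
    v <- rows[, j]
    v <- v[v != "-"]
    tab <- table(factor(v, levels = aa_one))
    if (length(v)) as.numeric(tab) / length(v) else rep(0, 20)
  }, numeric(20))
  rownames(freq) <- aa_one
  structure(list(rows = rows, frequencies = freq, reference = reference),
            class = "structure_msa")
}

#' @export
print.structure_msa <- function(x, ...) {
  cat(sprintf("structure_msa: %d rows x %d columns (reference segment %d)\n",
              nrow(x$rows), ncol(x$rows), x$reference))
  invisible(x)
}

#' All-vs-all CA RMSD matrix over repeat segments
#'
#' Pairs are superposed by Kabsch on the residue correspondence induced
#' by the structure-guided alignment (columns where both segments are
#' non-gapped). Entries with fewer than 3 aligned residues are NA.
#'
#' @param model a [structure_model].
#' @param segments a [segment_repeats] result.
#' @param msa optional precomputed [structure_guided_msa]; built on
#'   demand otherwise.
#' @return k x k symmetric numeric matrix with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(model, segments, msa = NULL) {
  k <- nrow(segments)
  if (k < 2) stop("pairwise_rmsd_matrix: need >= 2 segments")
  reference <- if (is.null(msa)) 1 else msa$reference
  colmap <- segment_column_map(model, segments, reference)
  out <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      both <- which(!is.na(colmap[i, ]) & !is.na(colmap[j, ]))
      if (length(both) < 3) {
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      rmsd <- kabsch_rmsd(model$ca[colmap[i, both], , drop = FALSE],
                          model$ca[colmap[j, both], , drop = FALSE])
      out[i, j] <- out[j, i] <- rmsd
    }
  }
  out
}

#' Columns conserved for a given residue in a structure alignment
#'
#' @param msa a [structure_guided_msa] result.
#' @param residue one-letter residue code (default Cys).
#' @param min_frequency minimum non-gap frequency of the residue.
#' @return Integer vector of 1-based column indices.
#' @export
find_conserved_columns <- function(msa, residue = "C", min_frequency = 1) {
  if (min_frequency > 1) stop("find_conserved_columns: min_frequency > 1")
  if (!ncol(msa$rows)) return(integer())
  f <- msa$frequencies[toupper(residue), ]
  which(f >= min_frequency & f > 0)
}

#' Detect disulfide bonds from Cys SG coordinates
#'
#' All Cys-Cys pairs with SG-SG distance at or below the cutoff are
#' considered; pairs are accepted closest-first with each Cys in at
#' most one bond.
#'
#' @param model a [structure_model] carrying SG coordinates.
#' @param cutoff SG-SG distance cutoff, Angstrom.
#' @return Data frame: `res_i`, `res_j` (sequential residue numbers),
#'   `distance` (Angstrom).
#' @export
detect_disulfides <- function(model, cutoff = 2.5) {
  cys <- which(model$resid == "CYS" & is.finite(model$sg[, 1]))
  out <- data.frame(res_i = integer(), res_j = integer(),
                    distance = numeric())
  if (length(cys) < 2) return(out)
  sg <- model$sg[cys, , drop = FALSE]
  pr <- t(utils::combn(length(cys), 2))
  d <- sqrt(rowSums((sg[pr[, 1], , drop = FALSE] -
                       sg[pr[, 2], , drop = FALSE])^2))
  ok <- which(d <= cutoff)
  ok <- ok[order(d[ok])]
  used <- logical(length(cys))
  for (r in ok) {
    a <- pr[r, 1]; b <- pr[r, 2]
    if (used[a] || used[b]) next
    used[a] <- used[b] <- TRUE
    out <- rbind(out, data.frame(res_i = cys[a], res_j = cys[b],
                                 distance = d[r]))
  }
  out[order(out$res_i), , drop = FALSE]
}

#' Global pairwise sequence identity (Needleman-Wunsch, BLOSUM62)
#'
#' Percent identity of the optimal global alignment with affine gap
#' penalties: identical columns divided by the full alignment length
#' (gap columns count in the denominator).
#'
#' @param seq_a,seq_b protein sequences (single strings, standard 20
#'   amino acids).
#' @param gap_open,gap_extend affine gap penalties (a gap of length g
#'   costs `gap_open + g * gap_extend`).
#' @return Percent identity in [0, 100], with attributes `score` and
#'   `alignment_length`.
#' @export
global_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("global_identity: empty sequence")
    bad <- setdiff(strsplit(toupper(s), "")[[1]], aa_one)
    if (length(bad))
      stop("global_identity: non-amino-acid symbol(s): ",
           paste(unique(bad), collapse = ", "))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(seq_a)), Biostrings::AAString(toupper(seq_b)),
    type = "global", substitutionMatrix = get("BLOSUM62"),
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  len <- length(a)
  ident <- sum(a == b & a != "-") / len * 100
  attr(ident, "score") <- Biostrings::score(pa)
  attr(ident, "alignment_length") <- len
  ident
}

#' Summary statistics of a repeat segmentation
#'
#' @param segments a [segment_repeats] result.
#' @param msa a [structure_guided_msa] over the same segments.
#' @return List: `count`, `mean_length`, `sd_length`,
#'   `mean_pairwise_identity` (percent, identical columns over columns
#'   where both rows are non-gap).
#' @export
repeat_stats <- function(segments, msa) {
  if (nrow(segments) < 1) stop("repeat_stats: no segments")
  len <- segments$end - segments$start + 1
  k <- nrow(msa$rows)
  pid <- if (k >= 2) {
    pr <- t(utils::combn(k, 2))
    vals <- vapply(seq_len(nrow(pr)), function(r) {
      a <- msa$rows[pr[r, 1], ]; b <- msa$rows[pr[r, 2], ]
      both <- a != "-" & b != "-"
      if (!any(both)) return(NA_real_)
      mean(a[both] == b[both]) * 100
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  } else NA_real_
  list(count = nrow(segments), mean_length = mean(len),
       sd_length = stats::sd(len), mean_pairwise_identity = pid)
}
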