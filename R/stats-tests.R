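#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Computes the U statistic with midrank ties. For `n1 * n2 <= 64` the
#' two-sided p value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the observed (mid)ranks;
#' otherwise the tie-corrected normal approximation is used (no
#' continuity correction). The enumeration handles ties exactly, which
#' the classical exact distribution does not.
#'
#' @param x,y numeric samples (non-empty).
#' @return List of class `test_result`: `statistic` (U of `x`),
#'   `p_value` (two-sided), `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("mann_whitney_u: empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 64) {
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sig2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    z <- (u - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u, p_value = min(p, 1), n1 = n1, n2 = n2,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Compare detachment curves between two groups at fixed timepoints
#'
#' At each timepoint the replicate curve values are compared with a
#' two-sample equal-variance Student t test (the Welch statistic is
#' reported alongside), together with per-group mean and standard
#' deviation.
#'
#' @param group_a,group_b lists of detachment curves (data frames with
#'   `time_s` and `fraction_remaining` or `value`), >= 2 replicates
#'   each.
#' @param timepoints seconds at which to test (defaults to the assay's
#'   50/100/150/200 s).
#' @return Data frame: `time_s`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `t`, `p_value`, `t_welch`, `p_welch`.
#' @export
compare_curves <- function(group_a, group_b,
                           timepoints = c(50, 100, 150, 200)) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("compare_curves: need >= 2 replicates per group")
  val_at <- function(curve, t) {
    y <- if ("fraction_remaining" %in% names(curve))
      curve$fraction_remaining else curve$value
    if (t < min(curve$time_s) || t > max(curve$time_s))
      stop("compare_curves: curve not defined at timepoint ", t)
    stats::approx(curve$time_s, y, xout = t)$y
  }
  do.call(rbind, lapply(timepoints, function(tp) {
    a <- vapply(group_a, val_at, numeric(1), t = tp)
    b <- vapply(group_b, val_at, numeric(1), t = tp)
    if (isTRUE(all.equal(a, b))) {
      tt <- list(statistic = 0, p.value = 1)
      tw <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tw <- stats::t.test(a, b, var.equal = FALSE)
    }
    data.frame(time_s = tp, mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               t = unname(tt$statistic), p_value = tt$p.value,
               t_welch = unname(tw$statistic), p_welch = tw$p.value)
  }))
}
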