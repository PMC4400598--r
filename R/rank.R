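# Mann-Whitney comparison with Hodges-Lehmann shift, and Fisher's exact test.

#' Mann-Whitney test with Hodges-Lehmann shift estimate
#'
#' Convention: `U` is the number of (x, y) pairs with `y < x`, plus half the
#' tied pairs (equivalently the rank-sum of `x` minus `n1(n1+1)/2`). The exact
#' null distribution (no ties, both sizes <= `exact_threshold`) is computed by
#' the count recursion over rank assignments; otherwise a normal approximation
#' with continuity and tie correction is used. The shift estimate is the
#' Hodges-Lehmann estimator: the median of all pairwise differences `y - x`,
#' with the distribution-free confidence interval read from the ordered
#' pairwise differences at the normal-approximation rank cutoff.
#'
#' @param x,y non-empty numeric samples (degrees, for division angles), or
#'   [angle_dataset()] objects.
#' @param exact_threshold use the exact null when both sizes are at or below
#'   this and there are no ties (default 12).
#' @param conf_level confidence level for the Hodges-Lehmann interval.
#' @return An object of class `rank_test`: `U`, `p`, `method`,
#'   `median_1`, `median_2`, `hl_shift` (location shift of y relative to x),
#'   `ci_low`, `ci_high`, `confidence`, `n1`, `n2`, `convention`.
#' @export
mann_whitney <- function(x, y, exact_threshold = 12L, conf_level = 0.95) {
  lx <- if (inherits(x, "angle_dataset")) x$label else "x"
  ly <- if (inherits(y, "angle_dataset")) y$label else "y"
  if (inherits(x, "angle_dataset")) x <- x$angles
  if (inherits(y, "angle_dataset")) y <- y$angles
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) validation_error("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)

  if (!has_ties && n1 <= exact_threshold && n2 <= exact_threshold) {
    method <- "exact"
    cnt <- u_null_counts(n1, n2)
    tot <- sum(cnt)
    u0 <- as.integer(round(U))
    p_le <- sum(cnt[seq_len(u0 + 1L)]) / tot
    p_ge <- sum(cnt[(u0 + 1L):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    method <- "normal_approximation"
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma   # continuity correction
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }

  diffs <- sort(as.vector(outer(y, x, "-")))
  nd <- n1 * n2
  hl <- median(diffs)
  sigma0 <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  k <- max(0L, min(floor(nd / 2 - zq * sigma0), floor((nd - 1) / 2)))
  ci_low <- diffs[k + 1L]
  ci_high <- diffs[nd - k]

  structure(
    list(U = U, p = p, method = method,
         median_1 = median(x), median_2 = median(y),
         hl_shift = hl, ci_low = ci_low, ci_high = ci_high,
         confidence = conf_level, n1 = n1, n2 = n2,
         labels = c(lx, ly),
         convention = "U = #{(x,y): y < x} + ties/2; hl_shift = median(y - x)"),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$U, x$p, x$n1, x$n2))
  cat(sprintf("medians %.3f vs %.3f; Hodges-Lehmann shift %.3f [%g%% CI %.3f, %.3f]\n",
              x$median_1, x$median_2, x$hl_shift, 100 * x$confidence,
              x$ci_low, x$ci_high))
  invisible(x)
}

# Null counts of U for sample sizes (n, m) without ties: counts[u+1] is the
# number of rank assignments with U = u, u = 0..n*m. Recursion
# c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1).
#' @noRd
u_null_counts <- function(n, m) {
  N <- n * m
  # d[u+1, i+1, j+1] = c(u; i, j)
  d <- array(0, dim = c(N + 1L, n + 1L, m + 1L))
  d[1L, , ] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      for (u in seq_len(i * j)) {
        from_left <- if (u - j >= 0L) d[u - j + 1L, i, j + 1L] else 0
        d[u + 1L, i + 1L, j + 1L] <- from_left + d[u + 1L, i + 1L, j]
      }
    }
  }
  d[, n + 1L, m + 1L]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Hypergeometric enumeration: with margins fixed, the two-sided p-value is
#' the sum of the probabilities of all tables as or less probable than the
#' observed one. A table with an empty margin carries no information and
#' returns p = 1 (degenerate case, by convention).
#'
#' @param table a 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- if (is.matrix(table)) table else matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  if (any(dim(tab) != 2L)) validation_error("table must be 2x2")
  v <- as.vector(tab)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    validation_error("counts must be non-negative integers")
  }
  m <- sum(tab[1L, ])      # row-1 margin
  n <- sum(tab[2L, ])      # row-2 margin
  k <- sum(tab[, 1L])      # column-1 margin
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- tab[1L, 1L]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}
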