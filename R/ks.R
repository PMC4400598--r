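# Kolmogorov-Smirnov machinery for division-angle distributions.
#
# The null hypothesis "spindle orientation is random" is a uniform
# distribution of theta on [0, 90] degrees; angles are normalised to [0, 1]
# by dividing by 90 before the test.

#' Bundle a labelled set of division angles
#'
#' @param label group label (e.g. a genotype).
#' @param angles numeric vector of division angles in degrees, all in \[0, 90\],
#'   at least one.
#' @return An object of class `angle_dataset` with fields `label`, `angles`, `n`.
#' @export
angle_dataset <- function(label, angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L) {
    validation_error("angle_dataset requires n >= 1 angles")
  }
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90)) {
    validation_error("angles must be finite and within [0, 90] degrees")
  }
  structure(list(label = as.character(label), angles = angles, n = length(angles)),
            class = "angle_dataset")
}

#' Normalise division angles onto \[0, 1\]
#'
#' Maps each theta to theta/90, the scale on which the uniform null is tested.
#'
#' @param dataset an [angle_dataset()] or a numeric vector of degrees.
#' @return Numeric vector of fractions in \[0, 1\], order preserved.
#' @export
normalize_angles <- function(dataset) {
  if (!inherits(dataset, "angle_dataset")) {
    dataset <- angle_dataset("unnamed", dataset)
  }
  dataset$angles / 90
}

#' One-sample KS statistic against the uniform CDF on \[0, 1\]
#'
#' D is the sup-distance between the empirical CDF of `u` and the identity:
#' `max_i max(i/n - u_(i), u_(i) - (i-1)/n)` over the sorted sample.
#'
#' @param u numeric vector of values in \[0, 1\], n >= 1.
#' @return The statistic D in \[0, 1\].
#' @export
ks_statistic_uniform <- function(u) {
  if (length(u) < 1L) validation_error("ks_statistic_uniform requires n >= 1")
  if (any(!is.finite(u)) || any(u < 0 | u > 1)) {
    validation_error("values must lie in [0, 1]")
  }
  n <- length(u)
  us <- sort(u)
  i <- seq_len(n)
  max(pmax(i / n - us, us - (i - 1) / n))
}

#' Asymptotic one-sample Kolmogorov p-value
#'
#' With lambda = sqrt(n) * D, `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)`,
#' the series truncated once a term falls below 1e-16 of the running sum, and
#' the result clamped to \[0, 1\].
#'
#' @param D KS statistic in \[0, 1\].
#' @param n sample size (>= 1).
#' @return The p-value.
#' @export
kolmogorov_p_asymptotic <- function(D, n) {
  if (!is.finite(D) || D < 0 || D > 1) validation_error("D must lie in [0, 1]")
  if (n < 1) validation_error("n must be >= 1")
  lambda <- sqrt(n) * D
  if (lambda == 0) return(1)
  s <- 0
  term <- Inf
  k <- 1L
  while (k <= 100000L) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-16 * abs(s)) break
    k <- k + 1L
  }
  min(max(2 * s, 0), 1)
}

#' Exact one-sample Kolmogorov p-value (Durbin/Marsaglia matrix method)
#'
#' Computes `P(D_n >= D)` exactly for 1 <= n <= 1000 via the
#' Marsaglia-Tsang-Wang formulation of Durbin's matrix recursion:
#' `P(D_n < d) = n!/n^n * (H^n)[k, k]` with `k = ceil(n d)`, `m = 2k - 1`,
#' `h = k - n d`, and the m x m matrix H of partial binomial sums. Converges
#' to the asymptotic value as n grows.
#'
#' @param D KS statistic in \[0, 1\].
#' @param n sample size, 1 <= n <= 1000.
#' @return The p-value `P(D_n >= D)`.
#' @export
kolmogorov_p_exact <- function(D, n) {
  if (!is.finite(D) || D < 0 || D > 1) validation_error("D must lie in [0, 1]")
  if (n < 1 || n > 1000) validation_error("kolmogorov_p_exact supports 1 <= n <= 1000")
  n <- as.integer(n)
  if (D >= 1) return(0)
  if (D <= 1 / (2 * n)) return(1)  # P(D_n < d) = 0 for d <= 1/(2n)
  nd <- n * D
  k <- as.integer(ceiling(nd - 1e-12))
  m <- 2L * k - 1L
  h <- k - nd
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1L >= 0L) H[i, j] <- 1
    }
  }
  for (i in seq_len(m)) {
    H[i, 1L] <- H[i, 1L] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1L)
  }
  H[m, 1L] <- H[m, 1L] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1L > 0L) {
        H[i, j] <- H[i, j] / prod(seq_len(i - j + 1L))
      }
    }
  }
  # H^n with exponent tracking to avoid under/overflow
  pow <- list(mat = diag(m), expo = 0)
  base <- list(mat = H, expo = 0)
  nn <- n
  while (nn > 0L) {
    if (nn %% 2L == 1L) {
      pow$mat <- pow$mat %*% base$mat
      pow$expo <- pow$expo + base$expo
      if (pow$mat[k, k] > 1e140) {
        pow$mat <- pow$mat / 1e140
        pow$expo <- pow$expo + 140
      }
    }
    base$mat <- base$mat %*% base$mat
    base$expo <- base$expo * 2
    if (base$mat[k, k] > 1e140) {
      base$mat <- base$mat / 1e140
      base$expo <- base$expo + 140
    }
    nn <- nn %/% 2L
  }
  s <- pow$mat[k, k]
  expo <- pow$expo
  # multiply by n!/n^n term by term, rescaling as needed
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) {
      s <- s * 1e140
      expo <- expo - 140
    }
  }
  cdf <- s * 10^expo
  min(max(1 - cdf, 0), 1)
}

#' Two-sample KS test
#'
#' D is the sup-distance between the two empirical CDFs; the p-value uses the
#' asymptotic Kolmogorov formula at effective size `n*m/(n+m)`.
#'
#' @param u,v non-empty numeric samples.
#' @param labels optional length-2 character vector for the result.
#' @return A [ks_result()] with `mode = "two_sample"`.
#' @export
ks_two_sample <- function(u, v, labels = NULL) {
  if (length(u) < 1L || length(v) < 1L) validation_error("both samples must be non-empty")
  n <- length(u)
  m <- length(v)
  pooled <- sort(unique(c(u, v)))
  Fu <- ecdf(u)(pooled)
  Fv <- ecdf(v)(pooled)
  D <- max(abs(Fu - Fv))
  n_eff <- n * m / (n + m)
  p <- kolmogorov_p_asymptotic(D, n_eff)
  ks_result(D, p, n = n_eff, method = "asymptotic", mode = "two_sample",
            labels = labels)
}

#' @noRd
ks_result <- function(D, p, n, method, mode, labels = NULL, seed = NULL) {
  if (D < 0 || D > 1 || p < 0 || p > 1) {
    validation_error("KS result requires D and p in [0, 1]")
  }
  structure(
    list(D = D, p = p, n = n, method = method, mode = mode,
         labels = labels, seed = seed),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov (%s, %s): D = %.4f, p = %.4g, n = %g\n",
              x$mode, x$method, x$D, x$p, x$n))
  invisible(x)
}

#' Test a division-angle distribution against the random (uniform) null
#'
#' Angles are normalised to \[0, 1\] by theta/90. The default mode tests the
#' sample against the uniform CDF (one-sample). `mode = "two_sample"` instead
#' draws a seeded uniform sample of equal size and runs the two-sample test —
#' provided as an alternative reading of "versus a random distribution", never
#' used silently.
#'
#' @param dataset an [angle_dataset()] (or numeric vector of degrees).
#' @param mode `"one_sample_uniform"` (default) or `"two_sample"`.
#' @param method for the one-sample mode: `"auto"` (exact when n <= 140, else
#'   asymptotic), `"exact"`, or `"asymptotic"`.
#' @param seed RNG seed for the two-sample mode's uniform draw (default 1729,
#'   recorded in the result).
#' @return A `ks_result` with fields `D`, `p`, `n`, `method`, `mode`, `seed`.
#' @export
test_against_random <- function(dataset, mode = c("one_sample_uniform", "two_sample"),
                                method = c("auto", "exact", "asymptotic"),
                                seed = 1729L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!inherits(dataset, "angle_dataset")) dataset <- angle_dataset("unnamed", dataset)
  u <- normalize_angles(dataset)
  n <- length(u)
  if (mode == "one_sample_uniform") {
    D <- ks_statistic_uniform(u)
    use_exact <- switch(method, auto = n <= 140, exact = TRUE, asymptotic = FALSE)
    p <- if (use_exact) kolmogorov_p_exact(D, n) else kolmogorov_p_asymptotic(D, n)
    ks_result(D, p, n = n,
              method = if (use_exact) "exact" else "asymptotic",
              mode = mode, labels = dataset$label)
  } else {
    v <- withr::with_seed(seed, runif(n))
    res <- ks_two_sample(u, v, labels = c(dataset$label, "uniform_draw"))
    res$seed <- seed
    res
  }
}
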