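# Self-contained circular statistics: resultant lengths, circular SD,
# von Mises sampling and calibration, Watson's two-sample U2 test, and the
# scalar two-group comparisons used alongside the polarity metrics.

#' Circular mean direction and mean resultant length
#'
#' For an angle sample `theta`, the resultant is `sum(exp(1i * theta)) / n`;
#' its modulus is the mean resultant length R-bar (1 = perfectly aligned,
#' 0 = balanced/uniform) and its argument the mean direction.
#'
#' @param angles numeric vector of angles in radians (any range; reduced
#'   internally into `(-pi, pi]`).
#' @return list with `mean_angle` (radians, `NA` when R-bar < 1e-12, i.e. no
#'   defined direction), `rbar` in `[0, 1]`, and `n`.
#' @examples
#' circ_mean_resultant(c(0, pi / 2))  # mean pi/4, rbar sqrt(2)/2
#' @export
circ_mean_resultant <- function(angles) {
  angles <- wrap_angle(angles[is.finite(angles)])
  n <- length(angles)
  if (n == 0) return(list(mean_angle = NA_real_, rbar = NA_real_, n = 0L))
  C <- mean(cos(angles)); S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  mean_angle <- if (rbar < 1e-12) NA_real_ else atan2(S, C)
  list(mean_angle = mean_angle, rbar = min(rbar, 1), n = n)
}

#' Circular standard deviation from a mean resultant length
#'
#' `sqrt(-2 * log(rbar))`, the standard circular SD; strictly decreasing in
#' `rbar`, 0 at `rbar = 1` and `Inf` at `rbar = 0`.
#'
#' @param rbar mean resultant length(s) in `[0, 1]`.
#' @return circular SD in radians.
#' @export
circ_sd <- function(rbar) {
  stopifnot(all(rbar >= 0 & rbar <= 1))
  ifelse(rbar == 0, Inf, sqrt(-2 * log(rbar)))
}

#' Expected mean resultant length of a von Mises distribution
#'
#' `A(kappa) = I1(kappa) / I0(kappa)` via exponentially scaled Bessel
#' functions (stable for large kappa).
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return expected R-bar in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  stopifnot(all(kappa >= 0))
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Concentration parameter matching a target mean resultant length
#'
#' Numerical inverse of [vm_mean_resultant()]; useful for building synthetic
#' populations whose expected R-bar equals an observed value.
#'
#' @param rbar target mean resultant length in `[0, 1)`.
#' @return kappa >= 0 with `vm_mean_resultant(kappa) == rbar`.
#' @export
vm_concentration <- function(rbar) {
  stopifnot(length(rbar) == 1, rbar >= 0, rbar < 1)
  if (rbar == 0) return(0)
  # A(kappa) ~ 1 - 1/(2 kappa) for large kappa; switch before besselI
  # underflows in the scaled regime
  if (rbar >= vm_mean_resultant(1e4)) return(1 / (2 * (1 - rbar)))
  stats::uniroot(function(k) vm_mean_resultant(k) - rbar,
                 lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; the circular analogue of the
#' Gaussian, with mean direction `mu` and concentration `kappa` (`kappa = 0`
#' is the circular uniform).
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[keep] - 0.5) * acos(f[keep]))
  }
  wrap_angle(out[seq_len(n)] + mu)
}

# Watson's two-sample U2 statistic. Computed from the pooled sorted sample as
# U2 = n*m / N^2 * sum_k (d_k - mean(d))^2, d_k = F_a(k) - F_b(k) at the k-th
# pooled order statistic; subtracting mean(d) makes the statistic invariant to
# the choice of origin on the circle. Ties are resolved by pooled sort order.
watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  z <- c(a, b)
  lab <- c(rep(1L, n), rep(0L, m))[order(z)]
  d <- cumsum(lab) / n - cumsum(1L - lab) / m
  n * m / N^2 * sum((d - mean(d))^2)
}

# U2 for many label permutations at once: `labs` is an N x P 0/1 matrix of
# group-A indicators already aligned to the pooled sort order.
watson_u2_stat_perm <- function(labs, n, m) {
  N <- n + m
  ca <- apply(labs, 2, cumsum)
  d <- ca / n - (matrix(seq_len(N), N, ncol(labs)) - ca) / m
  n * m / N^2 * colSums((d - matrix(colMeans(d), N, ncol(d), byrow = TRUE))^2)
}

#' Watson's two-sample U-squared test for circular data
#'
#' Nonparametric test of whether two circular samples come from the same
#' distribution, with the classic rank-based U2 statistic. P-values come from
#' seeded label permutation (default), from exhaustive enumeration of all
#' label partitions (small samples), or from interpolation in the asymptotic
#' critical-value table.
#'
#' @param a,b numeric vectors of angles in radians.
#' @param method `"permutation"`, `"exact"` or `"asymptotic"`.
#' @param n_permutations number of random label permutations (default 9999).
#' @param seed optional integer seed making the permutation p-value
#'   reproducible without touching the global RNG stream.
#' @return an object of class `htest` with `statistic`, `p.value`, `method`
#'   and sample sizes; permutation results carry `n_permutations` and `seed`.
#'   The permutation p-value uses the add-one convention `(b + 1) / (m + 1)`
#'   and therefore never reports exactly 0.
#' @examples
#' a <- rvonmises(30, 0, 2)
#' watson_u2(a, a + 0.01, n_permutations = 199, seed = 1)
#' @export
watson_u2 <- function(a, b, method = c("permutation", "exact", "asymptotic"),
                      n_permutations = 9999, seed = NULL) {
  method <- match.arg(method)
  a <- wrap_angle(a[is.finite(a)]); b <- wrap_angle(b[is.finite(b)])
  n <- length(a); m <- length(b); N <- n + m
  stopifnot(n >= 1, m >= 1)
  tol <- 1e-12
  if (diff(range(c(a, b))) < tol) {
    # fully tied pooled sample: no evidence of any difference
    return(structure(list(statistic = c(U2 = 0), p.value = 1,
                          method = "Watson two-sample U2 test (degenerate)",
                          n = c(n_a = n, n_b = m),
                          n_permutations = NA_integer_, seed = seed,
                          data.name = paste(n, "and", m, "angles")),
                     class = "htest"))
  }
  obs <- watson_u2_stat(a, b)
  if (method == "permutation") {
    p <- local_seed(seed, {
      labs <- vapply(seq_len(n_permutations),
                     function(i) {
                       v <- integer(N); v[sample.int(N, n)] <- 1L; v
                     }, integer(N))
      stat <- watson_u2_stat_perm(labs, n, m)
      (sum(stat >= obs - tol) + 1) / (n_permutations + 1)
    })
    meth <- "Watson two-sample U2 test (permutation p-value)"
  } else if (method == "exact") {
    idx <- utils::combn(N, n)
    stat <- apply(idx, 2, function(ii) {
      v <- integer(N); v[ii] <- 1L
      cumsum_a <- cumsum(v)
      d <- cumsum_a / n - (seq_len(N) - cumsum_a) / m
      n * m / N^2 * sum((d - mean(d))^2)
    })
    p <- mean(stat >= obs - tol)
    n_permutations <- ncol(idx)
    meth <- "Watson two-sample U2 test (exact enumeration)"
  } else {
    stopifnot(n >= 4, m >= 4)
    # asymptotic upper quantiles of U2 (Watson 1962 / standard tables)
    crit <- c(`0.5` = 0.071, `0.2` = 0.105, `0.1` = 0.152, `0.05` = 0.187,
              `0.02` = 0.233, `0.01` = 0.268, `0.005` = 0.304, `0.001` = 0.385)
    alphas <- as.numeric(names(crit))
    p <- if (obs <= crit[1]) 1 else if (obs >= crit[length(crit)]) 0.001 else
      exp(stats::approx(crit, log(alphas), xout = obs)$y)
    meth <- "Watson two-sample U2 test (asymptotic)"
  }
  structure(list(statistic = c(U2 = obs), p.value = min(p, 1), method = meth,
                 n = c(n_a = n, n_b = m), n_permutations = n_permutations,
                 seed = seed,
                 data.name = paste(n, "and", m, "angles")),
            class = "htest")
}

#' Compare two scalar samples (Welch's t or Mann-Whitney U)
#'
#' Thin wrapper on [stats::t.test()] (Welch, unequal variances) and
#' [stats::wilcox.test()] (two-sided, exact when possible), the two tests
#' applied to the non-circular per-cell metrics.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param method `"welch"` or `"mann_whitney"`.
#' @return an `htest` object (two-sided p-value).
#' @export
compare_groups <- function(x, y, method = c("welch", "mann_whitney")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("compare_groups() needs at least 2 finite values per group")
  }
  if (method == "welch") {
    stats::t.test(x, y, var.equal = FALSE)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
  }
}

#' Rose-diagram bin counts for an angle sample
#'
#' Counts per equal angular bin, for plotting circular diagrams of the
#' translational-polarity angles.
#'
#' @param angles radians.
#' @param bins number of equal divisions of the circle (default 20).
#' @return data.frame with `bin_mid_rad`, `bin_mid_deg`, `count`.
#' @export
rose_counts <- function(angles, bins = 20) {
  stopifnot(bins >= 2)
  a <- wrap_angle(angles[is.finite(angles)])
  br <- seq(-pi, pi, length.out = bins + 1)
  idx <- pmin(findInterval(a, br, rightmost.closed = TRUE), bins)
  cnt <- tabulate(idx, nbins = bins)
  mid <- (br[-1] + br[-(bins + 1)]) / 2
  data.frame(bin_mid_rad = mid, bin_mid_deg = mid * 180 / pi, count = cnt)
}

# Evaluate `expr` under a temporary seed without disturbing the caller's RNG
# stream; with seed = NULL, uses (and advances) the current stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
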