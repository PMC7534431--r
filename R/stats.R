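# Statistics layer: 2x2 chi-square contingency tests (Yates correction on
# by default), Mann-Whitney U with exact enumeration for small samples,
# Wilson score intervals for proportions, and Southern-blot
# recipient:donor ratio arithmetic.

#' 2x2 chi-square contingency test
#'
#' Two-sided chi-square test on a 2x2 table of counts, with the Yates
#' continuity correction applied by default (the convention under which
#' the published P-values this package recomputes are reproduced).
#'
#' @param a,b,c,d Counts: rows are condition 1/2, columns outcome
#'   yes/no. A 2x2 matrix may be supplied as `a` instead.
#' @param continuity_correction Apply the Yates correction (default
#'   TRUE).
#' @return A list with `statistic`, `p_value`, `df` (= 1), `corrected`.
#' @examples
#' chisq_2x2(35, 337, 55, 322)$p_value  # ~0.04
#' @export
chisq_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                      continuity_correction = TRUE) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop("matrix input must be 2x2")
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("table total must be > 0")
  rs <- c(a + b, c + d); cs <- c(a + c, b + d)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin: chi-square test undefined")
  }
  O <- matrix(counts, 2, 2, byrow = TRUE)
  E <- outer(rs, cs) / n
  adj <- if (continuity_correction) pmin(abs(O - E), 0.5) else 0
  stat <- sum((abs(O - E) - adj)^2 / E)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, corrected = continuity_correction)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For samples with both sizes at most
#' `exact_max` the null distribution of U is enumerated exactly,
#' conditional on the observed (possibly tied) rank multiset, via a
#' counting recursion; the p-value is the null probability of a deviation
#' of U from its mean at least as large as observed. For larger samples
#' the normal approximation with tie correction is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest per-sample size for the exact path (8).
#' @return A list with `U` (the smaller of U_x and U_y), `U_x`, `U_y`,
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_y <- n1 * n2 - u_x
  u <- min(u_x, u_y)
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    # exact: distribution of the x-sample rank sum over all C(N, n1)
    # subsets of the observed rank multiset (doubled to integers)
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
    f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
    f[1, 1] <- 1
    for (v in r2) {
      kmax <- n1
      for (k in kmax:1) {
        src <- f[k, ]
        nz <- which(src > 0)
        if (length(nz) > 0) {
          tgt <- nz + v
          ok <- tgt <= smax + 1L
          f[k + 1L, tgt[ok]] <- f[k + 1L, tgt[ok]] + src[nz[ok]]
        }
      }
    }
    counts <- f[n1 + 1L, ]
    sums <- (seq_along(counts) - 1) / 2            # back to rank-sum scale
    u_all <- sums - n1 * (n1 + 1) / 2              # U_x for each subset sum
    dev <- abs(u_all - mu)
    obs_dev <- abs(u_x - mu)
    p <- sum(counts[dev >= obs_dev - 1e-9]) / sum(counts)
    list(U = u, U_x = u_x, U_y = u_y, p_value = p, method = "exact")
  } else {
    N <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0 || u_x == mu) {
      p <- 1
    } else {
      z <- (u_x - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    list(U = u, U_x = u_x, U_y = u_y, p_value = min(p, 1),
         method = "normal_tie_corrected")
  }
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes. @param n Trials (> 0). @param level Confidence
#'   level.
#' @return Named numeric `c(lower, upper)`, within \[0, 1\] and bracketing
#'   k/n.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Southern-blot time series of band intensities
#'
#' @param timepoints Hours after induction; must include 0.
#' @param recipient_intensity,donor_intensity Densitometry readings of
#'   the intact recipient and donor fragments (donor > 0 everywhere).
#' @return An object of class `southern_series`.
#' @export
southern_series <- function(timepoints, recipient_intensity, donor_intensity) {
  if (length(timepoints) != length(recipient_intensity) ||
      length(timepoints) != length(donor_intensity)) {
    stop("timepoints and intensity vectors must have equal length")
  }
  if (!any(timepoints == 0)) stop("a timepoint at t = 0 is required")
  if (any(donor_intensity <= 0)) stop("donor intensity must be > 0 everywhere")
  if (anyDuplicated(timepoints)) stop("duplicate timepoints")
  structure(list(timepoints = timepoints,
                 recipient_intensity = recipient_intensity,
                 donor_intensity = donor_intensity),
            class = "southern_series")
}

#' Normalized recipient:donor ratios
#'
#' The recipient signal is normalized to the donor signal at each
#' timepoint, and each ratio is then normalized to the t = 0 ratio
#' (`r_0` = 1 exactly). Invariant to rescaling all intensities by a
#' positive constant.
#'
#' @param series A `southern_series`.
#' @return A data.frame with columns `time`, `ratio`.
#' @export
southern_normalize <- function(series) {
  stopifnot(inherits(series, "southern_series"))
  raw <- series$recipient_intensity / series$donor_intensity
  r0 <- raw[series$timepoints == 0]
  data.frame(time = series$timepoints, ratio = raw / r0)
}

#' Maximum cut fraction of the recipient allele
#'
#' `1 - min(r_t)`: the largest fraction of recipient molecules observed
#' broken at any timepoint.
#'
#' @param series A `southern_series` (or the data.frame from
#'   [southern_normalize()]).
#' @return Numeric scalar.
#' @export
cut_fraction <- function(series) {
  r <- if (inherits(series, "southern_series")) southern_normalize(series)$ratio else series$ratio
  1 - min(r)
}

#' Fraction of broken molecules repaired between two timepoints
#'
#' The recovered share of broken molecules,
#' `(r_t2 - r_t1) / (1 - r_t1)`; defined only when breaks exist at t1
#' (`r_t1 < 1`). The raw ratio difference `r_t2 - r_t1` is available as
#' an alternative.
#'
#' @param series A `southern_series`.
#' @param t1,t2 Timepoints present in the series.
#' @param method `"recovered_share"` (default) or `"raw_difference"`.
#' @return Numeric scalar.
#' @export
repaired_fraction <- function(series, t1, t2,
                              method = c("recovered_share", "raw_difference")) {
  method <- match.arg(method)
  norm <- southern_normalize(series)
  get_r <- function(t) {
    i <- which(norm$time == t)
    if (length(i) != 1L) stop("timepoint ", t, " not in series")
    norm$ratio[i]
  }
  r1 <- get_r(t1); r2 <- get_r(t2)
  if (method == "raw_difference") return(r2 - r1)
  if (r1 >= 1) stop("repaired_fraction undefined: no breaks at t1 (r_t1 >= 1)")
  (r2 - r1) / (1 - r1)
}
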