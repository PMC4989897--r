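# Shared nonparametric rank tests. Tag counts and methylation differences
# are heavily tied and often tiny-sample, so exact p-values are computed by
# enumeration / convolution where feasible (ties handled exactly via
# midranks), with the tie-corrected normal approximation beyond that.

# Distribution of the rank-sum of a size-nA subset of `ranks` (midranks,
# possibly half-integer), as a table over doubled sums. Enumerates all
# choose(n, nA) subsets.
.ranksum_null <- function(ranks, n_a) {
  combos <- utils::combn(length(ranks), n_a)
  r2 <- round(ranks * 2)
  colSums(matrix(r2[combos], nrow = n_a))
}

#' Two-sample rank-sum test (Mann-Whitney)
#'
#' Compares two unpaired samples by ranks. When both samples have at most
#' `exact_max` observations the p-value is exact, by enumerating every
#' assignment of the pooled midranks to group A (correct under ties);
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used. Two-sided p is the null probability of a statistic
#' at least as far from its mean as observed.
#'
#' @param x,y Numeric vectors (class A and class B), both non-empty.
#' @param exact_max Largest per-group size for the exact path (default 10).
#' @return List with `statistic` (Mann-Whitney U for A), `p_greater`
#'   (one-sided, A tends larger), `p_less`, `p_two_sided`, and `exact`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n_a <- length(x); n_b <- length(y); n <- n_a + n_b
  r <- rank(c(x, y))
  w_a <- sum(r[seq_len(n_a)])
  u <- w_a - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  if (n_a <= exact_max && n_b <= exact_max) {
    null2 <- .ranksum_null(r, n_a)            # doubled rank-sums
    obs2 <- round(w_a * 2)
    mu2 <- mean(null2)
    p_ge <- mean(null2 >= obs2)
    p_le <- mean(null2 <= obs2)
    p_two <- mean(abs(null2 - mu2) >= abs(obs2 - mu2) - 1e-9)
    return(list(statistic = u, p_greater = p_ge, p_less = p_le,
                p_two_sided = min(1, p_two), exact = TRUE))
  }
  tie_tab <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  s <- sqrt(sigma2)
  if (s == 0) {
    return(list(statistic = u, p_greater = 1, p_less = 1, p_two_sided = 1,
                exact = FALSE))
  }
  p_g <- stats::pnorm((u - mu - 0.5) / s, lower.tail = FALSE)
  p_l <- stats::pnorm((u - mu + 0.5) / s)
  p_two <- min(1, 2 * stats::pnorm((abs(u - mu) - 0.5) / s, lower.tail = FALSE))
  list(statistic = u, p_greater = p_g, p_less = p_l, p_two_sided = p_two,
       exact = FALSE)
}

# Exact distribution of the positive-rank sum V over the 2^n sign
# assignments, via polynomial convolution on doubled ranks. Returns
# P(V2 = k) for k = 0..sum(2r).
.signedrank_null <- function(ranks2) {
  probs <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) / 2 + shifted / 2
  }
  probs
}

#' One-sample / paired Wilcoxon signed-rank test
#'
#' Tests whether paired differences (or a single sample against 0) are
#' centered at zero. Zero differences are dropped first. For `n <=
#' exact_max` remaining differences the null distribution of the
#' positive-rank sum is computed exactly by convolution over all sign
#' assignments (midranks under ties); beyond that, a tie-corrected normal
#' approximation with continuity correction. If every difference is zero
#' the test is degenerate and p = 1 is reported with `degenerate = TRUE`.
#'
#' @param d Numeric vector of differences.
#' @param exact_max Largest n for the exact path (default 25).
#' @return List with `statistic` (positive-rank sum V), `p_greater`
#'   (one-sided, shifted above 0), `p_less`, `p_two_sided`, `n_used`,
#'   `exact`, `degenerate`.
#' @export
signed_rank_test <- function(d, exact_max = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_greater = 1, p_less = 1, p_two_sided = 1,
                n_used = 0L, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    r2 <- round(r * 2)
    probs <- .signedrank_null(r2)
    k <- seq_along(probs) - 1       # doubled V values
    v2 <- round(v * 2)
    mu2 <- sum(k * probs)
    p_ge <- sum(probs[k >= v2 - 1e-9])
    p_le <- sum(probs[k <= v2 + 1e-9])
    p_two <- sum(probs[abs(k - mu2) >= abs(v2 - mu2) - 1e-9])
    return(list(statistic = v, p_greater = p_ge, p_less = p_le,
                p_two_sided = min(1, p_two), n_used = n, exact = TRUE,
                degenerate = FALSE))
  }
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  s <- sqrt(sigma2)
  p_g <- stats::pnorm((v - mu - 0.5) / s, lower.tail = FALSE)
  p_l <- stats::pnorm((v - mu + 0.5) / s)
  p_two <- min(1, 2 * stats::pnorm((abs(v - mu) - 0.5) / s, lower.tail = FALSE))
  list(statistic = v, p_greater = p_g, p_less = p_l, p_two_sided = p_two,
       n_used = n, exact = FALSE, degenerate = FALSE)
}
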