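#' One-way ANOVA power via the noncentral F distribution
#'
#' Power of the balanced one-way ANOVA with `k` groups of `n` subjects at
#' significance level `alpha` for a standardized effect size Cohen's f:
#' the test statistic follows a noncentral F distribution with
#' `df1 = k - 1`, `df2 = k (n - 1)` and noncentrality `lambda = f^2 k n`,
#' so `power = P(F' > F_crit(1 - alpha))`. With `f = 0` the power equals
#' `alpha` exactly. An unequal-n variant uses `lambda = f^2 N` with
#' `N = sum(n_i)` and `df2 = N - k`.
#'
#' @param k number of groups (>= 2).
#' @param n per-group size (>= 2); ignored when `n_i` is given.
#' @param f Cohen's f (>= 0).
#' @param alpha significance level (default 0.05).
#' @param n_i optional vector of unequal group sizes.
#' @return the power, a number in `(0, 1)`.
#' @examples
#' anova_power(k = 4, n = 18, f = 0.40)   # ~0.80, the canonical benchmark
#' @export
anova_power <- function(k, n, f, alpha = 0.05, n_i = NULL) {
  stopifnot(k >= 2, f >= 0, alpha > 0, alpha < 1)
  if (is.null(n_i)) {
    stopifnot(n >= 2)
    df2 <- k * (n - 1)
    lambda <- f^2 * k * n
  } else {
    stopifnot(length(n_i) == k, all(n_i >= 2))
    df2 <- sum(n_i) - k
    lambda <- f^2 * sum(n_i)
  }
  df1 <- k - 1
  if (df2 < 1) stop("invalid residual degrees of freedom")
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimum detectable Cohen's f
#'
#' The smallest standardized effect size a one-way ANOVA design detects with
#' the target power: the root of `power(f) - target`, found by bracketed
#' numerical root-finding to absolute tolerance 1e-8. As the target power
#' approaches `alpha`, f tends to zero.
#'
#' @param k,n,alpha,n_i design, as in [anova_power()].
#' @param power target power (in `(alpha, 1)`).
#' @return Cohen's f.
#' @examples
#' # design sensitivity of a 4-group cohort with smallest group n = 7,
#' # Bonferroni-corrected over six modules, at 80% power:
#' min_detectable_f(k = 4, n = 7, alpha = 0.05 / 6, power = 0.80)
#' @export
min_detectable_f <- function(k, n, alpha = 0.05, power = 0.80, n_i = NULL) {
  stopifnot(power > alpha, power < 1)
  fn <- function(f) anova_power(k, n, f, alpha, n_i = n_i) - power
  upper <- 1
  while (fn(upper) < 0 && upper < 1e3) upper <- upper * 2
  stats::uniroot(fn, c(1e-10, upper), tol = 1e-8)$root
}
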