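# The study's statistical battery, implemented from first principles with
# exact small-sample modes: rank-enumeration for Mann-Whitney, a
# generating-function convolution for the signed-rank null, direct pmf
# summation for the binomial test, the asymptotic Kolmogorov distribution
# for the two-sample KS test, and permutation-exact Spearman correlation.

.test_result <- function(statistic, p_value, method, alternative,
                         n1 = NA_integer_, n2 = NA_integer_,
                         n_pairs = NA_integer_, extra = list()) {
  stopifnot(p_value >= -1e-12, p_value <= 1 + 1e-12)
  structure(c(list(statistic = statistic,
                   p_value = min(1, max(0, p_value)),
                   method = method, alternative = alternative,
                   n1 = n1, n2 = n2, n_pairs = n_pairs), extra),
            class = "ephys_test")
}

#' @export
print.ephys_test <- function(x, ...) {
  cat(sprintf("statistic = %g, p = %g (%s, %s)\n",
              x$statistic, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test for a difference in medians. `U` counts the pairs
#' `(x_i, y_j)` with `x_i > y_j` (ties count one half). The p-value is
#' exact -- computed by enumerating all `choose(n1+n2, n1)` rank
#' assignments -- when `n1 + n2 <= exact_max_n` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (direction of
#'   the location of `x` relative to `y`).
#' @param exact_max_n Combined-size bound for the exact mode (default 12,
#'   924 arrangements at most).
#' @return An `ephys_test` with `statistic` (U for `x`), `p_value`,
#'   `method` (`"exact"`/`"asymptotic"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "less",
                                               "greater"),
                         exact_max_n = 12) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 values", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= exact_max_n) {
    # exact null: U for every assignment of n1 ranks out of n1+n2
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two_sided = mean(abs(u_all - n1 * n2 / 2) >=
                         abs(u - n1 * n2 / 2) - 1e-9),
      greater = mean(u_all >= u - 1e-9),
      less = mean(u_all <= u + 1e-9))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                                (N * (N - 1)))
    if (sigma2 <= 0)     # all observations identical
      return(.test_result(u, 1, "degenerate", alternative,
                          n1 = n1, n2 = n2))
    mu <- n1 * n2 / 2
    z <- u - mu
    cc <- 0.5 * sign(z)
    if (alternative == "two_sided") {
      p <- 2 * stats::pnorm(-abs(z - cc) / sqrt(sigma2))
    } else if (alternative == "greater") {
      p <- stats::pnorm((z - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      p <- stats::pnorm((z + 0.5) / sqrt(sigma2))
    }
    p <- min(1, p)
    method <- "asymptotic"
  }
  .test_result(u, p, method, alternative, n1 = n1, n2 = n2)
}

# exact null distribution of the positive signed-rank sum V for ranks 1..n:
# coefficients of prod_k (1 + q^k) / 2^n, by polynomial convolution
.signrank_null <- function(n) {
  coef <- 1
  for (k in seq_len(n)) coef <- c(coef, numeric(k)) + c(numeric(k), coef)
  coef / 2^n                      # index i -> P(V = i - 1)
}

#' Wilcoxon signed-rank test
#'
#' Paired / one-sample rank test on differences. Zero differences are
#' dropped (recorded in `n_zero`); `V` is the sum of ranks of the positive
#' differences and the reported statistic `W` is the smaller of the two
#' signed-rank sums. The p-value is exact -- from the full null
#' distribution of `V` obtained by convolution over the 2^n sign patterns
#' -- when `n <= exact_max_n` and the absolute differences are untied,
#' otherwise a normal approximation with tie and continuity correction.
#'
#' @param x Differences, or the first paired sample when `y` is given.
#' @param y Optional second paired sample (`differences = x - y`).
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @param exact_max_n Sample-size bound for the exact mode (default 20).
#' @return An `ephys_test` with `statistic` (W = min signed-rank sum),
#'   `p_value`, `method`, `n_pairs` (nonzero differences), `n_zero`, `V`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two_sided", "less",
                                                 "greater"),
                                 exact_max_n = 20) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(.test_result(NA_real_, 1, "degenerate", alternative,
                        n_pairs = 0L, extra = list(n_zero = n_zero,
                                                   V = NA_real_,
                                                   flagged = TRUE)))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  tot <- n * (n + 1) / 2
  w <- min(v, tot - v)
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_max_n) {
    pmf <- .signrank_null(n)
    pv <- function(op, val) sum(pmf[op(seq_along(pmf) - 1, val)])
    p <- switch(alternative,
      # symmetric null: two-sided mass of outcomes at least as extreme
      two_sided = min(1, 2 * pv(`<=`, w + 1e-9)),
      greater = pv(`>=`, v - 1e-9),
      less = pv(`<=`, v + 1e-9))
    method <- "exact"
  } else {
    mu <- tot / 2
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0)
      return(.test_result(w, 1, "degenerate", alternative, n_pairs = n,
                          extra = list(n_zero = n_zero, V = v,
                                       flagged = TRUE)))
    z <- v - mu
    if (alternative == "two_sided") {
      p <- 2 * stats::pnorm(-(abs(z) - 0.5) / sqrt(sigma2))
    } else if (alternative == "greater") {
      p <- stats::pnorm((z - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      p <- stats::pnorm((z + 0.5) / sqrt(sigma2))
    }
    p <- min(1, p)
    method <- "asymptotic"
  }
  .test_result(w, p, method, alternative, n_pairs = n,
               extra = list(n_zero = n_zero, V = v, flagged = FALSE))
}

#' Exact binomial proportion test
#'
#' Tests `k` successes in `n` trials against a null proportion `p0` by
#' direct summation of the binomial pmf. Two two-sided conventions are
#' offered: `"small_p"` sums every outcome whose pmf does not exceed the
#' observed outcome's pmf (the common "exact two-sided" definition), and
#' `"double"` doubles the smaller tail.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials.
#' @param p0 Null proportion in (0, 1); the degenerate values 0 and 1
#'   yield an indicator p-value.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @param convention Two-sided convention (default `"small_p"`).
#' @return An `ephys_test` with `statistic` (k), `p_value`, `method`
#'   `"exact"`, `n1` (= n), `convention`.
#' @export
binomial_proportion_test <- function(k, n, p0,
                                     alternative = c("two_sided", "less",
                                                     "greater"),
                                     convention = c("small_p", "double")) {
  alternative <- match.arg(alternative)
  convention <- match.arg(convention)
  stopifnot(k >= 0, k <= n, n >= 1)
  if (p0 <= 0 || p0 >= 1) {
    p <- if ((p0 <= 0 && k == 0) || (p0 >= 1 && k == n)) 1 else 0
    return(.test_result(k, p, "degenerate", alternative, n1 = n,
                        extra = list(convention = convention)))
  }
  pmf <- stats::dbinom(0:n, n, p0)
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  p <- switch(alternative,
    less = lower,
    greater = upper,
    two_sided = if (convention == "small_p")
      sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
    else min(1, 2 * min(lower, upper)))
  .test_result(k, p, "exact", alternative, n1 = n,
               extra = list(convention = convention))
}

# asymptotic Kolmogorov survival function Q(t) = 2 sum (-1)^{k-1} e^{-2k^2t^2}
.kolmogorov_sf <- function(t) {
  if (t < 1e-3) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Two-sample Kolmogorov-Smirnov comparison with compound criterion
#'
#' Computes the two-sample statistic `D` (maximum absolute ECDF
#' difference) directly and the asymptotic p-value from the Kolmogorov
#' distribution at `sqrt(n1 n2 / (n1 + n2)) * D`. Significance uses the
#' compound rule applied to the distribution comparisons in this workflow:
#' `p < alpha_p` AND `D > alpha_D`.
#'
#' @param x,y Numeric samples (warning below 10 values each: the
#'   asymptotic p is then unreliable).
#' @param alpha_p,alpha_D Compound-criterion levels (defaults 0.01
#'   and 0.1).
#' @return An `ephys_test` with `statistic` (D), `p_value`, `significant`
#'   (logical compound criterion), `n1`, `n2`.
#' @export
ks_compare <- function(x, y, alpha_p = 0.01, alpha_D = 0.1) {
  x <- sort(x[is.finite(x)]); y <- sort(y[is.finite(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs >= 2 values", call. = FALSE)
  if (n1 < 10 || n2 < 10)
    warning("fewer than 10 values per sample: asymptotic p unreliable")
  pooled <- sort(c(x, y))
  ex <- vapply(pooled, function(v) sum(x <= v), 0) / n1
  ey <- vapply(pooled, function(v) sum(y <= v), 0) / n2
  D <- max(abs(ex - ey))
  en <- sqrt(n1 * n2 / (n1 + n2))
  p <- .kolmogorov_sf(en * D)
  .test_result(D, p, "asymptotic", "two_sided", n1 = n1, n2 = n2,
               extra = list(significant = (p < alpha_p) && (D > alpha_D),
                            alpha_p = alpha_p, alpha_D = alpha_D))
}

# all permutations of 1..n as a matrix (n! rows); recursive construction
.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) # insert i, shift the rest
  }))
}

#' Spearman rank correlation
#'
#' Midranks for ties; `rho` is the Pearson correlation of the ranks. The
#' two-sided p-value is exact by full permutation enumeration for
#' `n <= exact_max_n` (default 9, 362880 permutations), otherwise the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @param exact_max_n Bound for the exact permutation mode.
#' @return An `ephys_test` with `statistic` (rho), `p_value`, `method`,
#'   `n_pairs`.
#' @export
spearman <- function(x, y, exact_max_n = 9) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("Spearman correlation requires n >= 5", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- .permutations(n)
    cy <- ry - mean(ry)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rho_all <- as.vector((matrix(cx[perms], nrow(perms)) %*% cy) / denom)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-9)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "asymptotic"
  }
  .test_result(rho, p, method, "two_sided", n_pairs = n)
}

#' Which two-sided binomial convention reproduces reported p-values
#'
#' Report-only calibration helper: evaluates both two-sided conventions of
#' [binomial_proportion_test()] on one or more (k, n, p0) cases and flags,
#' per case, which convention matches a reported p-value to the printed
#' precision.
#'
#' @param cases data.frame with columns `k`, `n`, `p0` and optionally
#'   `reported_p`.
#' @param digits Printed precision of the reported values (default 4).
#' @return data.frame with `p_small_p`, `p_double` and, when reported
#'   values are supplied, `matches` (`"small_p"`, `"double"`, `"both"` or
#'   `"neither"`).
#' @export
binomial_convention_report <- function(cases, digits = 4) {
  stopifnot(all(c("k", "n", "p0") %in% names(cases)))
  ps <- vapply(seq_len(nrow(cases)), function(i)
    binomial_proportion_test(cases$k[i], cases$n[i], cases$p0[i],
                             convention = "small_p")$p_value, 0)
  pd <- vapply(seq_len(nrow(cases)), function(i)
    binomial_proportion_test(cases$k[i], cases$n[i], cases$p0[i],
                             convention = "double")$p_value, 0)
  out <- cbind(cases, p_small_p = ps, p_double = pd)
  if ("reported_p" %in% names(cases)) {
    ms <- round(ps, digits) == round(cases$reported_p, digits)
    md <- round(pd, digits) == round(cases$reported_p, digits)
    out$matches <- ifelse(ms & md, "both",
                   ifelse(ms, "small_p",
                   ifelse(md, "double", "neither")))
  }
  out
}
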