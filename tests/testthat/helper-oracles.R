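# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive loops / direct formula
# evaluation, not the code paths they check.

oracle_coastline <- function(y) {
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + abs(y[i + 1] - y[i])
  s / length(y)
}

oracle_sliding_corr <- function(x, w) {
  L <- length(w)
  vapply(seq_len(length(x) - L + 1), function(k)
    suppressWarnings(stats::cor(x[k:(k + L - 1)], w)), 0)
}

oracle_sliding_power <- function(x, wlen) {
  vapply(seq_len(length(x) - wlen + 1), function(k)
    mean(x[k:(k + wlen - 1)]^2), 0)
}

oracle_kurtosis <- function(v) {
  m <- sum(v) / length(v)
  m2 <- sum((v - m)^2) / length(v)
  m4 <- sum((v - m)^4) / length(v)
  m4 / m2^2
}

# Mann-Whitney exact two-sided p by enumerating every rank assignment
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(combos) - n1 * (n1 + 1) / 2
  mean(abs(u_all - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-9)
}

# Wilcoxon signed-rank exact two-sided p by enumerating all 2^n sign
# patterns explicitly
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  tot <- n * (n + 1) / 2
  w_obs <- min(v_obs, tot - v_obs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  w_all <- pmin(v_all, tot - v_all)
  mean(w_all <= w_obs + 1e-9)
}

# exact binomial two-sided p by direct pmf summation (small-p convention)
oracle_binom_p <- function(k, n, p0) {
  pm <- vapply(0:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}

# two-sample KS D by direct ECDF evaluation on a dense grid of the data
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  mx <- vapply(pts, function(v) mean(x <= v), 0)
  my <- vapply(pts, function(v) mean(y <= v), 0)
  max(abs(mx - my))
}

# SE rule by exhaustive O(n^2) scan of all onset-anchored windows
oracle_se_flags <- function(onsets, window_s = 3600, min_seizures = 4) {
  t <- sort(onsets)
  flagged <- logical(length(t))
  for (i in seq_along(t)) {
    cnt <- 0
    for (j in seq_along(t))
      if (t[j] >= t[i] && t[j] < t[i] + window_s) cnt <- cnt + 1
    if (cnt >= min_seizures) flagged[i] <- TRUE
  }
  flagged
}

# greedy matching of detected to injected event times within a tolerance;
# returns TP / FP / FN counts
match_events <- function(detected, truth, tol_s) {
  used <- rep(FALSE, length(truth))
  tp <- 0
  for (t in detected) {
    j <- which(!used & abs(truth - t) <= tol_s)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}
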