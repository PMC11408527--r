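# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (direct summation, full enumeration) and
# share no code with the package internals they verify.

# Pearson correlation by direct summation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Per-window pairwise Fisher-z matrices by direct summation.
oracle_windowed_z <- function(a, b, W, S, clip = 1e-7) {
  n <- nrow(a)
  n_win <- floor((n - W) / S) + 1
  out <- array(NA_real_, c(ncol(a), ncol(b), n_win))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * S + 1):((w - 1) * S + W)
    for (i in seq_len(ncol(a)))
      for (j in seq_len(ncol(b))) {
        r <- oracle_pearson(a[idx, i], b[idx, j])
        r <- min(max(r, -1 + clip), 1 - clip)
        out[i, j, w] <- 0.5 * log((1 + r) / (1 - r))
      }
  }
  out
}

# Benjamini-Hochberg step-up by hand: returns rejection flags and
# monotone adjusted p-values in input order.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0) return(list(rejected = logical(0), adjusted = numeric(0)))
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(pmin(ps * m / seq_len(m), 1))))
  k <- which(ps <= seq_len(m) * q / m)
  rej_sorted <- rep(FALSE, m)
  if (length(k) > 0) rej_sorted[seq_len(max(k))] <- TRUE
  list(rejected = rej_sorted[order(o)], adjusted = adj[order(o)])
}

# Exact two-sided one-sample Wilcoxon p-value by enumerating all 2^n sign
# assignments (untied absolute values, zeros removed beforehand).
oracle_wilcoxon_exact <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  mu_v <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu_v) >= abs(v_obs - mu_v) - 1e-9))
}

# Kruskal-Wallis H with tie correction, from the rank-sum formula.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  rk <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
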