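#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilizing transform `z = atanh(r)` used throughout the
#' connectivity chains. Correlations of exactly +/-1 (e.g. from duplicated
#' traces) are clipped into the open interval before the transform so the
#' result stays finite and order-preserving.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`. `NA` values are
#'   passed through (missing edges stay missing).
#' @param clip_eps Clipping margin; `r` is clipped into
#'   `[-1 + clip_eps, 1 - clip_eps]`. Must lie in `(0, 1e-3]`.
#' @return Numeric vector of Fisher z values, same length as `r`.
#' @examples
#' fisher_z(0.5)            # 0.5 * log(3)
#' tanh(fisher_z(0.3))      # recovers 0.3
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  if (is.logical(r) && all(is.na(r))) r <- as.numeric(r)
  stopifnot(is.numeric(r), length(clip_eps) == 1L,
            clip_eps > 0, clip_eps <= 1e-3)
  if (any(is.nan(r) | is.infinite(r)))
    stop("invalid correlation: non-finite value")
  out <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12))
    stop("invalid correlation: outside [-1, 1]")
  rc <- pmin(pmax(r[ok], -1 + clip_eps), 1 - clip_eps)
  out[ok] <- atanh(rc)
  out
}

#' Benjamini-Hochberg false-discovery-rate decision
#'
#' Step-up FDR control across a family of p-values. Adjusted p-values are
#' the standard BH values (monotone, capped at 1) reported in the original
#' input order; a test is rejected when its adjusted p is at or below
#' `q`.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`. May be empty.
#' @param q Target FDR level in `(0, 1)`; default 0.05.
#' @return An object of class `fdr_decision`: a list with `raw_p`,
#'   `q_threshold`, `adjusted_p` and logical `rejected`.
#' @export
bh_fdr <- function(raw_p, q = 0.05) {
  stopifnot(is.numeric(raw_p), length(q) == 1L, q > 0, q < 1)
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p <- unname(as.numeric(raw_p))
  adj <- stats::p.adjust(p, method = "BH")
  structure(
    list(raw_p = p, q_threshold = q, adjusted_p = adj,
         rejected = !is.na(adj) & adj <= q),
    class = "fdr_decision")
}

new_test_result <- function(statistic, p_value, n, method,
                            tails = "two-sided", ...) {
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           n = n, method = method, tails = tails), list(...)),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.6g, p = %.4g, n = %s\n",
              x$method, x$tails, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Two-sided t-tests (one-sample, paired, unpaired)
#'
#' Thin wrapper around [stats::t.test()] that standardises the result
#' container and the error behaviour used by the connectivity chains.
#' Unpaired tests default to the classical pooled-variance form; set
#' `var_equal = FALSE` for Welch.
#'
#' @param x Numeric vector (first sample).
#' @param y Second sample for `"paired"`/`"unpaired"`, otherwise `NULL`.
#' @param mode One of `"unpaired"`, `"one_sample"`, `"paired"`.
#' @param mu Null value for the (mean) difference; default 0.
#' @param var_equal Pooled variance for unpaired mode (default `TRUE`).
#' @return A `test_result` with fields `statistic`, `p_value`, `n`,
#'   `method`, `tails`, `estimate`, `df`.
#' @export
t_test <- function(x, y = NULL, mode = c("unpaired", "one_sample", "paired"),
                   mu = 0, var_equal = TRUE) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (mode == "one_sample") {
    if (length(x) < 2L) stop("need at least 2 observations")
    if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
    ht <- stats::t.test(x, mu = mu)
    n <- length(x)
  } else {
    y <- as.numeric(y)
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 observations per group")
    if (mode == "paired") {
      if (length(x) != length(y)) stop("paired samples must match in length")
      d <- x - y
      if (stats::sd(d) == 0) stop("degenerate sample: zero variance")
      ht <- stats::t.test(x, y, paired = TRUE, mu = mu)
      n <- length(x)
    } else {
      if (stats::var(x) + stats::var(y) == 0)
        stop("degenerate sample: zero variance")
      ht <- stats::t.test(x, y, var.equal = var_equal, mu = mu)
      n <- c(length(x), length(y))
    }
  }
  new_test_result(ht$statistic, ht$p.value, n,
                  method = paste0(mode, "_t"),
                  estimate = unname(if (mode == "unpaired")
                    diff(rev(ht$estimate)) else ht$estimate),
                  df = unname(ht$parameter))
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether a sample is symmetric about `mu`. Exact differences of
#' zero are dropped before ranking (their count is reported); the exact
#' null distribution is used for n <= 25 when the absolute differences are
#' untied, otherwise a normal approximation with continuity correction.
#'
#' @param x Numeric vector.
#' @param mu Hypothesised centre; default 0.
#' @return A `test_result` with `statistic` (V), `p_value`, `n` (after
#'   dropping zeros), `n_zero` and `exact` flag.
#' @export
wilcoxon_one_sample <- function(x, mu = 0) {
  x <- as.numeric(x)
  d <- x[!is.na(x)] - mu
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no non-zero differences")
  exact <- n <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  new_test_result(ht$statistic, ht$p.value, n,
                  method = "wilcoxon_signed_rank",
                  n_zero = n_zero, exact = exact)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across `k` groups followed by Dunn's
#' pairwise z-tests on mean ranks, with the pairwise p-values adjusted for
#' multiplicity (Benjamini-Hochberg by default, Bonferroni optionally).
#'
#' @param groups List of numeric vectors, one per group (named or not).
#' @param q Significance level applied to the adjusted pairwise p-values.
#' @param p_adjust Multiplicity adjustment across pairs: `"BH"` or
#'   `"bonferroni"`.
#' @return List with `kw` (a `test_result`) and `pairwise` (data frame of
#'   Dunn comparisons: groups, z, raw and adjusted p, significance flag).
#' @export
kruskal_dunn <- function(groups, q = 0.05, p_adjust = c("BH", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  groups <- groups[vapply(groups, length, 1L) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  kw <- stats::kruskal.test(x, grp)
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, grp, mean)
  n_i <- tabulate(grp)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[a] + 1 / n_i[b]))
    z[j] <- (mean_rank[a] - mean_rank[b]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- stats::p.adjust(p_raw, method = ifelse(p_adjust == "BH",
                                                  "BH", "bonferroni"))
  list(
    kw = new_test_result(kw$statistic, kw$p.value, n_i,
                         method = "kruskal_wallis", df = unname(kw$parameter)),
    pairwise = data.frame(
      group1 = names(groups)[pairs[1, ]],
      group2 = names(groups)[pairs[2, ]],
      z = z, p_raw = p_raw, p_adjusted = p_adj,
      significant = p_adj <= q,
      row.names = NULL))
}

#' Flatten a list of test results to a table
#'
#' @param tests List of `test_result` objects (optionally named).
#' @param fdr Optional `fdr_decision` aligned with `tests`.
#' @return Data frame with one row per test: method, statistic, n, p, and
#'   (if `fdr` given) adjusted p and rejection flag.
#' @export
test_table <- function(tests, fdr = NULL) {
  df <- data.frame(
    label = if (is.null(names(tests))) seq_along(tests) else names(tests),
    method = vapply(tests, function(t) t$method, ""),
    statistic = vapply(tests, function(t) t$statistic, 0),
    n = vapply(tests, function(t) paste(t$n, collapse = "/"), ""),
    p_value = vapply(tests, function(t) t$p_value, 0),
    row.names = NULL)
  if (!is.null(fdr)) {
    df$p_adjusted <- fdr$adjusted_p
    df$rejected <- fdr$rejected
  }
  df
}
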