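#' Analysis configuration for the unit-level connectivity chain
#'
#' @param bin_dt_s Spike-count bin width (default 50 ms).
#' @param smooth_sigma_bins Gaussian smoothing SD in bins (default 2,
#'   i.e. 100 ms at the default bin width).
#' @param kernel_truncation Kernel support in multiples of sigma.
#' @param fc_window_s,fc_step_s Correlation window and step (60 s / 30 s).
#' @param analysis_span_s Analysed span after each injection (900 s).
#' @param injection_lag_s Delay between the recorded injection time and
#'   the start of the analysed span (default 0).
#' @param clip_eps Passed to [fisher_z()].
#' @param average_on Average windowed values on the Fisher-z scale
#'   (`"z"`, default) or on the raw correlation scale (`"r"`).
#' @return An `npx_config` list.
#' @export
npx_config <- function(bin_dt_s = 0.05, smooth_sigma_bins = 2,
                       kernel_truncation = 4, fc_window_s = 60,
                       fc_step_s = 30, analysis_span_s = 900,
                       injection_lag_s = 0, clip_eps = 1e-7,
                       average_on = c("z", "r")) {
  stopifnot(bin_dt_s > 0, smooth_sigma_bins >= 0, kernel_truncation > 0,
            fc_window_s > 0, fc_step_s > 0, analysis_span_s >= fc_window_s,
            injection_lag_s >= 0)
  if (abs(fc_window_s / bin_dt_s - round(fc_window_s / bin_dt_s)) > 1e-9)
    stop("fc window must be a whole number of bins")
  structure(list(bin_dt_s = bin_dt_s, smooth_sigma_bins = smooth_sigma_bins,
                 kernel_truncation = kernel_truncation,
                 fc_window_s = fc_window_s, fc_step_s = fc_step_s,
                 analysis_span_s = analysis_span_s,
                 injection_lag_s = injection_lag_s, clip_eps = clip_eps,
                 average_on = match.arg(average_on)),
            class = "npx_config")
}

#' Bin spike times into counts
#'
#' Counts per half-open bin `[t, t + dt)` over a block `[start, end)`;
#' a trailing partial bin is dropped. Row order follows the dataset's
#' unit order.
#'
#' @param dataset A `spike_dataset`.
#' @param block Numeric `c(start_s, end_s)`.
#' @param bin_dt_s Bin width in seconds.
#' @return Integer matrix (units x bins) with unit ids as row names.
#' @export
bin_spikes <- function(dataset, block, bin_dt_s = 0.05) {
  stopifnot(inherits(dataset, "spike_dataset"), length(block) == 2L,
            bin_dt_s > 0)
  start <- block[1]; end <- block[2]
  n_bins <- floor((end - start) / bin_dt_s)
  if (n_bins < 1) stop("empty block: no complete bin fits")
  counts <- t(vapply(dataset$spikes, function(st) {
    st <- st[st >= start & st < start + n_bins * bin_dt_s]
    tabulate(floor((st - start) / bin_dt_s) + 1L, nbins = n_bins)
  }, integer(n_bins)))
  rownames(counts) <- dataset$units$unit_id
  counts
}

# Discrete Gaussian kernel, unit sum, truncated at +/- trunc*sigma.
gaussian_kernel <- function(sigma, trunc = 4) {
  h <- max(1L, ceiling(trunc * sigma))
  g <- stats::dnorm(-h:h, sd = sigma)
  g / sum(g)
}

#' Smooth binned counts and z-score per unit
#'
#' Each row is convolved with a discrete Gaussian kernel (unit sum,
#' truncated at `truncation * sigma`, reflected boundaries) and then
#' z-scored over the analysed span. Rows with zero variance (silent or
#' constant units) are flagged for exclusion rather than producing
#' non-finite values.
#'
#' @param counts Units x bins matrix from [bin_spikes()].
#' @param sigma_bins Kernel SD in bins; 0 skips smoothing.
#' @param truncation Kernel support in multiples of sigma.
#' @return List with `z` (units x bins matrix; excluded rows are `NA`),
#'   `excluded` (integer row indices with reasons as names).
#' @export
smooth_zscore <- function(counts, sigma_bins = 2, truncation = 4) {
  stopifnot(is.matrix(counts), sigma_bins >= 0)
  x <- counts * 1.0
  n <- ncol(x)
  if (sigma_bins > 0) {
    g <- gaussian_kernel(sigma_bins, truncation)
    h <- (length(g) - 1L) %/% 2L
    if (n <= h) stop("too few bins for the smoothing kernel")
    x <- .smooth_rows_reflect(x, g)
  }
  mu <- rowMeans(x)
  sdv <- sqrt(pmax(rowMeans(x^2) - mu^2, 0) * n / (n - 1))
  sdv[sdv < 1e-12 * (1 + abs(mu))] <- 0
  excluded <- which(sdv == 0)
  names(excluded) <- rep("zero variance", length(excluded))
  z <- (x - mu) / ifelse(sdv == 0, NA_real_, sdv)
  z[excluded, ] <- NA_real_
  list(z = z, excluded = excluded)
}

#' Windowed cross-region unit correlations
#'
#' Pearson correlation between every pair of one MOs unit and one SSp
#' unit over the bins of each sliding window, Fisher z-transformed.
#' Pairs with zero variance inside a window are marked missing.
#'
#' @param z_mos,z_ssp Units x bins matrices on the same bin grid (rows
#'   may contain `NA` for excluded units).
#' @param bin_dt_s Bin width (seconds).
#' @param fc_window_s,fc_step_s Window and step (seconds).
#' @param clip_eps Passed to [fisher_z()].
#' @return List with `window_start_s` and `z` (n_mos x n_ssp x window
#'   array).
#' @export
windowed_unit_fc <- function(z_mos, z_ssp, bin_dt_s = 0.05,
                             fc_window_s = 60, fc_step_s = 30,
                             clip_eps = 1e-7) {
  stopifnot(ncol(z_mos) == ncol(z_ssp), nrow(z_mos) >= 1, nrow(z_ssp) >= 1)
  W <- round(fc_window_s / bin_dt_s)
  S <- round(fc_step_s / bin_dt_s)
  n <- ncol(z_mos)
  if (n < W) stop("no complete window fits the span")
  n_win <- floor((n - W) / S) + 1L
  starts <- (seq_len(n_win) - 1L) * S
  out <- array(NA_real_, c(nrow(z_mos), nrow(z_ssp), n_win),
               dimnames = list(rownames(z_mos), rownames(z_ssp), NULL))
  for (w in seq_len(n_win)) {
    idx <- (starts[w] + 1L):(starts[w] + W)
    a <- t(z_mos[, idx, drop = FALSE])
    b <- t(z_ssp[, idx, drop = FALSE])
    r <- suppressWarnings(stats::cor(a, b))
    r[!is.finite(r)] <- NA  # zero-variance or excluded units
    zz <- fisher_z(r, clip_eps)
    dim(zz) <- dim(r)
    out[, , w] <- zz
  }
  list(window_start_s = starts * bin_dt_s, z = out)
}

#' Static and difference connectivity matrices with per-unit summaries
#'
#' Static fc per block = per-pair mean of the windowed values across
#' windows (missing windows excluded per pair; on the Fisher-z scale by
#' default). The difference matrix is drug-block static minus
#' vehicle-block static, and the per-unit effect of each MOs unit is the
#' mean of its difference row across all SSp units.
#'
#' @param wfc_vehicle,wfc_drug Results of [windowed_unit_fc()] for the
#'   vehicle and drug blocks (matched unit sets).
#' @param average_on `"z"` (default) averages Fisher-z values; `"r"`
#'   averages back-transformed correlations.
#' @return A `unit_fc_result`: `static_vehicle`, `static_drug`,
#'   `diff_fc`, `per_unit_delta` (named by MOs unit), `excluded_units`.
#' @export
static_and_diff_fc <- function(wfc_vehicle, wfc_drug, average_on = "z") {
  stopifnot(identical(dim(wfc_vehicle$z)[1:2], dim(wfc_drug$z)[1:2]))
  avg <- function(arr) {
    if (average_on == "r") arr <- tanh(arr)
    m <- apply(arr, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    if (average_on == "r") m <- fisher_z(m)
    m
  }
  sv <- avg(wfc_vehicle$z)
  sd_ <- avg(wfc_drug$z)
  diff_fc <- sd_ - sv
  # units observed in only one block propagate as NA rows/cols
  row_na <- apply(diff_fc, 1, function(v) all(is.na(v)))
  per_unit <- rowMeans(diff_fc, na.rm = TRUE)
  per_unit[row_na] <- NA_real_
  structure(list(static_vehicle = sv, static_drug = sd_, diff_fc = diff_fc,
                 per_unit_delta = per_unit,
                 excluded_units = rownames(diff_fc)[row_na]),
            class = "unit_fc_result")
}

#' Full unit-connectivity chain for one animal
#'
#' Runs binning, smoothing/z-scoring, windowed cross-region correlation
#' for the vehicle and drug blocks (the `analysis_span_s` following each
#' injection), and the static/difference summary. Units that are
#' zero-variance in either block are excluded from both.
#'
#' @param dataset A `spike_dataset` with `injections` (vehicle, drug).
#' @param config An `npx_config`.
#' @param within_region Also compute the within-region (MOs-MOs upper
#'   triangle) analogue used as a negative control.
#' @return List with `result` (a `unit_fc_result`), `windows` (per-block
#'   [windowed_unit_fc()] outputs), `excluded`, and optionally `within`.
#' @export
npx_unit_fc <- function(dataset, config = npx_config(),
                        within_region = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  inj <- dataset$injections
  spans <- lapply(inj$time_s + config$injection_lag_s,
                  function(t0) c(t0, t0 + config$analysis_span_s))
  names(spans) <- inj$label
  mos <- dataset$units$region == "MOs"
  ssp <- dataset$units$region == "SSp"
  if (!any(mos) || !any(ssp)) stop("need units in both MOs and SSp")
  prep <- lapply(spans, function(sp) {
    counts <- bin_spikes(dataset, sp, config$bin_dt_s)
    smooth_zscore(counts, config$smooth_sigma_bins,
                  config$kernel_truncation)
  })
  excluded <- sort(unique(unlist(lapply(prep, `[[`, "excluded"))))
  keep <- setdiff(seq_len(nrow(dataset$units)), excluded)
  wfc <- lapply(prep, function(p) {
    z <- p$z
    z[setdiff(seq_len(nrow(z)), keep), ] <- NA_real_
    windowed_unit_fc(z[mos, , drop = FALSE], z[ssp, , drop = FALSE],
                     config$bin_dt_s, config$fc_window_s, config$fc_step_s,
                     config$clip_eps)
  })
  res <- static_and_diff_fc(wfc$vehicle, wfc$drug, config$average_on)
  out <- list(result = res, windows = wfc,
              excluded = dataset$units$unit_id[excluded])
  if (within_region) {
    wfc_w <- lapply(prep, function(p) {
      z <- p$z
      z[setdiff(seq_len(nrow(z)), keep), ] <- NA_real_
      windowed_unit_fc(z[mos, , drop = FALSE], z[mos, , drop = FALSE],
                       config$bin_dt_s, config$fc_window_s,
                       config$fc_step_s, config$clip_eps)
    })
    ww <- static_and_diff_fc(wfc_w$vehicle, wfc_w$drug, config$average_on)
    # drop self-pairs from the per-unit summary
    diag(ww$diff_fc) <- NA
    rn <- apply(ww$diff_fc, 1, function(v) all(is.na(v)))
    ww$per_unit_delta <- rowMeans(ww$diff_fc, na.rm = TRUE)
    ww$per_unit_delta[rn] <- NA_real_
    out$within <- ww
  }
  out
}

#' Pooled per-unit deltas of a cohort
#'
#' @param cohort List of [gen_spikes()]-style results or bare
#'   `spike_dataset`s.
#' @param config An `npx_config`.
#' @return Numeric vector of per-unit deltas pooled across animals
#'   (NA-free), named `animal.unit`.
#' @export
cohort_unit_deltas <- function(cohort, config = npx_config()) {
  ds <- lapply(cohort, function(x)
    if (inherits(x, "spike_dataset")) x else x$dataset)
  out <- lapply(seq_along(ds), function(i) {
    d <- npx_unit_fc(ds[[i]], config)$result$per_unit_delta
    stats::setNames(d, paste0("a", i, ".", names(d)))
  })
  v <- unlist(out)
  v[!is.na(v)]
}

#' Group comparison of per-unit connectivity changes
#'
#' Mirrors the unit-level statistics of the dual-probe analysis: a
#' two-sided one-sample Wilcoxon signed-rank test of each group's pooled
#' per-unit deltas against zero, and a Kruskal-Wallis test with Dunn's
#' post-hoc comparisons across groups.
#'
#' @param deltas_by_group Named list of numeric vectors (per-unit deltas
#'   pooled over animals within each group).
#' @param q Significance level for the adjusted pairwise p-values.
#' @return List with `per_group` (data frame: group, n units, median,
#'   Wilcoxon V and p, flag), `kw` (a `test_result`) and `dunn`
#'   (pairwise data frame) when >= 2 groups are supplied.
#' @export
group_compare <- function(deltas_by_group, q = 0.05) {
  stopifnot(is.list(deltas_by_group), length(deltas_by_group) >= 1)
  per_group <- do.call(rbind, lapply(names(deltas_by_group), function(g) {
    d <- deltas_by_group[[g]]
    d <- d[!is.na(d)]
    wt <- tryCatch(wilcoxon_one_sample(d, 0), error = function(e) NULL)
    data.frame(group = g, n_units = length(d),
               median_delta = stats::median(d),
               statistic = if (is.null(wt)) NA_real_ else wt$statistic,
               p_value = if (is.null(wt)) NA_real_ else wt$p_value,
               significant = if (is.null(wt)) FALSE else wt$p_value <= q,
               degenerate = is.null(wt))
  }))
  out <- list(per_group = per_group)
  if (length(deltas_by_group) >= 2) {
    kd <- kruskal_dunn(deltas_by_group, q = q)
    out$kw <- kd$kw
    out$dunn <- kd$pairwise
  }
  out
}
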