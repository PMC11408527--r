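#' Analysis configuration for the pfUS chain
#'
#' @param band_low_hz,band_high_hz Band-pass edges for the connectivity
#'   analysis (defaults 0.01 and 0.2 Hz).
#' @param baseline_span_s Baseline span ending at the drug challenge (the
#'   final 5 min before the challenge by default).
#' @param fc_window_s,fc_step_s Sliding-window length and step for the
#'   regional connectivity (defaults 300 s / 60 s).
#' @param despike_k MAD multiplier of the artifact detector.
#' @param cbv_bin_s Bin width for the CBV change series and its tests.
#' @param q FDR level for the window-wise tests.
#' @return A `pfus_config` list.
#' @export
pfus_config <- function(band_low_hz = 0.01, band_high_hz = 0.2,
                        baseline_span_s = 300,
                        fc_window_s = 300, fc_step_s = 60,
                        despike_k = 5, cbv_bin_s = 60, q = 0.05) {
  stopifnot(band_low_hz > 0, band_low_hz < band_high_hz,
            baseline_span_s > 0, fc_window_s > 0, fc_step_s > 0,
            despike_k > 0, cbv_bin_s > 0, q > 0, q < 1)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 baseline_span_s = baseline_span_s,
                 fc_window_s = fc_window_s, fc_step_s = fc_step_s,
                 despike_k = despike_k, cbv_bin_s = cbv_bin_s, q = q),
            class = "pfus_config")
}

#' Remove transient artifacts from a power-Doppler trace
#'
#' Hampel-style detector: samples deviating from an 11-sample rolling
#' median by more than `k` times the rolling MAD (scaled to be consistent
#' with a Gaussian SD, floored at a small epsilon) are flagged and
#' replaced by linear interpolation between the nearest unflagged
#' neighbours; flagged edge samples take the nearest unflagged value.
#'
#' @param trace Numeric vector, length >= 11.
#' @param k MAD multiplier (default 5).
#' @param window Rolling-median window length (odd; default 11).
#' @param scale_window Window for the rolling MAD scale estimate (odd;
#'   default 101). A short window here makes the scale estimate itself so
#'   noisy that a 5-MAD threshold fires on about 1% of clean samples; a
#'   longer window keeps the false-flag rate at the Gaussian tail level
#'   while still tracking slow changes in local scatter.
#' @return List with `trace` (cleaned) and `mask` (logical, flagged
#'   samples). Warns if more than 20% of samples are flagged.
#' @export
despike <- function(trace, k = 5, window = 11L, scale_window = 101L) {
  stopifnot(is.numeric(trace), k > 0, window %% 2 == 1)
  n <- length(trace)
  if (n < window) stop("trace shorter than the despiking window")
  sw <- min(scale_window, if (n %% 2 == 1) n else n - 1L)
  if (sw %% 2 == 0) sw <- sw - 1L
  med <- stats::runmed(trace, window, endrule = "median")
  dev <- trace - med
  sigma <- 1.4826 * stats::runmed(abs(dev), sw, endrule = "median")
  eps <- 1e-10 * (1 + stats::median(abs(trace)))
  mask <- abs(dev) > k * pmax(sigma, eps)
  if (all(mask)) stop("all samples flagged as artifacts")
  if (mean(mask) > 0.2)
    warning(sprintf("despike: %.1f%% of samples flagged", 100 * mean(mask)))
  clean <- trace
  if (any(mask)) {
    keep <- which(!mask)
    clean[mask] <- stats::approx(keep, trace[keep], xout = which(mask),
                                 rule = 2)$y
  }
  list(trace = clean, mask = mask)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 2nd-order Butterworth band-pass, the
#' filtering applied to despiked traces before windowed connectivity. DC
#' is removed; the output has the same length as the input and no phase
#' shift, so window timing is preserved.
#'
#' @param trace Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param low,high Pass-band edges (Hz), `low < high < fs/2`.
#' @return Filtered numeric vector.
#' @export
bandpass <- function(trace, fs, low = 0.01, high = 0.2) {
  stopifnot(low > 0, low < high, high < fs / 2)
  min_len <- 3L * ceiling(fs / low)
  if (length(trace) < min_len)
    stop("trace too short for band: need at least ", min_len, " samples")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding suppresses the start-up transient of the
  # forward-backward pass, which would otherwise leak a large shared
  # component into the first and last correlation windows
  n <- length(trace)
  pad <- min(n - 1L, 3L * ceiling(fs / low))
  ext <- c(2 * trace[1] - trace[(pad + 1):2], trace,
           2 * trace[n] - trace[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(pad + 1):(pad + n)]
}

#' Percent CBV change of one subject relative to the pre-challenge baseline
#'
#' Operates on despiked, unfiltered traces. The baseline B is the mean
#' over the final `baseline_span_s` before the drug challenge;
#' `dCBV/CBV(t) = 100 (x(t) - B)/B`. The series is also averaged into
#' `cbv_bin_s` bins for plotting and for the group-level bin tests.
#'
#' @param tc_set A `roi_timecourse_set` (traces already despiked).
#' @param config A `pfus_config`.
#' @return List with `pct` (samples x ROI matrix, %), `binned` (bins x
#'   ROI), `bin_start_s`, `baseline` (per-ROI B), `events`.
#' @export
delta_cbv <- function(tc_set, config = pfus_config()) {
  x <- tc_set$traces
  fs <- tc_set$fs
  drug <- tc_set$events$drug_time_s
  b0 <- drug - config$baseline_span_s
  if (b0 < 0) stop("baseline span starts before the recording")
  idx_base <- which(tc_set$time_s >= b0 & tc_set$time_s < drug)
  B <- colMeans(x[idx_base, , drop = FALSE])
  if (any(B <= 0)) stop("non-positive baseline")
  pct <- 100 * sweep(sweep(x, 2, B, `-`), 2, B, `/`)
  bin <- floor(tc_set$time_s / config$cbv_bin_s)
  binned <- apply(pct, 2, function(col) tapply(col, bin, mean))
  list(pct = pct, binned = binned,
       bin_start_s = as.numeric(rownames(binned)) * config$cbv_bin_s,
       baseline = B, events = tc_set$events)
}

#' Sliding-window regional connectivity
#'
#' For each window of `fc_window_s` advanced by `fc_step_s`, the pairwise
#' Pearson correlation between all ROI columns over the in-window samples,
#' Fisher z-transformed. Pairs with zero variance inside a window are
#' marked missing and excluded from all downstream averages.
#'
#' @param traces Samples x ROI matrix (despiked, band-passed).
#' @param fs Sampling rate (Hz).
#' @param fc_window_s,fc_step_s Window length and step (seconds).
#' @param clip_eps Passed to [fisher_z()].
#' @return An `fc_window_series`: list with `window_start_s`, `z` (ROI x
#'   ROI x window array, diagonal `NA`), `n_samples_per_window`.
#' @export
windowed_regional_fc <- function(traces, fs, fc_window_s = 300,
                                 fc_step_s = 60, clip_eps = 1e-7) {
  stopifnot(is.matrix(traces), ncol(traces) >= 2)
  W <- round(fc_window_s * fs)
  S <- round(fc_step_s * fs)
  n <- nrow(traces)
  if (W < 4) stop("window too short: need at least 4 samples")
  if (n < W) stop("no complete window fits the trace")
  n_win <- floor((n - W) / S) + 1L
  R <- ncol(traces)
  z <- array(NA_real_, c(R, R, n_win),
             dimnames = list(colnames(traces), colnames(traces), NULL))
  starts <- (seq_len(n_win) - 1L) * S
  for (w in seq_len(n_win)) {
    idx <- (starts[w] + 1L):(starts[w] + W)
    xw <- traces[idx, , drop = FALSE]
    sds <- apply(xw, 2, stats::sd)
    r <- suppressWarnings(stats::cor(xw))
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
    zw <- fisher_z(r, clip_eps)
    dim(zw) <- c(R, R)
    diag(zw) <- NA
    z[, , w] <- zw
  }
  structure(list(window_start_s = starts / fs, z = z,
                 n_samples_per_window = W,
                 fc_window_s = fc_window_s, fc_step_s = fc_step_s),
            class = "fc_window_series")
}

#' Regional connectivity strength per window
#'
#' Mean Fisher z over all edges incident to one ROI (7 edges in the
#' standard 8-ROI set), per window; missing edges are excluded, and a
#' window with no observed incident edge yields `NA`.
#'
#' @param fcs An `fc_window_series`.
#' @param roi ROI label (must match a dimension name).
#' @return Numeric vector, one value per window.
#' @export
regional_strength <- function(fcs, roi) {
  labs <- dimnames(fcs$z)[[1]]
  i <- match(roi, labs)
  if (is.na(i)) stop("unknown ROI: ", roi)
  apply(fcs$z[i, -i, , drop = FALSE], 3, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

# Mean z over all edges between two ROI label sets, per window.
cross_group_fc <- function(fcs, set_a, set_b) {
  labs <- dimnames(fcs$z)[[1]]
  ia <- match(set_a, labs); ib <- match(set_b, labs)
  if (any(is.na(c(ia, ib)))) stop("ROI set contains unknown labels")
  apply(fcs$z[ia, ib, , drop = FALSE], 3, function(m) {
    if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  })
}

#' Baseline-referenced PFC-SM connectivity change of a cohort
#'
#' Per subject and window: the mean Fisher z over all PFC x SM edges; the
#' change `dz(w)` is referenced to the final pre-challenge window (the
#' window whose span is the last `fc_window_s` before the drug time).
#' Group statistics: per-window paired t-tests of the windowed value
#' against each subject's own baseline value, BH-FDR-corrected across
#' windows; per-subject AUC of the post-drug `dz` (trapezoid over window
#' start times from the drug time to the end).
#'
#' @param fcs_list List of `fc_window_series`, one per subject (identical
#'   window grids).
#' @param events List with `drug_time_s` (and `duration_s`).
#' @param groups List with `pfc` and `sm` label vectors; default
#'   [pfus_roi_groups()].
#' @param config A `pfus_config` (for `q`).
#' @return A `delta_summary` list: `window_start_s`, `dz` (subject x
#'   window), `mean_dz`, `baseline_window`, `auc` (per subject),
#'   `tests` (window test table with FDR flags), `post_drug` (logical per
#'   window).
#' @export
group_delta_fc <- function(fcs_list, events, groups = pfus_roi_groups(),
                           config = pfus_config()) {
  stopifnot(length(fcs_list) >= 1)
  starts <- fcs_list[[1]]$window_start_s
  W <- fcs_list[[1]]$fc_window_s
  vals <- t(vapply(fcs_list, cross_group_fc, numeric(length(starts)),
                   set_a = groups$pfc, set_b = groups$sm))
  wb <- which(abs(starts - (events$drug_time_s - W)) < 1e-9)
  if (length(wb) != 1L) stop("baseline window not computable from grid")
  dz <- vals - vals[, wb]
  post <- starts >= events$drug_time_s
  n_sub <- nrow(vals)
  test_idx <- setdiff(seq_along(starts), wb)
  tests <- NULL
  fdr <- NULL
  if (n_sub >= 2) {
    tests <- lapply(test_idx, function(w)
      tryCatch(t_test(vals[, w], vals[, wb], mode = "paired"),
               error = function(e) new_test_result(
                 NA_real_, NA_real_, n_sub, "paired_t")))
    fdr <- bh_fdr(vapply(tests, `[[`, 0, "p_value"), q = config$q)
    tests <- test_table(stats::setNames(tests, sprintf("w%03d", test_idx)),
                        fdr)
    tests$window_start_s <- starts[test_idx]
    tests$post_drug <- post[test_idx]
  }
  auc <- if (any(post)) apply(dz[, post, drop = FALSE], 1, function(y)
    trapz_integral(starts[post], y)) else rep(NA_real_, n_sub)
  structure(list(window_start_s = starts, dz = dz,
                 mean_dz = colMeans(dz), baseline_window = wb,
                 auc = auc, tests = tests, fdr = fdr, post_drug = post,
                 events = events),
            class = "delta_summary")
}

#' Full pfUS pipeline for one subject
#'
#' Despikes every ROI trace, band-passes for connectivity, computes the
#' CBV change summary from the despiked unfiltered traces and the
#' sliding-window regional connectivity from the filtered traces.
#'
#' @param tc_set A `roi_timecourse_set`.
#' @param config A `pfus_config`.
#' @return List with `despiked` (matrix), `masks` (logical matrix),
#'   `filtered`, `cbv` (from [delta_cbv()]), `fc` (an
#'   `fc_window_series`).
#' @export
pfus_subject_pipeline <- function(tc_set, config = pfus_config()) {
  raw <- tc_set$traces
  ds <- apply(raw, 2, despike, k = config$despike_k, simplify = FALSE)
  clean <- vapply(ds, `[[`, numeric(nrow(raw)), "trace")
  masks <- vapply(ds, `[[`, logical(nrow(raw)), "mask")
  tc_clean <- tc_set
  tc_clean$traces <- clean
  filt <- apply(clean, 2, bandpass, fs = tc_set$fs,
                low = config$band_low_hz, high = config$band_high_hz)
  colnames(filt) <- colnames(raw)
  list(despiked = clean, masks = masks, filtered = filt,
       cbv = delta_cbv(tc_clean, config),
       fc = windowed_regional_fc(filt, tc_set$fs, config$fc_window_s,
                                 config$fc_step_s))
}

#' Group-level CBV bin tests against baseline
#'
#' For each ROI and time bin, a paired t-test across subjects of the
#' binned raw CBV values against each subject's own baseline mean, with
#' BH-FDR correction across the whole ROI x bin family.
#'
#' @param cbv_list List of [delta_cbv()] results (one per subject).
#' @param config A `pfus_config`.
#' @return Data frame: roi, bin_start_s, t statistic, p, adjusted p,
#'   rejected.
#' @export
cbv_group_tests <- function(cbv_list, config = pfus_config()) {
  stopifnot(length(cbv_list) >= 2)
  bins <- cbv_list[[1]]$bin_start_s
  rois <- colnames(cbv_list[[1]]$binned)
  rows <- list()
  for (r in rois) {
    mat <- vapply(cbv_list, function(cb) cb$binned[, r], numeric(length(bins)))
    for (b in seq_along(bins)) {
      tr <- tryCatch(t_test(mat[b, ], rep(0, ncol(mat)), mode = "paired"),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, bin_start_s = bins[b],
        statistic = if (is.null(tr)) NA_real_ else tr$statistic,
        p_value = if (is.null(tr)) NA_real_ else tr$p_value)
    }
  }
  df <- do.call(rbind, rows)
  ok <- !is.na(df$p_value)
  fdr <- bh_fdr(df$p_value[ok], q = config$q)
  df$p_adjusted <- NA_real_; df$rejected <- NA
  df$p_adjusted[ok] <- fdr$adjusted_p
  df$rejected[ok] <- fdr$rejected
  df
}
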