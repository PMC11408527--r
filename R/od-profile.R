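#' Rectangle specification for optical-density profiling
#'
#' Defines the rectangular region placed over the structure of interest
#' on an autoradiograph and how its line profile is summarised: the mean
#' intensity trace runs along `axis`, the central `center_fraction` of
#' the trace is treated as the peak (signal) span and the two flanks
#' outside it provide the baseline.
#'
#' @param x0,y0 Top-left corner (1-based pixel indices; x = column,
#'   y = row).
#' @param width,height Rectangle extent in pixels.
#' @param axis Profile axis: `"x"` (trace along columns, averaged over
#'   rows) or `"y"`.
#' @param center_fraction Fraction of the trace treated as the peak span
#'   (default 0.4).
#' @param invert Negate intensities on input (for film scans where
#'   stronger signal is darker).
#' @return A `profile_spec` list.
#' @export
profile_spec <- function(x0, y0, width, height, axis = c("x", "y"),
                         center_fraction = 0.4, invert = FALSE) {
  axis <- match.arg(axis)
  stopifnot(x0 >= 1, y0 >= 1, width >= 1, height >= 1,
            center_fraction > 0, center_fraction < 1)
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 axis = axis, center_fraction = center_fraction,
                 invert = invert),
            class = "profile_spec")
}

#' Mean-intensity line profile over a rectangle
#'
#' The average of pixel intensities across the rectangle's short axis at
#' each position along the profile axis -- the plot-profile trace used to
#' quantify expression signal on autoradiographs.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param spec A `profile_spec`.
#' @return Numeric vector of mean intensities, length = rectangle extent
#'   along the profile axis.
#' @export
line_profile <- function(image, spec) {
  stopifnot(is.matrix(image), inherits(spec, "profile_spec"))
  x1 <- spec$x0 + spec$width - 1L
  y1 <- spec$y0 + spec$height - 1L
  if (x1 > ncol(image) || y1 > nrow(image))
    stop("rectangle outside image")
  sub <- image[spec$y0:y1, spec$x0:x1, drop = FALSE]
  if (spec$invert) sub <- -sub
  if (spec$axis == "x") colMeans(sub) else rowMeans(sub)
}

#' Baseline-subtracted area under the central profile peak
#'
#' The baseline is the median of the two flank segments outside the
#' central `center_fraction` span; the AUC is the trapezoidal integral
#' over the central span of the baseline-subtracted profile floored at
#' zero (intensity x pixels).
#'
#' @param profile Numeric trace from [line_profile()] (length >= 5).
#' @param spec A `profile_spec` (for `center_fraction`).
#' @return An `od_result` list: `profile`, `baseline_level`, `auc`,
#'   `center_idx` (indices of the central span).
#' @export
profile_auc <- function(profile, spec = profile_spec(1, 1, length(profile), 1)) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  half <- spec$center_fraction / 2
  pos <- (seq_len(n) - 0.5) / n
  center <- which(pos >= 0.5 - half & pos <= 0.5 + half)
  flanks <- setdiff(seq_len(n), center)
  if (length(flanks) == 0) stop("flanks empty")
  baseline <- stats::median(profile[flanks])
  elevated <- pmax(profile[center] - baseline, 0)
  auc <- trapz_integral(as.numeric(center), elevated)
  structure(list(profile = profile, baseline_level = baseline,
                 auc = auc, center_idx = center),
            class = "od_result")
}

#' Fold change of a case AUC relative to the control mean
#'
#' @param auc_case Case AUC (>= 0).
#' @param auc_control_mean Mean AUC of the control group (> 0).
#' @return `auc_case / auc_control_mean`.
#' @export
fold_change <- function(auc_case, auc_control_mean) {
  if (!is.finite(auc_control_mean) || auc_control_mean <= 0)
    stop("control mean must be positive")
  auc_case / auc_control_mean
}
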