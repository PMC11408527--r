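# Plain-text readers and writers: timecourse TSV + events JSON, spike CSV,
# 16-bit TIFF images, rectangle JSON. Every written table carries a header
# comment with the package version and, when known, the generating seed.

output_header <- function(seed = NULL, extra = NULL) {
  v <- as.character(utils::packageVersion("clawfc"))
  h <- sprintf("# clawfc version=%s", v)
  if (!is.null(seed)) h <- paste0(h, sprintf(" seed=%s", seed))
  if (!is.null(extra)) h <- paste0(h, " ", extra)
  h
}

#' Write a regional timecourse set to TSV (+ events JSON)
#'
#' @param tc_set A `roi_timecourse_set`.
#' @param path Output TSV path; the events are written next to it as
#'   `<path stem>_events.json`.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, the TSV path.
#' @export
write_timecourses <- function(tc_set, path, seed = NULL) {
  df <- data.frame(time_s = tc_set$time_s, tc_set$traces,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, sprintf("subject=%s", tc_set$subject_id)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  ev_path <- sub("\\.tsv$", "", path)
  jsonlite::write_json(tc_set$events, paste0(ev_path, "_events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a regional timecourse set from TSV (+ events JSON)
#'
#' The sampling rate is inferred from the time column, which must be
#' uniform to a relative tolerance of 1e-6. ROI column names of the form
#' `REGION_HEMI` (e.g. `MOs_L`) are parsed into region and hemisphere.
#'
#' @param path TSV path written by [write_timecourses()] (or matching its
#'   schema: a `time_s` column plus one column per ROI).
#' @param events_path Events JSON; defaults to `<path stem>_events.json`.
#' @return A `roi_timecourse_set`.
#' @export
read_timecourses <- function(path, events_path = NULL) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  if (ncol(df) < 3) stop("need at least 2 ROI columns")
  tv <- df$time_s
  dt <- diff(tv)
  if (length(dt) < 1 || any(dt <= 0) ||
      (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("non-uniform sampling in time column")
  traces <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  if (any(!is.finite(traces))) stop("non-finite values in traces")
  if (is.null(events_path))
    events_path <- paste0(sub("\\.tsv$", "", path), "_events.json")
  events <- jsonlite::read_json(events_path, simplifyVector = TRUE)
  labels <- colnames(traces)
  parts <- strsplit(labels, "_", fixed = TRUE)
  roi_info <- data.frame(
    label = labels,
    region = vapply(parts, `[`, "", 1),
    hemisphere = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""))
  structure(list(subject_id = sub("\\.tsv$", "", basename(path)),
                 fs = 1 / stats::median(dt), time_s = tv, traces = traces,
                 roi_labels = labels, roi_info = roi_info, events = events),
            class = "roi_timecourse_set")
}

#' Write a spike dataset to CSV (+ blocks JSON)
#'
#' @param dataset A `spike_dataset`.
#' @param path Output CSV (`unit_id, region, time_s`); blocks and
#'   injections go to `<path stem>_events.json`.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, the CSV path.
#' @export
write_spikes <- function(dataset, path, seed = NULL) {
  n_sp <- vapply(dataset$spikes, length, 1L)
  df <- data.frame(
    unit_id = rep(dataset$units$unit_id, n_sp),
    region = rep(dataset$units$region, n_sp),
    time_s = unlist(dataset$spikes, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, sprintf("group=%s", dataset$group_label)),
             con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(blocks = dataset$blocks, injections = dataset$injections,
         duration_s = dataset$duration_s,
         group_label = dataset$group_label),
    paste0(sub("\\.csv$", "", path), "_events.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spike dataset from CSV (+ blocks JSON)
#'
#' Spike times are sorted per unit (with a warning if the file was
#' unsorted); exact duplicate (unit, time) rows are dropped with a
#' message. Regions are validated against the declared set.
#'
#' @param path CSV with columns `unit_id, region, time_s`.
#' @param events_path Blocks/injections JSON; defaults to
#'   `<path stem>_events.json`.
#' @param regions Allowed region labels.
#' @return A `spike_dataset`.
#' @export
read_spikes <- function(path, events_path = NULL,
                        regions = c("MOs", "SSp")) {
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(events_path))
    events_path <- paste0(sub("\\.csv$", "", path), "_events.json")
  ev <- jsonlite::read_json(events_path, simplifyVector = TRUE)
  if (nrow(df) > 0 && !all(df$region %in% regions))
    stop("unknown region label(s): ",
         paste(setdiff(unique(df$region), regions), collapse = ", "))
  dup <- duplicated(df[, c("unit_id", "time_s")])
  if (any(dup)) {
    message(sum(dup), " duplicate (unit, time) rows dropped")
    df <- df[!dup, , drop = FALSE]
  }
  units <- unique(df[, c("unit_id", "region")])
  units <- units[order(units$unit_id), , drop = FALSE]
  rownames(units) <- NULL
  spikes <- lapply(units$unit_id, function(u) df$time_s[df$unit_id == u])
  unsorted <- any(vapply(spikes, is.unsorted, TRUE))
  if (unsorted) {
    warning("unsorted spike times; sorting")
    spikes <- lapply(spikes, sort)
  }
  structure(list(units = units,
                 spikes = stats::setNames(spikes, units$unit_id),
                 blocks = as.data.frame(ev$blocks),
                 injections = as.data.frame(ev$injections),
                 duration_s = ev$duration_s,
                 group_label = ev$group_label %||% "unknown"),
            class = "spike_dataset")
}

#' Write a grayscale image as 16-bit TIFF
#'
#' @param image Numeric matrix in arbitrary intensity units.
#' @param path Output path.
#' @param max_intensity Intensity mapped to the 16-bit ceiling.
#' @return Invisibly, the path.
#' @export
write_od_image <- function(image, path, max_intensity = 65535) {
  img <- pmin(pmax(image / max_intensity, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale image from TIFF or PNG
#'
#' @param path Image path (`.tif`/`.tiff` or `.png`).
#' @param max_intensity Intensity the unit-scaled ceiling maps back to.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
read_od_image <- function(path, max_intensity = 65535) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("png package required to read PNG images")
    png::readPNG(path)
  } else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * max_intensity
}

#' Read a rectangle annotation from JSON
#'
#' @param path JSON with fields `x0, y0, width, height` and optionally
#'   `axis`, `center_fraction`, `invert`.
#' @return A `profile_spec`.
#' @export
read_rectangle <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile_spec(r$x0, r$y0, r$width, r$height,
               axis = r$axis %||% "x",
               center_fraction = r$center_fraction %||% 0.4,
               invert = isTRUE(r$invert))
}
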