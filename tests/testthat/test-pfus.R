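test_that("despike leaves clean traces alone and repairs inserted bursts", {
  expect_identical(despike(rep(5, 100))$mask, rep(FALSE, 100))
  set.seed(3)
  clean <- 100 * (1 + 0.05 * clawfc:::ou_path(600, 1, 5) + 0.01 * rnorm(600))
  burst_at <- c(1L, 250L)           # one edge burst, one interior burst
  dirty <- clean
  dirty[burst_at] <- dirty[burst_at] * 10
  d <- despike(dirty, k = 5)
  expect_true(all(burst_at %in% which(d$mask)))
  rmse <- function(x) sqrt(mean((x - clean)^2))
  expect_lt(rmse(d$trace), 0.5 * rmse(dirty))
  # the edge burst is replaced by the nearest unflagged value
  first_clean <- which(!d$mask)[1]
  expect_equal(d$trace[1], d$trace[first_clean])
})

test_that("despike warns on heavy contamination and rejects tiny traces", {
  set.seed(4)
  x <- rnorm(200)
  x[sample(200, 80)] <- x[sample(200, 80)] + 50
  expect_warning(despike(x, k = 3), "flagged")
  expect_error(despike(rnorm(5)), "shorter")
})

test_that("bandpass blocks DC, passes the band, attenuates above it", {
  expect_lt(max(abs(bandpass(rep(7, 2400), fs = 1))), 1e-6 * 7)
  t <- 0:2399
  amp_of <- function(f) {
    y <- bandpass(sin(2 * pi * f * t), fs = 1)
    mid <- y[800:1600]  # steady-state section
    2 * sqrt(mean(mid^2)) / sqrt(2)
  }
  expect_gte(amp_of(0.05), 0.9)
  expect_lte(amp_of(0.4), 0.1)
  expect_error(bandpass(rnorm(100), fs = 1), "too short")
})

make_tc <- function(traces, fs = 1, drug = 1200, dur = nrow(traces)) {
  structure(list(subject_id = "t", fs = fs,
                 time_s = (seq_len(nrow(traces)) - 1) / fs,
                 traces = traces, roi_labels = colnames(traces),
                 events = list(vehicle_time_s = 300, drug_time_s = drug,
                               duration_s = dur)),
            class = "roi_timecourse_set")
}

test_that("delta_cbv is exact on constant and step traces", {
  x <- matrix(100, 2400, 2, dimnames = list(NULL, c("A", "B")))
  cb <- delta_cbv(make_tc(x))
  expect_true(all(cb$pct == 0))
  step <- x
  step[1201:2400, ] <- 110
  cb2 <- delta_cbv(make_tc(step))
  expect_true(all(abs(cb2$binned[cb2$bin_start_s >= 1200, ] - 10) < 1e-12))
  expect_true(all(abs(cb2$binned[cb2$bin_start_s < 1200, ]) < 1e-12))
  bad <- x; bad[, 1] <- -1
  expect_error(delta_cbv(make_tc(bad)), "non-positive baseline")
})

test_that("windowed fc: window arithmetic and duplicated-trace ceiling", {
  set.seed(5)
  tr <- matrix(rnorm(2400 * 2), ncol = 2,
               dimnames = list(NULL, c("A", "B")))
  fc <- windowed_regional_fc(tr, fs = 1, fc_window_s = 300, fc_step_s = 60)
  expect_length(fc$window_start_s, 36L)
  dup <- cbind(A = tr[, 1], B = tr[, 1])
  fcd <- windowed_regional_fc(dup, fs = 1)
  expect_true(all(abs(fcd$z[1, 2, ] - fisher_z(1)) < 1e-9))
  expect_error(windowed_regional_fc(tr[1:100, ], fs = 1, fc_window_s = 300),
               "no complete window")
})

test_that("windowed fc equals the direct-summation oracle", {
  set.seed(6)
  tr <- matrix(rnorm(700 * 4), ncol = 4,
               dimnames = list(NULL, paste0("R", 1:4)))
  fc <- windowed_regional_fc(tr, fs = 1, fc_window_s = 100, fc_step_s = 50)
  orc <- oracle_windowed_z(tr, tr, 100, 50)
  for (w in seq_along(fc$window_start_s)) {
    got <- fc$z[, , w]; want <- orc[, , w]
    diag(want) <- NA
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("zero-variance pairs are missing, not zero", {
  set.seed(7)
  tr <- cbind(A = rnorm(400), B = rnorm(400), C = rep(1, 400))
  fc <- windowed_regional_fc(tr, fs = 1, fc_window_s = 100, fc_step_s = 100)
  expect_true(all(is.na(fc$z[3, , ])))
  expect_true(all(is.finite(fc$z[1, 2, ])))
  s <- regional_strength(fc, "A")     # mean over observed edges only
  expect_equal(s, fc$z[1, 2, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("regional strength averages the incident edges", {
  z <- array(0.3, c(8, 8, 4),
             dimnames = list(pfus_roi_labels(), pfus_roi_labels(), NULL))
  for (w in 1:4) diag(z[, , w]) <- NA
  fcs <- structure(list(window_start_s = c(0, 60, 120, 180), z = z,
                        fc_window_s = 300, fc_step_s = 60),
                   class = "fc_window_series")
  expect_equal(regional_strength(fcs, "MOs_L"), rep(0.3, 4))
  # against a direct edge-list mean on random data
  set.seed(8)
  tr <- matrix(rnorm(500 * 4), ncol = 4,
               dimnames = list(NULL, paste0("R", 1:4)))
  fc <- windowed_regional_fc(tr, fs = 1, fc_window_s = 125, fc_step_s = 125)
  manual <- apply(fc$z[2, -2, , drop = FALSE], 3, mean)
  expect_equal(regional_strength(fc, "R2"), manual, tolerance = 1e-12)
})

# Build an fc_window_series whose PFC-SM mean takes prescribed values.
make_fcs <- function(vals, starts, window_s = 300) {
  R <- 8
  z <- array(NA_real_, c(R, R, length(vals)),
             dimnames = list(pfus_roi_labels(), pfus_roi_labels(), NULL))
  for (w in seq_along(vals)) {
    m <- matrix(vals[w], R, R)
    diag(m) <- NA
    z[, , w] <- m
  }
  structure(list(window_start_s = starts, z = z, fc_window_s = window_s,
                 fc_step_s = diff(starts)[1]),
            class = "fc_window_series")
}

test_that("group_delta_fc: identical windows give zero delta and AUC", {
  starts <- seq(0, 1500, by = 60)
  fcs <- make_fcs(rep(0.4, length(starts)), starts)
  events <- list(drug_time_s = 300, duration_s = 1800)
  gd <- group_delta_fc(list(fcs, fcs), events)
  expect_true(all(gd$dz == 0))
  expect_equal(unname(gd$auc), c(0, 0))
})

test_that("group_delta_fc: constant post-drug shift integrates exactly", {
  starts <- seq(0, 1500, by = 60)
  events <- list(drug_time_s = 300, duration_s = 1800)
  vals <- ifelse(starts >= 300, 0.5, 0.3)  # baseline window starts at 0
  fcs <- make_fcs(vals, starts)
  gd <- group_delta_fc(list(fcs, fcs), events)
  expect_equal(gd$baseline_window, 1L)
  # delta of 0.2 held over window starts spanning 1200 s
  expect_equal(unname(gd$auc), c(240, 240), tolerance = 1e-12)
  expect_error(group_delta_fc(list(fcs), list(drug_time_s = 310)),
               "baseline window")
})

test_that("the subject pipeline is deterministic end to end", {
  sim <- gen_pfus(pfus_sim_config(n_subjects = 1, seed = 12))
  p1 <- pfus_subject_pipeline(sim$subjects[[1]])
  p2 <- pfus_subject_pipeline(sim$subjects[[1]])
  expect_identical(p1$fc$z, p2$fc$z)
  expect_identical(p1$cbv$binned, p2$cbv$binned)
})

test_that("cbv group tests flag the drug-induced PFC drop with FDR control", {
  sim <- gen_pfus(pfus_sim_config(n_subjects = 6, seed = 13))
  pipe <- lapply(sim$subjects, pfus_subject_pipeline)
  tab <- cbv_group_tests(lapply(pipe, `[[`, "cbv"))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12, na.rm = TRUE))
  peak <- tab[tab$roi == "MOs_L" &
                tab$bin_start_s >= 1380 & tab$bin_start_s <= 1500, ]
  expect_true(any(peak$rejected))
  pre <- tab[tab$bin_start_s < 1100, ]
  expect_lt(mean(pre$rejected, na.rm = TRUE), 0.2)
})
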