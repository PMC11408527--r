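make_dataset <- function(spikes, regions, block_len = 1200) {
  ids <- sprintf("u%02d", seq_along(spikes))
  structure(
    list(units = data.frame(unit_id = ids, region = regions),
         spikes = stats::setNames(spikes, ids),
         blocks = data.frame(block = c("baseline", "vehicle", "drug"),
                             start_s = (0:2) * block_len,
                             end_s = (1:3) * block_len),
         injections = data.frame(label = c("vehicle", "drug"),
                                 time_s = c(1, 2) * block_len),
         duration_s = 3 * block_len, group_label = "test"),
    class = "spike_dataset")
}

test_that("bin_spikes uses half-open bins and drops the partial tail", {
  d <- make_dataset(list(c(0.01, 0.02, 0.06), numeric(0)), c("MOs", "SSp"))
  counts <- bin_spikes(d, c(0, 0.17), bin_dt_s = 0.05)
  expect_identical(ncol(counts), 3L)       # 0.17 s -> 3 complete bins
  expect_identical(unname(counts[1, ]), c(2L, 1L, 0L))
  expect_identical(unname(counts[2, ]), c(0L, 0L, 0L))
  big <- bin_spikes(d, c(0, 1200), bin_dt_s = 0.05)
  expect_identical(ncol(big), 24000L)
  expect_error(bin_spikes(d, c(0, 0.01), bin_dt_s = 0.05), "empty block")
})

test_that("smoothing kernel is normalised and flags constant units", {
  imp <- matrix(0, 2, 100)
  imp[1, 50] <- 1                    # impulse row; row 2 is constant
  sm <- smooth_zscore(imp, sigma_bins = 2, truncation = 4)
  expect_identical(unname(sm$excluded), 2L)
  expect_true(all(is.na(sm$z[2, ])))
  # centre weight of the discrete unit-sum kernel
  g <- dnorm(-8:8, sd = 2)
  smoothed_only <- clawfc:::.smooth_rows_reflect(imp, g / sum(g))
  expect_equal(smoothed_only[1, 50], dnorm(0, sd = 2) / sum(g),
               tolerance = 1e-12)
})

test_that("retained rows are z-scored to mean 0 and sd 1", {
  set.seed(61)
  counts <- matrix(rpois(6 * 2000, 0.2), 6, 2000)
  sm <- smooth_zscore(counts)
  keep <- setdiff(1:6, sm$excluded)
  expect_equal(rowMeans(sm$z[keep, , drop = FALSE]), rep(0, length(keep)),
               tolerance = 1e-10)
  expect_equal(apply(sm$z[keep, , drop = FALSE], 1, sd),
               rep(1, length(keep)), tolerance = 1e-10)
})

test_that("windowed unit fc: window arithmetic, ceiling, oracle equality", {
  set.seed(62)
  nb <- 18000                        # 900 s of 50 ms bins
  z <- matrix(rnorm(3 * nb), 3, nb)
  w <- windowed_unit_fc(z[1:2, ], z[3, , drop = FALSE], 0.05, 60, 30)
  expect_length(w$window_start_s, 29L)
  dup <- windowed_unit_fc(z[1, , drop = FALSE], z[1, , drop = FALSE],
                          0.05, 60, 30)
  expect_true(all(abs(dup$z[1, 1, ] - fisher_z(1)) < 1e-9))

  a <- matrix(rnorm(5 * 500), 5, 500)
  b <- matrix(rnorm(5 * 500), 5, 500)
  got <- windowed_unit_fc(a, b, bin_dt_s = 1, fc_window_s = 100,
                          fc_step_s = 50)
  expect_equal(got$z, oracle_windowed_z(t(a), t(b), 100, 50),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(windowed_unit_fc(a[, 1:50], b[, 1:50], 1, 100, 50),
               "no complete window")
})

test_that("static and difference matrices follow their definitions", {
  set.seed(63)
  z1 <- list(window_start_s = 0,
             z = array(rnorm(12), c(3, 4, 1),
                       dimnames = list(paste0("m", 1:3), NULL, NULL)))
  one <- static_and_diff_fc(z1, z1)
  expect_equal(one$static_vehicle, z1$z[, , 1], tolerance = 1e-12)
  expect_true(all(one$diff_fc == 0))
  expect_true(all(one$per_unit_delta == 0))

  zz <- array(rnorm(3 * 4 * 5), c(3, 4, 5),
              dimnames = list(paste0("m", 1:3), NULL, NULL))
  zz[2, 3, c(2, 4)] <- NA            # missing windows excluded per pair
  res <- static_and_diff_fc(list(z = zz), list(z = zz))
  expect_equal(res$static_drug[2, 3], mean(zz[2, 3, c(1, 3, 5)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("static fc is invariant to time reversal of the rate matrices", {
  set.seed(64)
  a <- matrix(rnorm(4 * 3000), 4, 3000)
  b <- matrix(rnorm(3 * 3000), 3, 3000)
  fwd <- windowed_unit_fc(a, b, 1, 500, 500)
  rev_ <- windowed_unit_fc(a[, 3000:1], b[, 3000:1], 1, 500, 500)
  s_f <- static_and_diff_fc(fwd, fwd)$static_vehicle
  s_r <- static_and_diff_fc(rev_, rev_)$static_vehicle
  expect_equal(s_f, s_r, tolerance = 1e-10)
})

test_that("unit permutation permutes rows and columns consistently", {
  set.seed(65)
  a <- matrix(rnorm(4 * 2000), 4, 2000,
              dimnames = list(paste0("m", 1:4), NULL))
  b <- matrix(rnorm(3 * 2000), 3, 2000,
              dimnames = list(paste0("s", 1:3), NULL))
  perm <- c(3, 1, 4, 2)
  w1 <- windowed_unit_fc(a, b, 1, 500, 250)
  w2 <- windowed_unit_fc(a[perm, ], b, 1, 500, 250)
  expect_equal(w2$z, w1$z[perm, , , drop = FALSE], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the full chain recovers a drug-block coupling drop", {
  g <- gen_spikes(spike_sim_config(seed = 17))
  out <- npx_unit_fc(g$dataset)
  expect_lt(median(out$result$per_unit_delta, na.rm = TRUE), -0.02)
})

test_that("within-region pairs show no block effect under a null schedule", {
  g <- gen_spikes(spike_sim_config(
    cross_region_coupling_by_block = c(0.3, 0.3, 0.3),
    within_region_coupling = 0.2, seed = 18))
  out <- npx_unit_fc(g$dataset, within_region = TRUE)
  expect_lt(abs(median(out$within$per_unit_delta, na.rm = TRUE)), 0.02)
  expect_lt(abs(median(out$result$per_unit_delta, na.rm = TRUE)), 0.02)
})

test_that("group_compare mirrors the unit-level statistics layout", {
  set.seed(66)
  d <- list(Ctrl = rnorm(60, -0.1, 0.05), cKO = rnorm(60, 0, 0.05))
  g <- group_compare(d)
  expect_identical(g$per_group$group, c("Ctrl", "cKO"))
  expect_true(g$per_group$significant[1])
  expect_lt(g$kw$p_value, 0.01)
  degen <- group_compare(list(flat = rep(0, 10)))
  expect_true(degen$per_group$degenerate)
  expect_false(degen$per_group$significant)
  same <- group_compare(list(a = 1:10, b = 1:10))
  expect_equal(same$kw$p_value, 1, tolerance = 1e-12)
})
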