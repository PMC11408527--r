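#' Seeded end-to-end demonstration run
#'
#' Reproduces the shape of the hallucinogen-challenge workflow on
#' synthetic data: a drug-responsive ("Ctrl") and a non-responsive
#' ("cKO") pfUS cohort through the CBV and sliding-window connectivity
#' chain, a Ctrl and a cKO dual-probe spike cohort through the unit
#' connectivity chain with group statistics, and a pair of
#' optical-density images through the line-profile quantifier. All
#' randomness derives from `seed`; identical seeds give identical
#' reports.
#'
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the main tables are
#'   written there as TSV.
#' @param n_subjects Animals per pfUS cohort.
#' @param n_animals Animals per spike cohort.
#' @param n_mos_units,n_ssp_units Units per probe per animal.
#' @return A report list with the Δz summaries, AUC comparison, CBV
#'   trough estimates, unit-level group statistics and OD fold change.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_subjects = 6,
                     n_animals = 2, n_mos_units = 30, n_ssp_units = 20) {
  seed <- as.integer(seed)
  cfg <- pfus_config()

  ## pfUS arm: responsive vs non-responsive cohort
  sim_ctrl <- gen_pfus(pfus_sim_config(n_subjects = n_subjects,
                                       seed = seed))
  sim_cko <- gen_pfus(pfus_sim_config(n_subjects = n_subjects,
                                      drug_coupling_delta = 0,
                                      drug_cbv_drop = -0.15,
                                      seed = seed + 500L))
  run_cohort <- function(sim) {
    pipe <- lapply(sim$subjects, pfus_subject_pipeline, config = cfg)
    ds <- group_delta_fc(lapply(pipe, `[[`, "fc"),
                         sim$subjects[[1]]$events, config = cfg)
    trough <- vapply(pipe, function(p) {
      post <- p$cbv$bin_start_s >= sim$subjects[[1]]$events$drug_time_s
      min(rowMeans(p$cbv$binned[post, pfus_roi_groups()$pfc, drop = FALSE]))
    }, 0)
    list(pipe = pipe, delta = ds, trough_pct = trough)
  }
  pf_ctrl <- run_cohort(sim_ctrl)
  pf_cko <- run_cohort(sim_cko)
  auc_test <- t_test(pf_ctrl$delta$auc, pf_cko$delta$auc, mode = "unpaired")

  ## Neuropixels arm: coupling drop in the drug block vs no change
  ctrl_cfg <- spike_sim_config(n_mos_units = n_mos_units,
                               n_ssp_units = n_ssp_units,
                               group_label = "Ctrl", seed = seed + 1000L)
  cko_cfg <- spike_sim_config(n_mos_units = n_mos_units,
                              n_ssp_units = n_ssp_units,
                              cross_region_coupling_by_block =
                                c(0.6, 0.05, 0.05),
                              group_label = "cKO", seed = seed + 2000L)
  npx_cfg <- npx_config()
  deltas <- list(
    Ctrl = cohort_unit_deltas(gen_spike_cohort(ctrl_cfg, n_animals), npx_cfg),
    cKO = cohort_unit_deltas(gen_spike_cohort(cko_cfg, n_animals), npx_cfg))
  groups <- group_compare(deltas)

  ## OD arm: full-amplitude vs half-amplitude band
  img_hi <- gen_od_image(band_amplitude = 100, seed = seed + 3000L)
  img_lo <- gen_od_image(band_amplitude = 50, seed = seed + 4000L)
  spec <- profile_spec(26, 26, 250, 100)
  auc_hi <- profile_auc(line_profile(img_hi$image, spec), spec)$auc
  auc_lo <- profile_auc(line_profile(img_lo$image, spec), spec)$auc

  report <- list(
    seed = seed,
    pfus = list(
      dz_ctrl = pf_ctrl$delta, dz_cko = pf_cko$delta,
      auc_ctrl = pf_ctrl$delta$auc, auc_cko = pf_cko$delta$auc,
      auc_test = auc_test,
      trough_ctrl_pct = mean(pf_ctrl$trough_pct),
      trough_cko_pct = mean(pf_cko$trough_pct)),
    npx = list(deltas = deltas, groups = groups),
    od = list(auc_hi = auc_hi, auc_lo = auc_lo,
              fold_change = fold_change(auc_lo, auc_hi)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      con <- file(p, "w"); on.exit(close(con), add = TRUE)
      writeLines(output_header(seed), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_tsv(data.frame(window_start_s = pf_ctrl$delta$window_start_s,
                         dz_ctrl = pf_ctrl$delta$mean_dz,
                         dz_cko = pf_cko$delta$mean_dz),
              "pfus_delta_z.tsv")
    write_tsv(data.frame(cohort = rep(c("Ctrl", "cKO"),
                                      c(length(pf_ctrl$delta$auc),
                                        length(pf_cko$delta$auc))),
                         auc = c(pf_ctrl$delta$auc, pf_cko$delta$auc)),
              "pfus_auc.tsv")
    write_tsv(pf_ctrl$delta$tests, "pfus_window_tests_ctrl.tsv")
    write_tsv(groups$per_group, "npx_group_stats.tsv")
    write_tsv(data.frame(group = rep(names(deltas),
                                     vapply(deltas, length, 1L)),
                         unit = unlist(lapply(deltas, names)),
                         delta_z = unlist(deltas)),
              "npx_unit_deltas.tsv")
    write_tsv(data.frame(image = c("full", "half"),
                         auc = c(auc_hi, auc_lo),
                         fold_change = c(1, report$od$fold_change)),
              "od_auc.tsv")
  }
  report
}
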