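#' Configuration for the synthetic pfUS session generator
#'
#' Describes a simulated power-Doppler session: a 40-min acquisition with a
#' vehicle injection at 5 min and a drug challenge at 20 min, eight
#' bilateral cortical ROIs (anterior cingulate ACA, secondary motor MOs,
#' primary motor MOp, primary somatosensory SSp), inter-ROI coupling
#' carried by shared latent factors, a pharmacokinetic-like CBV drop in the
#' prefrontal (PFC = ACA + MOs) ROIs, and multiplicative motion-artifact
#' bursts.
#'
#' Coupling model: every ROI loads on one global factor (weight
#' `sqrt(baseline_coupling)`), one group factor (PFC or sensorimotor SM =
#' MOp + SSp; weight `sqrt(drug_coupling_delta)`), and a private factor.
#' After the drug the two group factors are progressively mixed with a
#' common source, raising the PFC x SM latent correlation from
#' `baseline_coupling` to `baseline_coupling + drug_coupling_delta` at the
#' onset-kernel peak while leaving within-group coupling unchanged.
#'
#' @param n_subjects Number of simulated animals.
#' @param fs Sampling rate in Hz of the regional timecourses.
#' @param duration_s,vehicle_time_s,drug_time_s Session schedule (seconds).
#' @param baseline_coupling Target latent correlation between ROI pairs
#'   before the challenge (cross-group; within-group pairs additionally
#'   share the group factor).
#' @param drug_coupling_delta Added PFC-SM latent correlation at the peak
#'   of the drug onset kernel. Must satisfy
#'   `baseline_coupling + drug_coupling_delta < 1`.
#' @param drug_cbv_drop Fractional CBV change in PFC ROIs at the onset
#'   peak (e.g. -0.15 for a 15% drop).
#' @param onset_shape,onset_scale_s Gamma onset kernel (peak-normalised)
#'   applied to both the CBV change and the coupling change.
#' @param latent_tau_s Correlation time of the Ornstein-Uhlenbeck latent
#'   factors (seconds); keeps signal power inside the 0.01-0.2 Hz band.
#' @param loading Fractional signal modulation per unit latent deviation.
#' @param noise_sd Fractional white measurement noise per sample.
#' @param artifact_rate Motion bursts per minute (session-wide events
#'   hitting all ROIs simultaneously).
#' @param artifact_gain Multiplicative amplitude of a burst sample.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `pfus_sim_config` list.
#' @export
pfus_sim_config <- function(n_subjects = 10, fs = 1, duration_s = 2400,
                            vehicle_time_s = 300, drug_time_s = 1200,
                            baseline_coupling = 0.25,
                            drug_coupling_delta = 0.3,
                            drug_cbv_drop = -0.15,
                            onset_shape = 3, onset_scale_s = 150,
                            latent_tau_s = 4, loading = 0.05,
                            noise_sd = 0.01,
                            artifact_rate = 0.5, artifact_gain = 2,
                            seed = 1L) {
  cfg <- list(n_subjects = n_subjects, fs = fs, duration_s = duration_s,
              vehicle_time_s = vehicle_time_s, drug_time_s = drug_time_s,
              baseline_coupling = baseline_coupling,
              drug_coupling_delta = drug_coupling_delta,
              drug_cbv_drop = drug_cbv_drop,
              onset_shape = onset_shape, onset_scale_s = onset_scale_s,
              latent_tau_s = latent_tau_s, loading = loading,
              noise_sd = noise_sd, artifact_rate = artifact_rate,
              artifact_gain = artifact_gain, seed = seed)
  stopifnot(n_subjects >= 1, fs > 0,
            drug_time_s < duration_s, vehicle_time_s < drug_time_s,
            baseline_coupling >= 0, drug_coupling_delta >= 0,
            noise_sd >= 0, artifact_rate >= 0, artifact_gain > 0,
            abs(fs * duration_s - round(fs * duration_s)) < 1e-9)
  if (baseline_coupling + drug_coupling_delta >= 1)
    stop("infeasible coupling: baseline_coupling + drug_coupling_delta ",
         "must be < 1 (implied correlation not positive definite)")
  class(cfg) <- "pfus_sim_config"
  cfg
}

pfus_roi_labels <- function() {
  regions <- c("ACA", "MOs", "MOp", "SSp")
  paste(rep(regions, each = 2), c("L", "R"), sep = "_")
}

#' Default ROI grouping into prefrontal and sensorimotor sets
#' @return Named list with `pfc` (ACA, MOs bilaterally) and `sm`
#'   (MOp, SSp bilaterally) label vectors.
#' @export
pfus_roi_groups <- function() {
  list(pfc = c("ACA_L", "ACA_R", "MOs_L", "MOs_R"),
       sm  = c("MOp_L", "MOp_R", "SSp_L", "SSp_R"))
}

gen_pfus_subject <- function(cfg, subject_id) {
  n <- round(cfg$fs * cfg$duration_s)
  dt <- 1 / cfg$fs
  t_s <- (seq_len(n) - 1) * dt
  labels <- pfus_roi_labels()
  groups <- pfus_roi_groups()
  is_pfc <- labels %in% groups$pfc

  rho0 <- cfg$baseline_coupling
  delta <- cfg$drug_coupling_delta
  w_shared <- sqrt(rho0)
  w_group <- sqrt(delta)
  w_priv <- sqrt(1 - rho0 - delta)

  # latent sources: global, two group factors, one common mixing source,
  # eight private factors
  f <- ou_paths(n, 4 + 8, dt, cfg$latent_tau_s)
  g_all <- f[, 1]; g_pfc <- f[, 2]; g_sm <- f[, 3]; g_mix <- f[, 4]
  priv <- f[, 5:12, drop = FALSE]

  onset <- rep(0, n)
  post <- t_s >= cfg$drug_time_s
  onset[post] <- gamma_onset(t_s[post] - cfg$drug_time_s,
                             cfg$onset_shape, cfg$onset_scale_s)
  beta <- sqrt(onset)                     # mixing weight; corr gain = beta^2
  h_pfc <- sqrt(1 - beta^2) * g_pfc + beta * g_mix
  h_sm  <- sqrt(1 - beta^2) * g_sm  + beta * g_mix

  latent <- matrix(0, n, 8)
  for (i in seq_len(8)) {
    h <- if (is_pfc[i]) h_pfc else h_sm
    latent[, i] <- w_shared * g_all + w_group * h + w_priv * priv[, i]
  }

  cbv <- matrix(0, n, 8)
  cbv[, is_pfc] <- cfg$drug_cbv_drop * onset

  level <- 100 * stats::runif(8, 0.8, 1.2)
  noise <- matrix(stats::rnorm(n * 8, sd = cfg$noise_sd), n, 8)
  traces <- sweep(1 + cfg$loading * latent + cbv + noise, 2, level, `*`)

  # session-wide multiplicative motion bursts (1-3 samples)
  n_burst <- stats::rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
  artifact_idx <- integer(0)
  if (n_burst > 0) {
    starts <- sample.int(n, n_burst, replace = TRUE)
    lens <- sample(1:3, n_burst, replace = TRUE)
    artifact_idx <- sort(unique(unlist(
      mapply(function(s, l) s:min(s + l - 1L, n), starts, lens,
             SIMPLIFY = FALSE))))
    traces[artifact_idx, ] <- traces[artifact_idx, ] * cfg$artifact_gain
  }

  set <- structure(
    list(subject_id = subject_id, fs = cfg$fs, time_s = t_s,
         traces = `colnames<-`(traces, labels), roi_labels = labels,
         events = list(vehicle_time_s = cfg$vehicle_time_s,
                       drug_time_s = cfg$drug_time_s,
                       duration_s = cfg$duration_s)),
    class = "roi_timecourse_set")
  truth <- list(subject_id = subject_id,
                artifact_sample_indices = artifact_idx,
                injected_cbv_curve = cbv,
                baseline_coupling = rho0,
                peak_cross_coupling = rho0 + delta,
                onset = onset, level = level)
  list(set = set, truth = truth)
}

#' Generate a synthetic pfUS cohort with ground truth
#'
#' Produces `n_subjects` regional power-Doppler sessions under the model
#' described in [pfus_sim_config()]. Identical `(config, seed)` gives
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config A `pfus_sim_config`.
#' @return List with `subjects` (list of `roi_timecourse_set`) and `truth`
#'   (list of per-subject ground-truth records).
#' @export
gen_pfus <- function(config) {
  stopifnot(inherits(config, "pfus_sim_config"))
  with_local_seed(config$seed, {
    out <- lapply(seq_len(config$n_subjects), function(i)
      gen_pfus_subject(config, sprintf("sim%02d", i)))
    list(subjects = lapply(out, `[[`, "set"),
         truth = lapply(out, `[[`, "truth"),
         config = config)
  })
}
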