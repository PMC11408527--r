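#' Configuration for the synthetic dual-probe spike generator
#'
#' Describes a head-fixed session recorded simultaneously in secondary
#' motor cortex (MOs) and primary somatosensory cortex (SSp): three 20-min
#' blocks (baseline, vehicle, drug), with injections at the block
#' boundaries. Units are doubly stochastic Poisson processes whose
#' log-intensity loads on a region-private latent factor (within-region
#' coupling) and on a shared cross-region factor whose loading is scaled
#' per block -- the knob that emulates a drug-induced change in
#' cross-region correlated variability.
#'
#' `lambda_u(t) = exp(mu_u + a * f_region(t) + b_k * f_shared(t))`, with
#' unit-variance Ornstein-Uhlenbeck factors and `mu_u` offset by
#' `-(a^2 + b_k^2)/2` so the mean rate equals the drawn per-unit rate.
#'
#' @param n_mos_units,n_ssp_units Units per probe.
#' @param block_length_s Block duration (seconds); three blocks.
#' @param base_rate_hz Median firing rate; per-unit rates are lognormal.
#' @param rate_log_sd SD of per-unit log-rates.
#' @param within_region_coupling Loading `a` on the region factor.
#' @param cross_region_coupling_by_block Loadings `b_k`, one per block
#'   (baseline, vehicle, drug).
#' @param latent_timescale_s OU correlation time of the latent factors;
#'   short (sub-second) timescales emulate fast shared rate fluctuations.
#' @param bin_dt_for_latent_s Simulation step for the latent intensity.
#' @param group_label Cohort tag (e.g. "Ctrl", "cKO").
#' @param max_rate_hz Safety cap on the expected per-unit rate.
#' @param seed Integer seed.
#' @return A `spike_sim_config` list.
#' @export
spike_sim_config <- function(n_mos_units = 34, n_ssp_units = 12,
                             block_length_s = 1200,
                             base_rate_hz = 1.5, rate_log_sd = 0.4,
                             within_region_coupling = 0.1,
                             cross_region_coupling_by_block = c(0.6, 0.6, 0.2),
                             latent_timescale_s = 0.15,
                             bin_dt_for_latent_s = 0.05,
                             group_label = "Ctrl",
                             max_rate_hz = 200, seed = 1L) {
  cfg <- list(n_mos_units = n_mos_units, n_ssp_units = n_ssp_units,
              block_length_s = block_length_s, n_blocks = 3L,
              base_rate_hz = base_rate_hz, rate_log_sd = rate_log_sd,
              within_region_coupling = within_region_coupling,
              cross_region_coupling_by_block =
                as.numeric(cross_region_coupling_by_block),
              latent_timescale_s = latent_timescale_s,
              bin_dt_for_latent_s = bin_dt_for_latent_s,
              group_label = group_label, max_rate_hz = max_rate_hz,
              seed = seed)
  stopifnot(n_mos_units >= 1, n_ssp_units >= 1, block_length_s > 0,
            base_rate_hz > 0, rate_log_sd >= 0,
            length(cfg$cross_region_coupling_by_block) == 3L,
            latent_timescale_s > 0, bin_dt_for_latent_s > 0)
  if (any(abs(c(within_region_coupling,
                cfg$cross_region_coupling_by_block)) > 2))
    stop("coupling loadings too large: log-rates would be unrealistic")
  class(cfg) <- "spike_sim_config"
  cfg
}

#' Generate a synthetic dual-probe spike dataset with ground truth
#'
#' Simulates one animal under the doubly stochastic Poisson model of
#' [spike_sim_config()]. Spike counts are drawn per latent bin and spike
#' times placed uniformly within their bin; times are sorted and labelled
#' per unit. Identical `(config, seed)` gives identical spikes.
#'
#' @param config A `spike_sim_config`.
#' @return List with `dataset` (a `spike_dataset`: `units` data frame,
#'   `spikes` list of sorted time vectors, `blocks` data frame with
#'   injection times, `group_label`) and `truth` (coupling schedule and
#'   per-unit rates).
#' @export
gen_spikes <- function(config) {
  stopifnot(inherits(config, "spike_sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n_units <- cfg$n_mos_units + cfg$n_ssp_units
    region <- rep(c("MOs", "SSp"), c(cfg$n_mos_units, cfg$n_ssp_units))
    rates <- cfg$base_rate_hz * exp(stats::rnorm(n_units, 0,
                                                 cfg$rate_log_sd))
    if (any(rates > cfg$max_rate_hz)) stop("rate too high")
    dt <- cfg$bin_dt_for_latent_s
    bins_per_block <- floor(cfg$block_length_s / dt)
    a <- cfg$within_region_coupling
    spike_times <- vector("list", n_units)
    for (u in seq_len(n_units)) spike_times[[u]] <- vector("list", 3L)

    for (k in seq_len(3L)) {
      b <- cfg$cross_region_coupling_by_block[k]
      f <- ou_paths(bins_per_block, 3L, dt, cfg$latent_timescale_s)
      # per-region intensity envelope shared by that region's units; the
      # lognormal mean correction keeps the expected rate at the drawn rate
      env <- list(MOs = exp(a * f[, 1] + b * f[, 3] - (a^2 + b^2) / 2),
                  SSp = exp(a * f[, 2] + b * f[, 3] - (a^2 + b^2) / 2))
      env_sum <- vapply(env, sum, 0)
      block_start <- (k - 1) * cfg$block_length_s
      # Poisson thinning: total count ~ Pois(rate * dt * sum(envelope)),
      # bins sampled with probability proportional to the envelope, spike
      # placed uniformly inside its bin -- equivalent to independent
      # per-bin Poisson counts with intensity rate * dt * envelope
      for (u in seq_len(n_units)) {
        reg <- region[u]
        n_sp <- stats::rpois(1, rates[u] * dt * env_sum[[reg]])
        if (n_sp > 0) {
          bin_idx <- sample.int(bins_per_block, n_sp, replace = TRUE,
                                prob = env[[reg]])
          spike_times[[u]][[k]] <- block_start + (bin_idx - 1) * dt +
            stats::runif(n_sp) * dt
        }
      }
    }
    spikes <- lapply(spike_times, function(s) sort(unlist(s)))
    unit_ids <- sprintf("%s_%03d", region, stats::ave(
      seq_len(n_units), region, FUN = seq_along))
    blocks <- data.frame(
      block = c("baseline", "vehicle", "drug"),
      start_s = (0:2) * cfg$block_length_s,
      end_s = (1:3) * cfg$block_length_s)
    dataset <- structure(
      list(units = data.frame(unit_id = unit_ids, region = region),
           spikes = stats::setNames(spikes, unit_ids),
           blocks = blocks,
           injections = data.frame(
             label = c("vehicle", "drug"),
             time_s = c(1, 2) * cfg$block_length_s),
           duration_s = 3 * cfg$block_length_s,
           group_label = cfg$group_label),
      class = "spike_dataset")
    truth <- list(rates_hz = stats::setNames(rates, unit_ids),
                  within_region_coupling = a,
                  cross_region_coupling_by_block =
                    cfg$cross_region_coupling_by_block,
                  latent_timescale_s = cfg$latent_timescale_s)
    list(dataset = dataset, truth = truth, config = cfg)
  })
}

#' Generate a cohort of synthetic animals
#'
#' Repeated [gen_spikes()] with per-animal seeds `seed, seed + 1, ...`
#' derived from the config seed, mirroring a multi-animal experiment whose
#' units are pooled for group statistics.
#'
#' @param config A `spike_sim_config`; its `seed` seeds animal 1.
#' @param n_animals Number of animals.
#' @return List of `gen_spikes()` results, one per animal.
#' @export
gen_spike_cohort <- function(config, n_animals = 6) {
  stopifnot(inherits(config, "spike_sim_config"), n_animals >= 1)
  lapply(seq_len(n_animals), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L)
    gen_spikes(cfg)
  })
}
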