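#' Configuration of an end-to-end run
#'
#' Bundles every stage parameter of the simulate -> spectra -> cluster ->
#' compose -> patterns pipeline, fully serializable; a snapshot of the
#' config is written beside the outputs of every run for audit.
#'
#' @param label site/day label for the report.
#' @param seed RNG seed (mandatory).
#' @param n_species,gamma_true,a0_true,noise_sd scene parameters passed to
#'   [scene_config()].
#' @param min_transit_ms transit filter threshold, ms.
#' @param near_limit near-field limit, m.
#' @param fs effective sample rate, Hz.
#' @param out_dir output directory (`NULL` = no files written).
#' @param templates optional list of [species_template()]; defaults to
#'   `n_species` templates with wingbeat frequencies spread over the
#'   resolvable band and varied diel niches.
#' @return object of class `run_config`.
#' @export
run_config <- function(label = "demo", seed = 1L, n_species = 5,
                       gamma_true = 0.8, a0_true = 2000, noise_sd = 20,
                       min_transit_ms = 25, near_limit = 40, fs = 1750,
                       out_dir = NULL, templates = NULL) {
  structure(list(label = label, seed = as.integer(seed),
                 n_species = n_species, gamma_true = gamma_true,
                 a0_true = a0_true, noise_sd = noise_sd,
                 min_transit_ms = min_transit_ms,
                 near_limit = near_limit, fs = fs, out_dir = out_dir,
                 templates = templates),
            class = "run_config")
}

#' Default synthetic community for demos and end-to-end tests
#'
#' `k` species with wingbeat frequencies spread evenly over the resolvable
#' band (spacing at least three spectral bins), alternating harmonic
#' richness, detection ranges and diel niches (dawn, midday, dusk,
#' night-active, uniform).
#'
#' @param k number of species.
#' @param wbf_min,wbf_max band the fundamentals are spread over, Hz.
#' @return list of [species_template()].
#' @export
default_templates <- function(k, wbf_min = 100, wbf_max = 760) {
  stopifnot(k >= 1)
  # fundamentals sit on modulation-axis bin centres, spread evenly
  ax <- modulation_axis()
  ax <- ax[ax >= wbf_min & ax <= wbf_max]
  wbfs <- if (k == 1) ax[ceiling(length(ax) / 2)] else
    ax[round(seq(1, length(ax), length.out = k))]
  niches <- list(
    data.frame(hour = 6.5, sd_h = 0.7, weight = 1),            # dawn
    data.frame(hour = 18.5, sd_h = 0.7, weight = 1),           # dusk
    data.frame(hour = 13, sd_h = 2.0, weight = 1),             # midday
    data.frame(hour = c(1, 23), sd_h = c(1.5, 1.5),
               weight = c(0.5, 0.5)),                          # night
    data.frame(hour = 12, sd_h = Inf, weight = 1))             # uniform
  lapply(seq_len(k), function(i) {
    harm <- switch(1 + (i %% 3),
                   c(1, 0.6, 0.3, 0.15),
                   c(1, 0.3),
                   c(1, 0.7, 0.45, 0.25, 0.12))
    # neutral even/odd balance keeps every harmonic weaker than the
    # fundamental, so Nyquist-folded harmonics of fast species never
    # dominate their spectra
    species_template(
      species_id = sprintf("sp%02d", i),
      wbf = wbfs[i],
      harmonic_amps = harm,
      even_odd_balance = 0.5,
      body_fraction = 0.2 + 0.1 * (i %% 3),
      brightness = 1500 + 500 * (i %% 4),
      r_det = 150 + 40 * (i %% 5),
      alpha_range = 2,
      activity_profile = niches[[1 + (i - 1) %% length(niches)]])
  })
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Executes simulate -> transit filter -> spectra (with paired noise) ->
#' clustering with noise negative control -> composition fit ->
#' spatio-temporal pattern counts, and returns one report per run. With
#' an `out_dir`, all stage artifacts (config snapshot, observation CSV,
#' labels CSV, compensated-linkage curves, report JSON) are written.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with fields `label`, `seed`,
#'   `n_obs`, `n_survivors`, `beta`, `noc`, `noc_noise`, `a0`, `gamma`,
#'   `a_half`, `r2adj`, `n_unique_range_patterns`,
#'   `n_unique_time_patterns`, plus a `stages` attribute carrying the
#'   intermediate objects.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  templates <- config$templates
  if (is.null(templates)) templates <- default_templates(config$n_species)
  scfg <- scene_config(n_species = length(templates),
                       gamma_true = config$gamma_true,
                       a0_true = config$a0_true,
                       noise_sd = config$noise_sd,
                       near_limit = config$near_limit,
                       fs = config$fs,
                       seed = config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", generate_observations(scfg, templates))
  obs <- sim$observations
  surv <- stage("spectra", transit_filter(obs, config$min_transit_ms))
  # paired noise fragments: instrument noise under each survivor's mask
  noise_waves <- lapply(sim$waveforms[surv$obs_id], function(w)
    pmax(rnorm(length(w), scfg$baseline, scfg$noise_sd), 0))
  ens <- stage("spectra",
               build_ensemble(surv, sim$waveforms, noise_waves,
                              fs = config$fs))
  clus <- stage("cluster", cluster_spectra(ens$power))
  nctl <- stage("cluster", noise_control(ens$noise_power))
  counts <- sort_cluster_counts(clus$labels)
  comp <- if (length(counts) >= 3) {
    stage("compose", fit_composition(counts))
  } else {
    NULL
  }
  rh <- stage("patterns",
              range_histograms(clus$labels, surv, config$near_limit))
  th <- stage("patterns", time_histograms(clus$labels, surv))
  report <- list(
    label = config$label,
    seed = config$seed,
    n_obs = nrow(obs),
    n_survivors = nrow(surv),
    beta = clus$beta,
    noc = clus$noc,
    noc_noise = nctl$noc_noise,
    a0 = if (is.null(comp)) NA_real_ else comp$a0,
    gamma = if (is.null(comp)) NA_real_ else comp$gamma,
    a_half = if (is.null(comp)) NA_real_ else comp$a_half,
    r2adj = if (is.null(comp)) NA_real_ else comp$r2adj,
    n_unique_range_patterns = unique_pattern_count(rh),
    n_unique_time_patterns = unique_pattern_count(th))
  class(report) <- "run_report"
  attr(report, "stages") <- list(observations = obs, survivors = surv,
                                 ensemble = ens, clustering = clus,
                                 noise = nctl, composition = comp,
                                 range_hist = rh, time_hist = th)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_snapshot <- config
    cfg_snapshot$templates <- NULL
    yaml::write_yaml(unclass(cfg_snapshot),
                     file.path(config$out_dir, "config.yaml"))
    write_observations(obs, file.path(config$out_dir, "observations.csv"))
    write.csv(data.frame(obs_id = surv$obs_id,
                         cluster_id = clus$labels),
              file.path(config$out_dir, "labels.csv"), row.names = FALSE)
    p <- seq_along(clus$z)
    write.csv(data.frame(p = p, z = clus$z, z_comp = clus$z_comp,
                         z_noise_comp = c(nctl$z_comp,
                                          rep(NA, length(p) -
                                                length(nctl$z_comp)))),
              file.path(config$out_dir, "linkages.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run '%s' (seed %d)\n", x$label, x$seed))
  cat(sprintf("  observations: %d (%d past transit filter)\n",
              x$n_obs, x$n_survivors))
  cat(sprintf("  clusters: NoC = %d (noise control: %d), beta = %.3f\n",
              x$noc, x$noc_noise, x$beta))
  if (is.finite(x$gamma)) {
    cat(sprintf("  composition: A0 = %.4g, gamma = %.3f, A_half = %.4g, R2adj = %.4f\n",
                x$a0, x$gamma, x$a_half, x$r2adj))
  }
  cat(sprintf("  unique patterns: %d range, %d diel\n",
              x$n_unique_range_patterns, x$n_unique_time_patterns))
  invisible(x)
}
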