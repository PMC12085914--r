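#' Dino-factor parameter recovery across replicate synthetic cruises
#'
#' Repeatedly generates a synthetic cruise, runs the full pipeline
#' (normalize, biomass, co-locate) on the total mRNA pool and fits the
#' Dinoflagellate and pooled non-Dinoflagellate power laws, recording
#' the estimated Dino-factor and slopes with their standard errors.
#' Used to check that the estimator recovers the configured truth under
#' the generator's noise model.
#'
#' @param n_cruises Number of replicate cruises.
#' @param seed Base seed; cruise `i` uses `seed + i`.
#' @param config_args Named list of overrides passed to
#'   [cruise_config()] (the seed is set per cruise).
#' @param pool mRNA pool to calibrate (default `"total"`).
#' @return Tibble with one row per cruise: `seed`, `dino_factor`,
#'   `dino_factor_se`, `slope_dino`, `slope_se_dino`, `slope_other`,
#'   `slope_se_other`.
#' @export
simulate_factor_recovery <- function(n_cruises = 200, seed = 1,
                                     config_args = list(),
                                     pool = "total") {
  map_dfr(seq_len(n_cruises), function(i) {
    cfg <- do.call(cruise_config, c(list(seed = seed + i), config_args))
    truth <- generate_biomass_field(cfg)
    cells <- generate_cells(cfg, truth)
    tx <- generate_transcriptome(cfg, truth)
    conc <- taxon_concentrations(filter_contigs(tx$counts), tx$manifest) |>
      filter(.data$pool == !!pool)
    bins <- bin_latitude(sample_biomass(cells))
    pts <- suppressMessages(
      match_samples(average_replicates(conc), bins))
    fd <- fit_loglog(pts, "Dinoflagellate", pool = pool)
    fo <- fit_loglog(pts, "non-Dinoflagellate", pool = pool)
    sf <- dino_factor(fd, fo)
    tibble(seed = seed + i,
           dino_factor = sf$estimate, dino_factor_se = sf$se,
           slope_dino = fd$slope_b, slope_se_dino = fd$se_b,
           slope_other = fo$slope_b, slope_se_other = fo$se_b)
  })
}

#' AIC model-family selection under a lognormal power-law truth
#'
#' Simulates matched points from `T = a * C^b` with multiplicative
#' lognormal noise and records which model family (linear, log-log,
#' nonlinear) [compare_models()] selects.
#'
#' @param n_sims Number of simulated data sets.
#' @param n_points Points per data set.
#' @param seed Base seed.
#' @param a,b True power-law parameters.
#' @param noise_sd_log10 SD of the log10-scale noise.
#' @param log10_c_range Range of log10 carbon values sampled uniformly.
#' @return Tibble with `seed` and `best_model` per simulation.
#' @export
simulate_aic_selection <- function(n_sims = 200, n_points = 50, seed = 1,
                                   a = 5, b = 1, noise_sd_log10 = 0.25,
                                   log10_c_range = c(-1.5, 1)) {
  map_dfr(seq_len(n_sims), function(i) {
    with_seed(seed + i, {
      lc <- runif(n_points, log10_c_range[1], log10_c_range[2])
      carbon <- 10^lc
      transcripts <- a * carbon^b * 10^rnorm(n_points, 0, noise_sd_log10)
      cmp <- suppressWarnings(
        compare_models(tibble(carbon = carbon, transcripts = transcripts)))
      tibble(seed = seed + i, best_model = cmp$best_model)
    })
  })
}

#' Type-I error of the ANCOVA taxonomy test under the null
#'
#' Simulates five taxa sharing one transcript-to-carbon relationship
#' (all taxonomy offsets zero) and records the ANCOVA taxonomy p-value,
#' to calibrate the empirical false-positive rate of the partial
#' F-test.
#'
#' @param n_sims Number of null simulations.
#' @param n_per_taxon Points per taxon.
#' @param seed Base seed.
#' @param noise_sd_log10 Residual SD on the log10 scale.
#' @param log10_c_range Range of log10 carbon values.
#' @return Tibble with `seed` and `p_taxon` per simulation.
#' @export
simulate_ancova_null <- function(n_sims = 1000, n_per_taxon = 10, seed = 1,
                                 noise_sd_log10 = 0.25,
                                 log10_c_range = c(-1.5, 1)) {
  taxa <- taxon_levels()
  map_dfr(seq_len(n_sims), function(i) {
    with_seed(seed + i, {
      pts <- tibble(
        taxon_group = rep(taxa, each = n_per_taxon),
        log10_carbon = runif(length(taxa) * n_per_taxon,
                             log10_c_range[1], log10_c_range[2])
      ) |>
        mutate(log10_transcripts = .data$log10_carbon +
                 rnorm(n(), 0, noise_sd_log10))
      res <- ancova_taxa(pts, pairwise = FALSE)
      tibble(seed = seed + i, p_taxon = res$p_taxon)
    })
  })
}
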