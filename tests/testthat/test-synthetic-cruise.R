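test_that("configuration errors name the offending field", {
  expect_error(cruise_config(lat_min = 40, lat_max = 30), "lat_min",
               class = "dinofactor_config_error")
  expect_error(cruise_config(n_stations = 1), "n_stations",
               class = "dinofactor_config_error")
  expect_error(cruise_config(recovery_range = c(0, 0.5)), "recovery_range",
               class = "dinofactor_config_error")
  expect_error(cruise_config(functional_fraction = 0), "functional_fraction",
               class = "dinofactor_config_error")
  expect_error(cruise_config(noise_sd_log10 = -1), "noise_sd_log10",
               class = "dinofactor_config_error")
})

test_that("biomass field realizes the configured latitudinal gradients", {
  # degenerate gradient: fold-change 1 gives constant biomass
  flat <- cruise_config(taxa = dplyr::mutate(default_taxa(), fold_change = 1))
  tf <- generate_biomass_field(flat)
  expect_equal(dplyr::n_distinct(round(tf$biomass[tf$taxon_group ==
                                                    "Haptophyta"], 12)), 1)

  # two stations, fold-change 10: endpoint ratio is exactly 10
  two <- cruise_config(n_stations = 2,
                       taxa = dplyr::mutate(default_taxa(), fold_change = 10))
  t2 <- generate_biomass_field(two)
  ratio <- tapply(t2$biomass, t2$taxon_group, function(x) max(x) / min(x))
  expect_equal(as.vector(ratio), rep(10, 5), tolerance = 1e-12)

  # defaults: per-taxon max/min equals fold_change; total spans > 1 decade
  truth <- generate_biomass_field(cruise_config(seed = 42))
  per_taxon <- truth |>
    dplyr::left_join(dplyr::select(default_taxa(), taxon_group = name,
                                   fold_change), by = "taxon_group") |>
    dplyr::group_by(taxon_group, fold_change) |>
    dplyr::summarise(ratio = max(biomass) / min(biomass), .groups = "drop")
  expect_equal(per_taxon$ratio, per_taxon$fold_change, tolerance = 1e-10)
  total <- tapply(truth$biomass, truth$station_id, sum)
  expect_gte(max(total) / min(total), 10)

  # true transcripts follow T = a * C^b exactly
  chk <- truth |>
    dplyr::left_join(dplyr::select(default_taxa(), taxon_group = name,
                                   intercept_a, slope_b), by = "taxon_group")
  expect_equal(chk$transcripts_true, chk$intercept_a * chk$biomass^chk$slope_b)
  expect_equal(attr(truth, "dino_factor"), 6.4)
})

test_that("generated cells recover the true biomass within sampling error", {
  # zero biomass produces zero cells
  zero_taxa <- dplyr::mutate(default_taxa(),
                             biomass_south = c(1, 1e-12, 1e-12, 1e-12, 1e-12))
  cfg0 <- cruise_config(taxa = zero_taxa, n_stations = 2, seed = 9)
  cells0 <- generate_cells(cfg0)
  expect_setequal(unique(cells0$taxon_group), "Dinoflagellata")

  # single dominant taxon, large analyzed volume: biomass within 5% of truth
  cfg <- cruise_config(seed = 1, n_stations = 2, ifcb_volume = 5)
  truth <- generate_biomass_field(cfg)
  cells <- generate_cells(cfg, truth)
  est <- sample_biomass(cells) |>
    dplyr::inner_join(truth, by = c("latitude", "taxon_group"),
                      suffix = c("_est", "_true")) |>
    dplyr::filter(taxon_group == "Dinoflagellata")
  expect_equal(est$biomass_est, est$biomass_true, tolerance = 0.05)

  # ESD truncation contract over ~1e4 cells
  esd <- (6 / pi * cells$biovolume_um3)^(1 / 3)
  expect_gte(nrow(cells), 1e4)
  expect_gte(min(esd), 3)
  expect_lte(max(esd), 100)
})

test_that("transcriptome generation is deterministic and conserves totals", {
  cfg <- cruise_config(seed = 13, n_stations = 3, n_replicates = 2,
                       n_contigs = 12, noise_sd_log10 = 0)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1, tx2)

  cells1 <- generate_cells(cfg)
  cells2 <- generate_cells(cfg)
  expect_identical(cells1, cells2)

  # noiseless conservation: per-sample per-taxon counts equal the rounded
  # concentration divided by the manifest-implied normalization factor
  truth <- generate_biomass_field(cfg)
  m <- normalization_factor(tx1$manifest)
  totals <- tx1$counts |>
    dplyr::group_by(sample_id, taxon_group) |>
    dplyr::summarise(reads = sum(mapped_reads), .groups = "drop") |>
    dplyr::left_join(m, by = "sample_id") |>
    dplyr::left_join(truth, by = c("latitude", "taxon_group"))
  expect_equal(totals$reads,
               round(totals$transcripts_true * 1e9 / totals$norm_factor))
})

test_that("functional_fraction = 1 makes the pools identical", {
  cfg <- cruise_config(seed = 4, n_stations = 2, n_replicates = 1,
                       functional_fraction = 1, n_contigs = 10)
  tx <- generate_transcriptome(cfg)
  expect_true(all(!is.na(tx$counts$ko_id)))
  conc <- taxon_concentrations(tx$counts, tx$manifest) |>
    tidyr::pivot_wider(names_from = pool, values_from = concentration)
  expect_equal(conc$functional, conc$total)
})

test_that("spike-in normalization round-trips the generator", {
  # noiseless: recovery limited only by integer rounding of large counts
  cfg0 <- cruise_config(seed = 17, noise_sd_log10 = 0, n_contigs = 8,
                        recovery_range = c(2e-4, 2e-4),
                        volume_range = c(2, 2))
  truth <- generate_biomass_field(cfg0)
  tx <- generate_transcriptome(cfg0, truth)
  conc <- taxon_concentrations(filter_contigs(tx$counts), tx$manifest) |>
    dplyr::filter(pool == "total", taxon_group != "other") |>
    dplyr::left_join(truth, by = c("latitude", "taxon_group"))
  expect_equal(conc$concentration, conc$transcripts_true, tolerance = 1e-6)

  # with lognormal noise: recovery within 10^(+-2 * noise_sd_log10)
  cfg <- cruise_config(seed = 7)
  truth <- generate_biomass_field(cfg)
  tx <- generate_transcriptome(cfg, truth)
  conc <- taxon_concentrations(filter_contigs(tx$counts), tx$manifest) |>
    dplyr::filter(pool == "total", taxon_group != "other") |>
    dplyr::left_join(truth, by = c("latitude", "taxon_group"))
  lr <- abs(log10(conc$concentration / conc$transcripts_true))
  expect_lt(mean(lr <= 2 * cfg$noise_sd_log10), 1 + 1e-9)
  expect_gte(mean(lr <= 2 * cfg$noise_sd_log10), 0.93)
})
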