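#' Default taxon specifications for a synthetic cruise
#'
#' Five-taxon community with log-linear latitudinal biomass gradients
#' (concentration at the southern end and fold-change across the
#' transect), power-law transcript intercepts and slopes, and truncated
#' lognormal cell-size distributions. Dinoflagellata dominates biomass
#' and carries an intercept 6.4-fold above the shared non-dinoflagellate
#' intercept, so the configured Dino-factor of the default community is
#' exactly 41.6 / 6.5 = 6.4.
#'
#' @return Tibble with one row per taxon: `name`, `biomass_south`
#'   (ug C L^-1 at `lat_min`), `fold_change` (biomass multiplier from
#'   `lat_min` to `lat_max`), `intercept_a` (1e9 transcripts L^-1 at
#'   1 ug C L^-1), `slope_b`, `esd_median` (um), `esd_sdlog`
#'   (lognormal sd of ESD on the natural-log scale).
#' @export
default_taxa <- function() {
  tibble(
    name = taxon_levels(),
    biomass_south = c(0.50, 0.08, 0.10, 0.12, 0.03),
    fold_change = c(12, 25, 10, 8, 15),
    intercept_a = c(41.6, 6.5, 6.5, 6.5, 6.5),
    slope_b = c(1, 1, 1, 1, 1),
    esd_median = c(20, 15, 20, 8, 10),
    esd_sdlog = c(0.35, 0.40, 0.35, 0.30, 0.30)
  )
}

#' Configuration for a synthetic latitudinal cruise
#'
#' Bundles and validates every knob of the coupled cell/transcriptome
#' generator: transect geometry, replication, taxon parameters, spike-in
#' behaviour, measurement volumes and the lognormal transcript noise.
#'
#' @param lat_min,lat_max Transect latitude range in degrees north.
#' @param n_stations Number of equally spaced stations (>= 2).
#' @param n_replicates Biological replicates per station.
#' @param taxa Taxon specification tibble; see [default_taxa()].
#' @param spike_added Spike-in standard molecules added per sample.
#' @param recovery_range Min/max spike-in recovery fraction, sampled
#'   uniformly per sample; must lie in (0, 1].
#' @param volume_range Min/max filtered sample volume in liters.
#' @param noise_sd_log10 SD of the additive Normal noise on log10
#'   transcript concentration (multiplicative lognormal on the linear
#'   scale).
#' @param functional_fraction Fraction of each taxon's transcripts
#'   carrying a KO functional annotation, in (0, 1].
#' @param n_contigs Contigs per taxon over which counts are spread.
#' @param ifcb_volume Analyzed imaging-cytometer volume per station in
#'   liters (aggregated over triggers).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `cruise_config` list.
#' @export
cruise_config <- function(lat_min = 25, lat_max = 41, n_stations = 10,
                          n_replicates = 3, taxa = default_taxa(),
                          spike_added = 4e9,
                          recovery_range = c(2e-5, 2e-4),
                          volume_range = c(1.5, 2.5),
                          noise_sd_log10 = 0.25,
                          functional_fraction = 0.4,
                          n_contigs = 50, ifcb_volume = 0.5,
                          seed = 42) {
  if (!is.numeric(lat_min) || !is.numeric(lat_max) || lat_min >= lat_max) {
    abort("configuration error: `lat_min` must be < `lat_max`",
          class = "dinofactor_config_error")
  }
  if (n_stations < 2) {
    abort("configuration error: `n_stations` must be >= 2",
          class = "dinofactor_config_error")
  }
  if (n_replicates < 1) {
    abort("configuration error: `n_replicates` must be >= 1",
          class = "dinofactor_config_error")
  }
  check_columns(taxa, c("name", "biomass_south", "fold_change",
                        "intercept_a", "slope_b", "esd_median",
                        "esd_sdlog"), "taxa")
  check_positive(taxa$biomass_south, "taxa$biomass_south")
  check_positive(taxa$fold_change, "taxa$fold_change")
  check_positive(taxa$intercept_a, "taxa$intercept_a")
  check_positive(spike_added, "spike_added")
  if (length(recovery_range) != 2 || recovery_range[1] <= 0 ||
      recovery_range[1] > recovery_range[2] || recovery_range[2] > 1) {
    abort("configuration error: `recovery_range` must satisfy 0 < min <= max <= 1",
          class = "dinofactor_config_error")
  }
  if (length(volume_range) != 2 || any(volume_range <= 0) ||
      volume_range[1] > volume_range[2]) {
    abort("configuration error: `volume_range` must be positive with min <= max",
          class = "dinofactor_config_error")
  }
  check_positive(noise_sd_log10, "noise_sd_log10", strict = FALSE)
  if (functional_fraction <= 0 || functional_fraction > 1) {
    abort("configuration error: `functional_fraction` must be in (0, 1]",
          class = "dinofactor_config_error")
  }
  check_positive(n_contigs, "n_contigs")
  check_positive(ifcb_volume, "ifcb_volume")
  if (!is.numeric(seed) || !is.finite(seed)) {
    abort("configuration error: `seed` must be a finite integer",
          class = "dinofactor_config_error")
  }
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         n_stations = as.integer(n_stations),
         n_replicates = as.integer(n_replicates), taxa = taxa,
         spike_added = spike_added, recovery_range = recovery_range,
         volume_range = volume_range, noise_sd_log10 = noise_sd_log10,
         functional_fraction = functional_fraction,
         n_contigs = as.integer(n_contigs), ifcb_volume = ifcb_volume,
         seed = as.integer(seed)),
    class = "cruise_config"
  )
}

#' Ground-truth biomass and transcript field along the transect
#'
#' Places `n_stations` equally spaced stations between `lat_min` and
#' `lat_max` and assigns each taxon a log-linear biomass trend
#' `C(lat) = biomass_south * fold_change^((lat - lat_min) / span)`, so
#' within each taxon the max/min biomass ratio across stations equals
#' `fold_change` exactly. True transcript concentrations follow the
#' configured power law `T = a * C^b` with no noise.
#'
#' @param config A [cruise_config()].
#' @return Ground-truth tibble: `station_id`, `latitude`,
#'   `taxon_group`, `biomass` (ug C L^-1), `transcripts_true`
#'   (1e9 transcripts L^-1). The configured Dino-factor (dinoflagellate
#'   intercept over geometric-mean non-dinoflagellate intercept) is
#'   attached as attribute `"dino_factor"`.
#' @export
generate_biomass_field <- function(config) {
  stopifnot(inherits(config, "cruise_config"))
  lats <- seq(config$lat_min, config$lat_max,
              length.out = config$n_stations)
  span <- config$lat_max - config$lat_min
  truth <- crossing(
    tibble(station_id = sprintf("S%02d", seq_along(lats)), latitude = lats),
    config$taxa |> rename(taxon_group = "name")
  ) |>
    mutate(
      biomass = .data$biomass_south *
        .data$fold_change^((.data$latitude - config$lat_min) / span),
      transcripts_true = .data$intercept_a * .data$biomass^.data$slope_b
    ) |>
    select("station_id", "latitude", "taxon_group", "biomass",
           "transcripts_true")
  a_dino <- config$taxa$intercept_a[config$taxa$name == "Dinoflagellata"]
  a_other <- config$taxa$intercept_a[config$taxa$name != "Dinoflagellata"]
  attr(truth, "dino_factor") <- a_dino / exp(mean(log(a_other)))
  truth
}

# E[X^k | lo <= X <= hi] for X ~ Lognormal(mu, sigma)
truncated_lognormal_moment <- function(k, mu, sigma, lo, hi) {
  z <- function(x, shift = 0) (log(x) - mu - shift * sigma^2) / sigma
  num <- pnorm(z(hi, k)) - pnorm(z(lo, k))
  den <- pnorm(z(hi)) - pnorm(z(lo))
  exp(k * mu + k^2 * sigma^2 / 2) * num / den
}

# inverse-CDF sampler for lognormal ESD truncated to [lo, hi] um
sample_truncated_esd <- function(n, median, sdlog, lo = 3, hi = 100) {
  mu <- log(median)
  p_lo <- plnorm(lo, mu, sdlog)
  p_hi <- plnorm(hi, mu, sdlog)
  qlnorm(runif(n, p_lo, p_hi), mu, sdlog)
}

#' Generate classified cell observations from the ground truth
#'
#' Emulates the output of an imaging flow cytometer's classifier: one
#' row per imaged particle with taxon label and biovolume. Cells are
#' spheres drawn from each taxon's lognormal equivalent-spherical-
#' diameter distribution truncated to 3-100 um; the number of cells per
#' station and taxon is Poisson with mean chosen so the expected summed
#' carbon (under the supplied allometric coefficients) equals the true
#' biomass times the analyzed volume.
#'
#' @param config A [cruise_config()].
#' @param truth Ground-truth tibble from [generate_biomass_field()].
#' @param coeffs Allometric coefficients used to size the cell draw;
#'   use the same coefficients downstream so recovered biomass is
#'   unbiased.
#' @return Cell observation tibble (`roi_id`, `sample_id`,
#'   `taxon_group`, `biovolume_um3`, `latitude`, `sample_volume_L`).
#' @export
generate_cells <- function(config, truth = generate_biomass_field(config),
                           coeffs = default_allometric_coefficients()) {
  stopifnot(inherits(config, "cruise_config"))
  validate_coefficients(coeffs)
  spec <- config$taxa
  with_seed(config$seed + 1L, {
    cells <- pmap(truth, function(station_id, latitude, taxon_group,
                                  biomass, transcripts_true, ...) {
      ts <- spec[spec$name == taxon_group, ]
      cf <- coeffs[coeffs$taxon_group == taxon_group, ]
      # mean carbon quota (pg) under the truncated size distribution:
      # q = a * (pi/6)^b * d^(3b), d lognormal truncated to [3, 100]
      mean_quota <- cf$coefficient_a * (pi / 6)^cf$exponent_b *
        truncated_lognormal_moment(3 * cf$exponent_b, log(ts$esd_median),
                                   ts$esd_sdlog, 3, 100)
      target_pg <- biomass * config$ifcb_volume * 1e6
      n <- rpois(1, target_pg / mean_quota)
      if (n == 0) return(NULL)
      esd <- sample_truncated_esd(n, ts$esd_median, ts$esd_sdlog)
      tibble(
        sample_id = paste0(station_id, "_ifcb"),
        taxon_group = taxon_group,
        biovolume_um3 = pi / 6 * esd^3,
        latitude = latitude,
        sample_volume_L = config$ifcb_volume
      )
    })
    cells <- bind_rows(cells)
  })
  if (nrow(cells) == 0) {
    return(tibble(roi_id = character(), sample_id = character(),
                  taxon_group = character(), biovolume_um3 = double(),
                  latitude = double(), sample_volume_L = double()))
  }
  cells |>
    mutate(roi_id = sprintf("roi_%06d", row_number())) |>
    select("roi_id", everything())
}

# split `total` counts over weights; rmultinom when the total fits in
# an integer, deterministic largest-remainder apportionment otherwise
split_counts <- function(total, weights) {
  if (total == 0) return(rep(0, length(weights)))
  if (total <= .Machine$integer.max) {
    as.numeric(rmultinom(1, total, weights))
  } else {
    raw <- total * weights / sum(weights)
    base <- floor(raw)
    rem <- total - sum(base)
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
    base
  }
}

#' Generate contig counts and spike-in manifests from the ground truth
#'
#' For every station and biological replicate: the true per-taxon
#' transcript concentration is perturbed by multiplicative lognormal
#' noise (`10^epsilon`, `epsilon ~ N(0, noise_sd_log10)`), a spike-in
#' recovery and filtered volume are drawn uniformly from the configured
#' ranges, and the implied raw mapped-read total (concentration divided
#' by the sample's normalization factor) is rounded half-to-even and
#' spread over the taxon's contigs by a Dirichlet-multinomial draw.
#' Contig identities, their Dirichlet weights and their KO-annotation
#' flags (a `functional_fraction` share of transcripts, in expectation)
#' are fixed per cruise, emulating a shared assembly.
#'
#' @param config A [cruise_config()].
#' @param truth Ground-truth tibble from [generate_biomass_field()].
#' @return List with `counts` (contig count tibble: `sample_id`,
#'   `contig_id`, `taxon_group`, `ko_id`, `mapped_reads`) and
#'   `manifest` (spike-in manifest tibble: `sample_id`, `latitude`,
#'   `standards_added`, `standards_retrieved`, `volume_L`,
#'   `replicate_id`).
#' @export
generate_transcriptome <- function(config,
                                   truth = generate_biomass_field(config)) {
  stopifnot(inherits(config, "cruise_config"))
  nc <- config$n_contigs
  with_seed(config$seed + 2L, {
    # fixed per-cruise "assembly": contig weights and KO flags per taxon
    assembly <- config$taxa$name |>
      setNames(nm = config$taxa$name) |>
      map(function(tx) {
        w <- rgamma(nc, shape = 1)   # symmetric Dirichlet(1)
        list(
          contig_id = sprintf("%s_c%04d", abbreviate(tx, 6), seq_len(nc)),
          weights = w / sum(w),
          ko_id = ifelse(runif(nc) < config$functional_fraction,
                         sprintf("K%05d", sample.int(99999, nc)),
                         NA_character_)
        )
      })

    stations <- truth |> distinct(.data$station_id, .data$latitude)
    samples <- crossing(stations,
                        replicate_id = sprintf("r%d", seq_len(config$n_replicates))) |>
      mutate(
        sample_id = paste(.data$station_id, .data$replicate_id, sep = "_"),
        recovery = runif(n(), config$recovery_range[1],
                         config$recovery_range[2]),
        volume_L = runif(n(), config$volume_range[1],
                         config$volume_range[2]),
        standards_added = config$spike_added,
        standards_retrieved = pmax(round(config$spike_added * .data$recovery), 1)
      )

    counts <- map_dfr(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      factor_i <- (s$standards_added / s$standards_retrieved) / s$volume_L
      tr <- truth |> filter(.data$station_id == s$station_id)
      map_dfr(seq_len(nrow(tr)), function(j) {
        eps <- rnorm(1, 0, config$noise_sd_log10)
        conc <- tr$transcripts_true[j] * 10^eps      # 1e9 transcripts / L
        total <- round(conc * 1e9 / factor_i)        # half-to-even
        asm <- assembly[[tr$taxon_group[j]]]
        reads <- split_counts(total, asm$weights)
        keep <- reads > 0
        tibble(sample_id = s$sample_id,
               contig_id = asm$contig_id[keep],
               taxon_group = tr$taxon_group[j],
               ko_id = asm$ko_id[keep],
               mapped_reads = reads[keep])
      })
    })
  })
  manifest <- samples |>
    select("sample_id", latitude = "latitude",
           "standards_added", "standards_retrieved", "volume_L",
           "replicate_id")
  list(counts = counts, manifest = manifest)
}

#' Generate a complete synthetic cruise
#'
#' Runs [generate_biomass_field()], [generate_cells()] and
#' [generate_transcriptome()] under one configuration.
#'
#' @param config A [cruise_config()].
#' @param coeffs Allometric coefficients shared with the biomass stage.
#' @return List with `config`, `truth`, `cells`, `counts`, `manifest`.
#' @export
generate_cruise <- function(config = cruise_config(),
                            coeffs = default_allometric_coefficients()) {
  truth <- generate_biomass_field(config)
  cells <- generate_cells(config, truth, coeffs)
  tx <- generate_transcriptome(config, truth)
  list(config = config, truth = truth, cells = cells,
       counts = tx$counts, manifest = tx$manifest)
}

#' Write a synthetic cruise to a directory
#'
#' Writes the three downstream input tables (`cells.tsv`,
#' `contig_counts.tsv`, `spikein_manifest.tsv`), the ground truth
#' (`ground_truth.tsv`) and a YAML echo of the configuration
#' (`config.yml`).
#'
#' @param cruise List from [generate_cruise()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cruise <- function(cruise, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cells = file.path(outdir, "cells.tsv"),
    counts = file.path(outdir, "contig_counts.tsv"),
    manifest = file.path(outdir, "spikein_manifest.tsv"),
    truth = file.path(outdir, "ground_truth.tsv"),
    config = file.path(outdir, "config.yml")
  )
  readr::write_tsv(cruise$cells, paths["cells"])
  readr::write_tsv(cruise$counts, paths["counts"], na = "")
  readr::write_tsv(cruise$manifest, paths["manifest"])
  readr::write_tsv(cruise$truth, paths["truth"])
  cfg <- cruise$config
  cfg$taxa <- as.data.frame(cfg$taxa)
  yaml::write_yaml(unclass(cfg), paths["config"],
                   column.major = FALSE)
  invisible(paths)
}
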