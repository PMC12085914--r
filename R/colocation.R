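#' Average biological replicates per station
#'
#' Replicate samples collected at the same station (identified by a
#' shared latitude) are averaged on the linear concentration scale, the
#' default because downstream error bars are linear-scale standard
#' deviations; set `scale = "log10"` to average log-transformed values
#' instead (geometric mean).
#'
#' @param concentrations Transcript concentration tibble from
#'   [taxon_concentrations()] (columns `sample_id`, `latitude`,
#'   `taxon_group`, `pool`, `concentration`).
#' @param scale `"linear"` (default) or `"log10"`.
#' @return Tibble with one row per station x taxon x pool: `station_id`,
#'   `latitude`, `taxon_group`, `pool`, `concentration` (the replicate
#'   mean), `concentration_sd` (sample SD on the averaging scale; `NA`
#'   for single replicates) and `n_replicates`.
#' @export
average_replicates <- function(concentrations, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  check_columns(concentrations, c("sample_id", "latitude", "taxon_group",
                                  "pool", "concentration"),
                "concentrations")
  out <- concentrations |>
    group_by(.data$latitude, .data$taxon_group, .data$pool) |>
    summarise(
      # SD first: summarise evaluates sequentially, and `concentration`
      # is overwritten by its replicate mean below
      concentration_sd = if (scale == "linear") sd(.data$concentration) else
        sd(log10(pmax(.data$concentration, .Machine$double.xmin))),
      n_replicates = n(),
      concentration = if (scale == "linear") mean(.data$concentration) else
        10^mean(log10(pmax(.data$concentration, .Machine$double.xmin))),
      .groups = "drop"
    )
  out |>
    mutate(station_id = sprintf("st_%05.2f", .data$latitude)) |>
    select("station_id", "latitude", "taxon_group", "pool",
           "concentration", "concentration_sd", "n_replicates") |>
    arrange(.data$latitude, match(.data$taxon_group, all_taxon_levels()),
            .data$pool)
}

#' Match transcript stations to nearest 1-degree biomass bins
#'
#' Pairs each station-averaged transcript concentration with the mean
#' carbon biomass of the nearest 1-degree latitude bin (distance taken
#' to bin centers, `bin + 0.5`; ties broken toward the equatorward bin).
#' Stations farther than `max_distance` from every bin center are
#' dropped with a warning, as are pairs whose carbon or transcript
#' value is zero (not log-transformable).
#'
#' @param concentrations Station-level concentrations from
#'   [average_replicates()] (or any tibble with `latitude`,
#'   `taxon_group`, `pool`, `concentration`).
#' @param bins Biomass bins from [bin_latitude()].
#' @param max_distance Maximum station-to-bin-center distance in
#'   degrees (default 1.0).
#' @return Matched point tibble with columns `station_id`, `latitude`,
#'   `latitude_bin`, `taxon_group`, `pool`, `carbon` (ug C L^-1),
#'   `transcripts` (1e9 transcripts L^-1), `log10_carbon`,
#'   `log10_transcripts`.
#' @export
match_samples <- function(concentrations, bins, max_distance = 1.0) {
  check_columns(concentrations, c("latitude", "taxon_group", "pool",
                                  "concentration"), "concentrations")
  check_columns(bins, c("latitude_bin", "taxon_group", "mean_biomass"),
                "bins")
  if (nrow(concentrations) == 0) {
    abort("empty concentration table: nothing to match")
  }
  if (nrow(bins) == 0) {
    abort("empty biomass bin table: nothing to match against")
  }
  if (!"station_id" %in% names(concentrations)) {
    concentrations <- concentrations |>
      mutate(station_id = sprintf("st_%05.2f", .data$latitude))
  }

  bin_values <- sort(unique(bins$latitude_bin))
  # nearest bin center; a tie can only happen at a bin edge (integer
  # latitude), where the half-open [d, d + 1) floor convention makes the
  # containing (poleward) bin the consistent choice; if the containing
  # bin is unavailable, fall back to the equatorward candidate
  nearest <- vapply(concentrations$latitude, function(lat) {
    d <- abs(lat - (bin_values + 0.5))
    i <- which(d <= min(d) + 1e-9)
    if (length(i) > 1) {
      containing <- which(bin_values[i] == floor(lat))
      i <- if (length(containing) == 1) i[containing] else i[1]
    }
    c(bin = bin_values[i], dist = d[i])
  }, c(bin = 0, dist = 0))
  concentrations$latitude_bin <- as.integer(nearest["bin", ])
  concentrations$bin_distance <- nearest["dist", ]

  too_far <- concentrations$bin_distance > max_distance
  if (any(too_far)) {
    warn(sprintf(
      "%d station x taxon x pool rows beyond max_distance = %g of any bin center were dropped (stations: %s)",
      sum(too_far), max_distance,
      paste(unique(concentrations$station_id[too_far]), collapse = ", ")
    ))
    concentrations <- concentrations[!too_far, , drop = FALSE]
  }

  matched <- concentrations |>
    inner_join(bins |> select("latitude_bin", "taxon_group", "mean_biomass"),
               by = c("latitude_bin", "taxon_group")) |>
    rename(carbon = "mean_biomass", transcripts = "concentration")

  zero <- matched$carbon <= 0 | matched$transcripts <= 0
  if (any(zero)) {
    inform(sprintf(
      "%d matched pairs with zero carbon or zero transcripts were dropped",
      sum(zero)
    ))
    matched <- matched[!zero, , drop = FALSE]
  }

  matched |>
    mutate(log10_carbon = log10(.data$carbon),
           log10_transcripts = log10(.data$transcripts)) |>
    select("station_id", "latitude", "latitude_bin", "taxon_group", "pool",
           "carbon", "transcripts", "log10_carbon", "log10_transcripts") |>
    arrange(.data$latitude, match(.data$taxon_group, all_taxon_levels()),
            .data$pool)
}
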