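#' Per-sample taxon carbon biomass from classified cell observations
#'
#' Sums cellular carbon quotas (from [cell_carbon()]) over all imaged
#' cells of each sample and taxon group and converts to a concentration
#' in ug C per liter using the analyzed sample volume. Taxa of the
#' canonical set with no cells in a sample are reported with biomass 0.
#'
#' @param cells Cell observation tibble with columns `roi_id`,
#'   `sample_id`, `taxon_group`, `biovolume_um3`, `latitude`,
#'   `sample_volume_L`. One row per imaged particle.
#' @param coeffs Allometric coefficients; see
#'   [default_allometric_coefficients()].
#' @return Tibble with one row per `sample_id` x `taxon_group`:
#'   `sample_id`, `latitude`, `sample_volume_L`, `taxon_group`,
#'   `biomass` (ug C L^-1) and `n_cells`.
#' @export
sample_biomass <- function(cells, coeffs = default_allometric_coefficients()) {
  check_columns(cells, c("sample_id", "taxon_group", "biovolume_um3",
                         "latitude", "sample_volume_L"), "cells")
  validate_coefficients(coeffs)
  if (nrow(cells) == 0) {
    return(tibble(sample_id = character(), latitude = double(),
                  sample_volume_L = double(), taxon_group = character(),
                  biomass = double(), n_cells = integer()))
  }
  if (any(cells$biovolume_um3 <= 0)) {
    abort("`biovolume_um3` must be > 0 for every cell")
  }
  bad_vol <- cells |>
    group_by(.data$sample_id) |>
    summarise(n_vol = n_distinct(.data$sample_volume_L),
              n_lat = n_distinct(.data$latitude), .groups = "drop") |>
    filter(.data$n_vol > 1 | .data$n_lat > 1)
  if (nrow(bad_vol) > 0) {
    abort(sprintf(
      "inconsistent sample_volume_L or latitude within sample(s): %s",
      paste(bad_vol$sample_id, collapse = ", ")
    ))
  }
  cells |>
    mutate(taxon_group = canonicalize_taxon(.data$taxon_group),
           carbon_pg = cell_carbon(.data$biovolume_um3, .data$taxon_group,
                                   coeffs)) |>
    group_by(.data$sample_id, .data$latitude, .data$sample_volume_L,
             .data$taxon_group) |>
    summarise(biomass = sum(.data$carbon_pg) /
                (.data$sample_volume_L[1] * 1e6),  # pg -> ug, per liter
              n_cells = n(), .groups = "drop") |>
    # canonical taxa absent from a sample get biomass 0
    complete(
      tidyr::nesting(!!sym("sample_id"), !!sym("latitude"),
                     !!sym("sample_volume_L")),
      taxon_group = all_taxon_levels(),
      fill = list(biomass = 0, n_cells = 0L)
    ) |>
    arrange(.data$sample_id, match(.data$taxon_group, all_taxon_levels()))
}

#' Aggregate per-sample biomass to 1-degree latitude bins
#'
#' Bins samples by the floor of their latitude (half-open `[d, d + 1)`
#' bins) and averages biomass per taxon group over the sampling volumes
#' falling in each bin, with an unweighted arithmetic mean.
#'
#' @param biomass Per-sample biomass tibble from [sample_biomass()]
#'   (columns `sample_id`, `latitude`, `taxon_group`, `biomass`).
#' @return Tibble with columns `latitude_bin` (integer degree),
#'   `taxon_group`, `mean_biomass` (ug C L^-1) and `n_volumes`.
#' @export
bin_latitude <- function(biomass) {
  check_columns(biomass, c("sample_id", "latitude", "taxon_group", "biomass"),
                "biomass")
  if (any(!is.finite(biomass$latitude))) {
    abort("`latitude` must be finite")
  }
  biomass |>
    mutate(latitude_bin = as.integer(floor(.data$latitude))) |>
    group_by(.data$latitude_bin, .data$taxon_group) |>
    summarise(mean_biomass = mean(.data$biomass),
              n_volumes = n_distinct(.data$sample_id), .groups = "drop") |>
    arrange(.data$latitude_bin, match(.data$taxon_group, all_taxon_levels()))
}

#' Read a classified cell observation table
#'
#' @param path Tab-separated headered file with columns `roi_id`,
#'   `sample_id`, `taxon_group`, `biovolume_um3`, `latitude`,
#'   `sample_volume_L`.
#' @return Cell observation tibble.
#' @export
read_cells <- function(path) {
  cells <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(cells, c("roi_id", "sample_id", "taxon_group",
                         "biovolume_um3", "latitude", "sample_volume_L"),
                path)
  as_tibble(cells)
}
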