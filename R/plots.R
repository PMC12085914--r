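#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a transcript-to-carbon calibration
#'
#' Log-log scatter of matched points with the fitted Dinoflagellate and
#' pooled non-Dinoflagellate power laws overlaid, one panel per mRNA
#' pool.
#'
#' @param object A `calibration` object from [calibrate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration <- function(object, ...) {
  pts <- object$points |>
    filter(.data$taxon_group %in% taxon_levels()) |>
    mutate(group = ifelse(.data$taxon_group == "Dinoflagellata",
                          "Dinoflagellate", "non-Dinoflagellate"))
  lines <- map_dfr(object$fits, function(f) {
    rng <- range(pts$log10_carbon[pts$pool == f$pool])
    tibble(pool = f$pool, group = f$group,
           log10_carbon = seq(rng[1], rng[2], length.out = 20)) |>
      mutate(log10_transcripts = log10(f$intercept_a) +
               f$slope_b * .data$log10_carbon)
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$log10_carbon,
                                    .data$log10_transcripts,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = lines) +
    ggplot2::facet_wrap(~pool) +
    ggplot2::labs(
      x = expression(log[10] ~ "C biomass (" * mu * "g C " * L^-1 * ")"),
      y = expression(log[10] ~ "transcripts (" * 10^9 ~ L^-1 * ")"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot biomass and transcript transects
#'
#' Latitudinal overview of a run: per-bin mean carbon biomass and
#' station-mean transcript concentrations, stacked by taxon group.
#'
#' @param bins Biomass bin tibble from [bin_latitude()].
#' @param concentrations Station-level concentrations from
#'   [average_replicates()] (optional).
#' @param pool Pool to show from `concentrations`.
#' @return A ggplot object.
#' @export
plot_transect <- function(bins, concentrations = NULL, pool = "total") {
  bins <- bins |> filter(.data$taxon_group %in% taxon_levels())
  p <- ggplot2::ggplot(bins,
                       ggplot2::aes(.data$latitude_bin + 0.5,
                                    .data$mean_biomass,
                                    fill = .data$taxon_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "latitude (°N)",
                  y = expression("C biomass (" * mu * "g C " * L^-1 * ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(concentrations)) {
    conc <- concentrations |>
      filter(.data$pool == !!pool, .data$taxon_group %in% taxon_levels()) |>
      group_by(.data$latitude) |>
      summarise(concentration = sum(.data$concentration), .groups = "drop")
    p <- p + ggplot2::geom_point(
      data = conc,
      ggplot2::aes(.data$latitude, .data$concentration),
      inherit.aes = FALSE, shape = 17
    )
  }
  p
}
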