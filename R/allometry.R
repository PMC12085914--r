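#' Default allometric carbon-to-volume coefficients
#'
#' Per-taxon coefficients of the allometric relation `C = a * V^b` giving
#' cellular carbon (pg C) from biovolume (um^3). Defaults follow the
#' widely used protist/diatom regressions: diatoms carry less carbon per
#' unit volume than other protists because of the vacuole, so
#' Bacillariophyta gets `a = 0.288, b = 0.811` and every other group
#' `a = 0.216, b = 0.939`. Override by editing the returned tibble or by
#' supplying a coefficients file to [read_allometric_coefficients()].
#'
#' @return A tibble with columns `taxon_group`, `coefficient_a`
#'   (pg C per um^(3b)), `exponent_b` (dimensionless) and `source`.
#' @export
#' @examples
#' default_allometric_coefficients()
default_allometric_coefficients <- function() {
  tibble(
    taxon_group = all_taxon_levels(),
    coefficient_a = ifelse(all_taxon_levels() == "Bacillariophyta", 0.288, 0.216),
    exponent_b = ifelse(all_taxon_levels() == "Bacillariophyta", 0.811, 0.939),
    source = ifelse(all_taxon_levels() == "Bacillariophyta",
                    "diatom regression", "protist regression")
  )
}

validate_coefficients <- function(coeffs) {
  check_columns(coeffs, c("taxon_group", "coefficient_a", "exponent_b"),
                "coeffs")
  if (any(coeffs$coefficient_a <= 0)) {
    abort("configuration error: allometric `coefficient_a` must be > 0",
          class = "dinofactor_config_error")
  }
  if (any(coeffs$exponent_b <= 0 | coeffs$exponent_b > 1.2)) {
    abort("configuration error: allometric `exponent_b` must be in (0, 1.2]",
          class = "dinofactor_config_error")
  }
  invisible(coeffs)
}

#' Read allometric coefficients from a key-value file
#'
#' Expects a tab-separated headered table with columns `taxon_group`,
#' `coefficient_a`, `exponent_b` and optionally `source`.
#'
#' @param path Path to the coefficients file.
#' @return Coefficients tibble as in [default_allometric_coefficients()].
#' @export
read_allometric_coefficients <- function(path) {
  coeffs <- readr::read_tsv(path, show_col_types = FALSE)
  validate_coefficients(coeffs)
  as_tibble(coeffs)
}

#' Cellular carbon from biovolume
#'
#' Converts per-cell biovolume to cellular carbon content via the
#' allometric relation `C = a * V^b`, with taxon-specific coefficients.
#'
#' @param biovolume Numeric vector of cell biovolumes in um^3; must be > 0.
#' @param taxon Character vector of taxon-group labels, recycled against
#'   `biovolume`.
#' @param coeffs Allometric coefficients tibble; see
#'   [default_allometric_coefficients()].
#' @return Numeric vector of cellular carbon quotas in pg C.
#' @export
#' @examples
#' cell_carbon(1000, "Dinoflagellata")
cell_carbon <- function(biovolume, taxon,
                        coeffs = default_allometric_coefficients()) {
  validate_coefficients(coeffs)
  if (any(!is.finite(biovolume)) || any(biovolume <= 0)) {
    abort("`biovolume` must be finite and > 0")
  }
  idx <- match(taxon, coeffs$taxon_group)
  if (anyNA(idx)) {
    abort(sprintf(
      "configuration error: no allometric coefficients for taxon group(s): %s",
      paste(unique(taxon[is.na(idx)]), collapse = ", ")
    ), class = "dinofactor_config_error")
  }
  coeffs$coefficient_a[idx] * biovolume^coeffs$exponent_b[idx]
}
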