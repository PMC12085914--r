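#' Spike-in normalization factor per sample
#'
#' Each sample receives a known number of synthetic RNA standard
#' molecules before extraction; the fraction retrieved after sequencing
#' calibrates absolute quantification. The per-sample factor converting
#' mapped-read counts to transcripts per liter is
#'
#' `factor = (standards_added / standards_retrieved) / volume_L`
#'
#' @param manifest Spike-in manifest tibble with columns `sample_id`,
#'   `standards_added`, `standards_retrieved`, `volume_L` (and typically
#'   `latitude`, `replicate_id`, which are carried through).
#' @return The input tibble with an added `norm_factor` column
#'   (transcripts per mapped read per liter).
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = "s1", standards_added = 1e6,
#'                     standards_retrieved = 5e5, volume_L = 2)
#' normalization_factor(m)$norm_factor  # 1.0
normalization_factor <- function(manifest) {
  check_columns(manifest, c("sample_id", "standards_added",
                            "standards_retrieved", "volume_L"), "manifest")
  bad <- with(manifest, !is.finite(standards_added) | standards_added <= 0 |
                !is.finite(standards_retrieved) | standards_retrieved <= 0 |
                !is.finite(volume_L) | volume_L <= 0)
  if (any(bad)) {
    abort(sprintf(
      "invalid spike-in manifest (non-positive standards or volume) for sample(s): %s",
      paste(unique(manifest$sample_id[bad]), collapse = ", ")
    ), class = "dinofactor_validation_error")
  }
  over <- manifest$standards_retrieved > manifest$standards_added
  if (any(over)) {
    warn(sprintf(
      "standards_retrieved exceeds standards_added (recovery > 1) for sample(s): %s",
      paste(unique(manifest$sample_id[over]), collapse = ", ")
    ))
  }
  manifest |>
    mutate(norm_factor = (.data$standards_added / .data$standards_retrieved) /
             .data$volume_L)
}

#' Filter contigs by minimum mapped-read support
#'
#' Retains per-sample contig rows with at least `min_reads` mapped
#' transcripts (default 10), the support threshold applied before any
#' normalization or pooling. Row order is preserved.
#'
#' @param counts Contig count tibble with column `mapped_reads`.
#' @param min_reads Minimum mapped reads for a row to be kept.
#' @return Filtered tibble with the same columns.
#' @export
filter_contigs <- function(counts, min_reads = 10) {
  check_columns(counts, "mapped_reads", "counts")
  counts |> filter(.data$mapped_reads >= min_reads)
}

#' Absolute transcript concentrations per taxon group
#'
#' Applies per-sample spike-in normalization factors to mapped-read
#' counts and sums per taxon group, for both the functional pool (rows
#' carrying a KO annotation) and the total pool (all rows). Canonical
#' taxa with no surviving contigs in a sample get concentration 0 in
#' both pools.
#'
#' @param counts Filtered contig count tibble with columns `sample_id`,
#'   `contig_id`, `taxon_group`, `ko_id` (NA or empty when
#'   unannotated), `mapped_reads`. Apply [filter_contigs()] first.
#' @param manifest Spike-in manifest tibble (one row per `sample_id`).
#' @return Tibble with columns `sample_id`, `latitude`, `replicate_id`
#'   (if present in the manifest), `taxon_group`, `pool`
#'   (`"functional"` or `"total"`) and `concentration` in units of
#'   1e9 transcripts per liter.
#' @export
taxon_concentrations <- function(counts, manifest) {
  check_columns(counts, c("sample_id", "contig_id", "taxon_group",
                          "mapped_reads"), "counts")
  if (!"ko_id" %in% names(counts)) counts$ko_id <- NA_character_
  if (any(counts$mapped_reads < 0)) {
    abort("`mapped_reads` must be non-negative")
  }
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate manifest rows for sample(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "dinofactor_validation_error")
  }
  orphan <- setdiff(unique(counts$sample_id), manifest$sample_id)
  if (length(orphan) > 0) {
    abort(sprintf("no spike-in manifest row for sample(s): %s",
                  paste(orphan, collapse = ", ")),
          class = "dinofactor_validation_error")
  }
  manifest <- normalization_factor(manifest)
  carry <- intersect(c("latitude", "replicate_id"), names(manifest))

  counts |>
    mutate(taxon_group = canonicalize_taxon(.data$taxon_group),
           is_functional = !is.na(.data$ko_id) & .data$ko_id != "") |>
    left_join(manifest |> select(all_of(c("sample_id", "norm_factor"))),
              by = "sample_id") |>
    group_by(.data$sample_id, .data$taxon_group) |>
    summarise(
      total = sum(.data$mapped_reads * .data$norm_factor) / 1e9,
      functional = sum(.data$mapped_reads[.data$is_functional] *
                         .data$norm_factor[.data$is_functional]) / 1e9,
      .groups = "drop"
    ) |>
    # every manifest sample reports all canonical taxa, zero-filled
    complete(sample_id = manifest$sample_id,
             taxon_group = all_taxon_levels(),
             fill = list(total = 0, functional = 0)) |>
    left_join(manifest |> select(all_of(c("sample_id", carry))),
              by = "sample_id") |>
    pivot_longer(c("functional", "total"), names_to = "pool",
                 values_to = "concentration") |>
    arrange(.data$sample_id, match(.data$taxon_group, all_taxon_levels()),
            .data$pool)
}

#' Read a contig count table
#'
#' @param path Tab-separated headered file with columns `sample_id`,
#'   `contig_id`, `taxon_group`, `ko_id`, `mapped_reads`. Empty `ko_id`
#'   means no functional annotation.
#' @return Contig count tibble.
#' @export
read_contig_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(ko_id = readr::col_character()))
  check_columns(counts, c("sample_id", "contig_id", "taxon_group",
                          "ko_id", "mapped_reads"), path)
  as_tibble(counts)
}

#' Read a spike-in manifest table
#'
#' @param path Tab-separated headered file with columns `sample_id`,
#'   `latitude`, `standards_added`, `standards_retrieved`, `volume_L`,
#'   `replicate_id`.
#' @return Manifest tibble.
#' @export
read_spikein_manifest <- function(path) {
  manifest <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(manifest, c("sample_id", "latitude", "standards_added",
                            "standards_retrieved", "volume_L",
                            "replicate_id"), path)
  as_tibble(manifest)
}
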