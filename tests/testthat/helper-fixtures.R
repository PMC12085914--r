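# small in-code fixtures shared across test files

make_manifest <- function(n = 1, sample_id = paste0("s", seq_len(n)),
                          latitude = 25 + seq_len(n), added = 1e6,
                          retrieved = 5e5, volume = 2,
                          replicate_id = "r1") {
  tibble::tibble(
    sample_id = sample_id, latitude = latitude,
    standards_added = added, standards_retrieved = retrieved,
    volume_L = volume, replicate_id = replicate_id
  )
}

make_counts <- function(sample_id, contig_id, taxon_group, mapped_reads,
                        ko_id = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, contig_id = contig_id,
    taxon_group = taxon_group, ko_id = ko_id,
    mapped_reads = mapped_reads
  )
}

# cells with unit allometry (a = 1, b = 1) so carbon == biovolume in pg
unit_coeffs <- function() {
  tibble::tibble(
    taxon_group = c(taxon_levels(), "other"),
    coefficient_a = 1, exponent_b = 1, source = "unit"
  )
}

make_cells <- function(biovolume, taxon_group = "Dinoflagellata",
                       sample_id = "ifcb1", latitude = 30.5,
                       sample_volume_L = 1) {
  n <- length(biovolume)
  tibble::tibble(
    roi_id = paste0("roi", seq_len(n)), sample_id = sample_id,
    taxon_group = taxon_group, biovolume_um3 = biovolume,
    latitude = latitude, sample_volume_L = sample_volume_L
  )
}

# matched points lying exactly on T = a * C^b
power_law_points <- function(a, b, log10_c, taxon_group = "Dinoflagellata",
                             pool = "total") {
  tibble::tibble(
    taxon_group = taxon_group, pool = pool,
    carbon = 10^log10_c, transcripts = a * (10^log10_c)^b,
    log10_carbon = log10_c,
    log10_transcripts = log10(a * (10^log10_c)^b)
  )
}
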