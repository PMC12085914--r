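default_pipeline_config <- function() {
  list(
    cruise = list(seed = 42),
    normalize = list(min_reads = 10),
    match = list(max_distance = 1.0, replicate_scale = "linear"),
    calibrate = list(pools = c("functional", "total"),
                     factor_method = "intercept_ratio",
                     cruise_label = "synthetic",
                     use_true_biomass = FALSE)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("cannot read configuration file: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or the path to a YAML file")
  }
  cfg <- default_pipeline_config()
  for (section in names(config)) {
    cfg[[section]] <- utils::modifyList(cfg[[section]] %||% list(),
                                        as.list(config[[section]]))
  }
  known <- c("seed", "lat_min", "lat_max", "n_stations", "n_replicates",
             "taxa", "spike_added", "recovery_range", "volume_range",
             "noise_sd_log10", "functional_fraction", "n_contigs",
             "ifcb_volume")
  stray <- setdiff(names(cfg$cruise), known)
  if (length(stray) > 0) {
    abort(sprintf("unknown cruise configuration field(s): %s",
                  paste(stray, collapse = ", ")),
          class = "dinofactor_config_error")
  }
  if (!is.null(cfg$cruise$taxa) && !is.data.frame(cfg$cruise$taxa)) {
    cfg$cruise$taxa <- as_tibble(bind_rows(cfg$cruise$taxa))
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)),
          class = "dinofactor_stage_error", parent = e)
  })
}

#' Run the full synthetic-cruise calibration pipeline
#'
#' Orchestrates generate -> normalize -> biomass -> match -> calibrate
#' from one configuration, writing every stage's table plus a run
#' manifest (config hash, seed, file checksums) into `outdir`. Reruns
#' with the same configuration and seed reproduce byte-identical
#' output tables.
#'
#' @param config Path to a YAML configuration file or an equivalent
#'   nested list. Sections: `cruise` (arguments of [cruise_config()]),
#'   `normalize` (`min_reads`), `match` (`max_distance`,
#'   `replicate_scale`), `calibrate` (`pools`, `factor_method`,
#'   `cruise_label`, `use_true_biomass`). Missing fields take defaults.
#' @param outdir Output directory for all stage tables.
#' @param seed Optional override of the cruise seed.
#' @return Invisibly, a list with the `calibration` object, all
#'   intermediate tables and the run manifest.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("dinofactor_run_"),
                         seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$cruise$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cruise <- run_stage("synth", {
    cc <- do.call(cruise_config, cfg$cruise)
    cr <- generate_cruise(cc)
    write_cruise(cr, file.path(outdir, "synthetic"))
    cr
  })

  concentrations <- run_stage("normalize", {
    n0 <- nrow(cruise$counts)
    kept <- filter_contigs(cruise$counts, min_reads = cfg$normalize$min_reads)
    inform(sprintf("normalize: %d of %d contig rows pass the >= %d-read filter",
                   nrow(kept), n0, cfg$normalize$min_reads))
    conc <- taxon_concentrations(kept, cruise$manifest)
    readr::write_tsv(conc, file.path(outdir, "transcript_concentrations.tsv"))
    conc
  })

  bins <- run_stage("biomass", {
    if (isTRUE(cfg$calibrate$use_true_biomass)) {
      # bypass the stochastic cell stage: bin the generator's own truth
      b <- cruise$truth |>
        mutate(sample_id = paste0(.data$station_id, "_truth")) |>
        bin_latitude()
    } else {
      b <- bin_latitude(sample_biomass(cruise$cells))
    }
    readr::write_tsv(b, file.path(outdir, "biomass_bins.tsv"))
    b
  })

  points <- run_stage("match", {
    station_means <- average_replicates(
      concentrations, scale = cfg$match$replicate_scale)
    pts <- match_samples(station_means, bins,
                         max_distance = cfg$match$max_distance)
    inform(sprintf("match: %d matched points at %d locations",
                   nrow(pts), n_distinct(pts$latitude_bin)))
    readr::write_tsv(pts, file.path(outdir, "matched_points.tsv"))
    pts
  })

  cal <- run_stage("calibrate", {
    cal <- calibrate(points, pools = cfg$calibrate$pools,
                     cruise = cfg$calibrate$cruise_label,
                     factor_method = cfg$calibrate$factor_method)
    readr::write_tsv(cal$table, file.path(outdir, "calibration_report.tsv"))
    yaml::write_yaml(
      list(factors = lapply(cal$factors, function(f) unclass(f)),
           best_model = lapply(cal$model_comparison, `[[`, "best_model"),
           ancova = lapply(cal$ancova, function(a) {
             if (is.null(a)) NULL else
               list(p_carbon = a$p_carbon, p_taxon = a$p_taxon)
           })),
      file.path(outdir, "calibration_summary.yml"))
    cal
  })

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(outdir, "run_manifest.yml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dinofactor")),
    seed = cfg$cruise$seed,
    config_hash = unname(tools::md5sum(
      write_temp_yaml(cfg))),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = setNames(as.list(unname(tools::md5sum(outputs))),
                     substring(outputs, nchar(outdir) + 2L))
  )
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yml"))

  invisible(list(calibration = cal, points = points, bins = bins,
                 concentrations = concentrations, cruise = cruise,
                 manifest = manifest, outdir = outdir))
}

write_temp_yaml <- function(x) {
  path <- tempfile(fileext = ".yml")
  x$cruise$taxa <- if (!is.null(x$cruise$taxa)) as.data.frame(x$cruise$taxa)
  yaml::write_yaml(x, path)
  path
}

validate_one <- function(df, required, checks) {
  issues <- character()
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    issues <- c(issues, sprintf("missing column(s): %s",
                                paste(missing, collapse = ", ")))
    return(issues)
  }
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]](df))
    if (length(bad) > 0) {
      issues <- c(issues, sprintf("%s: row(s) %s", nm,
                                  paste(head(bad, 5), collapse = ", ")))
    }
  }
  issues
}

#' Validate pipeline input tables
#'
#' Checks schemas, enumerations and positivity invariants of the three
#' input table kinds. Unknown taxon labels trigger a warning (they are
#' mapped to `"other"` at run time), not a failure.
#'
#' @param paths Named character vector or list with any of `cells`,
#'   `counts`, `manifest` pointing to TSV files.
#' @return Tibble with one row per file: `table`, `path`, `pass` and
#'   `issues` (semicolon-separated messages, empty when passing).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  known <- c("cells", "counts", "manifest")
  if (is.null(names(paths)) || !all(names(paths) %in% known)) {
    abort(sprintf("`paths` must be named with any of: %s",
                  paste(known, collapse = ", ")))
  }
  map_dfr(names(paths), function(kind) {
    path <- paths[[kind]]
    if (!file.exists(path)) {
      abort(sprintf("cannot read input file: %s", path))
    }
    df <- readr::read_tsv(path, show_col_types = FALSE)
    issues <- switch(kind,
      cells = {
        iss <- validate_one(df,
          c("roi_id", "sample_id", "taxon_group", "biovolume_um3",
            "latitude", "sample_volume_L"),
          list("non-positive biovolume_um3" = function(d) d$biovolume_um3 > 0,
               "non-positive sample_volume_L" = function(d) d$sample_volume_L > 0,
               "non-finite latitude" = function(d) is.finite(d$latitude)))
        if (length(iss) == 0 && any(!(df$taxon_group %in% all_taxon_levels()))) {
          warn(sprintf("%s: unknown taxon labels will be mapped to \"other\"",
                       path))
        }
        iss
      },
      counts = validate_one(df,
        c("sample_id", "contig_id", "taxon_group", "mapped_reads"),
        list("negative mapped_reads" = function(d) d$mapped_reads >= 0)),
      manifest = validate_one(df,
        c("sample_id", "latitude", "standards_added", "standards_retrieved",
          "volume_L", "replicate_id"),
        list("non-positive standards_added" = function(d) d$standards_added > 0,
             "non-positive standards_retrieved" = function(d) d$standards_retrieved > 0,
             "non-positive volume_L" = function(d) d$volume_L > 0))
    )
    tibble(table = kind, path = path, pass = length(issues) == 0,
           issues = paste(issues, collapse = "; "))
  })
}
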