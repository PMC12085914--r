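#' Construct a power-law fit object
#'
#' Container for a fitted transcript-to-carbon power law `T = a * C^b`,
#' where `a` is the predicted transcript concentration (1e9 transcripts
#' L^-1) at `C = 1` ug C L^-1 and `b` the dimensionless log-log slope.
#' Useful for assembling fits from published regression tables as well
#' as holding the output of [fit_loglog()].
#'
#' @param intercept_a Intercept on the linear scale (must be > 0).
#' @param slope_b Log-log slope.
#' @param se_a Standard error of `intercept_a` on the linear scale.
#' @param se_b Standard error of `slope_b`.
#' @param n_points Number of points the fit used.
#' @param r_squared Coefficient of determination.
#' @param group Group label, e.g. `"Dinoflagellate"` or
#'   `"non-Dinoflagellate"`.
#' @param pool mRNA pool, `"functional"` or `"total"`.
#' @param cruise Cruise/run label.
#' @param model Optional underlying `lm` object.
#' @return An object of class `power_law_fit`.
#' @export
power_law_fit <- function(intercept_a, slope_b, se_a = NA_real_,
                          se_b = NA_real_, n_points = NA_integer_,
                          r_squared = NA_real_, group = NA_character_,
                          pool = NA_character_, cruise = NA_character_,
                          model = NULL) {
  if (!is.finite(intercept_a) || intercept_a <= 0) {
    abort("`intercept_a` must be finite and > 0")
  }
  structure(
    list(intercept_a = intercept_a, slope_b = slope_b,
         se_a = se_a, se_b = se_b,
         n_points = as.integer(n_points), r_squared = r_squared,
         group = group, pool = pool, cruise = cruise, model = model),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit T = a * C^b  [%s, %s pool, %s]\n  a = %.4g (SE %.3g)  b = %.4g (SE %.3g)  n = %d  R^2 = %.3g\n",
    x$group %||% NA, x$pool %||% NA, x$cruise %||% NA,
    x$intercept_a, x$se_a, x$slope_b, x$se_b, x$n_points, x$r_squared
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("intercept_a", "slope_b"),
    estimate = c(x$intercept_a, x$slope_b),
    std.error = c(x$se_a, x$se_b)
  )
}

#' @exportS3Method generics::glance
glance.power_law_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points,
         group = x$group, pool = x$pool, cruise = x$cruise)
}

# resolve a group label to the taxa it covers
group_taxa <- function(group) {
  switch(group,
    "Dinoflagellate" = "Dinoflagellata",
    "non-Dinoflagellate" = setdiff(taxon_levels(), "Dinoflagellata"),
    all = taxon_levels(),
    if (group %in% taxon_levels()) group else
      abort(sprintf("unknown group label: %s", group))
  )
}

#' Fit a log-log power law to matched transcript/carbon points
#'
#' Ordinary least squares of `log10(transcripts)` on `log10(carbon)`.
#' The fitted intercept is back-transformed to the linear scale
#' (`a = 10^intercept`) and its standard error propagated by the delta
#' method, `se_a = ln(10) * a * se_log_intercept`. For two-point fits
#' the line is reported but standard errors are suppressed (`NA`), since
#' no residual degrees of freedom remain.
#'
#' @param points Matched point tibble (needs `log10_carbon` and
#'   `log10_transcripts`, or linear `carbon`/`transcripts` from which
#'   they are computed).
#' @param group `"Dinoflagellate"`, `"non-Dinoflagellate"` (the pooled
#'   four other taxa), a single taxon name, or `"all"` (default) for all
#'   five canonical taxa. Rows labelled `"other"` are always excluded.
#' @param pool Optional pool filter (`"functional"` or `"total"`) when
#'   `points` has a `pool` column.
#' @param cruise Label stored on the fit.
#' @return A [power_law_fit()] object.
#' @export
fit_loglog <- function(points, group = "all", pool = NULL,
                       cruise = NA_character_) {
  check_columns(points, "taxon_group", "points")
  if (!all(c("log10_carbon", "log10_transcripts") %in% names(points))) {
    check_columns(points, c("carbon", "transcripts"), "points")
    points <- points |>
      mutate(log10_carbon = log10(.data$carbon),
             log10_transcripts = log10(.data$transcripts))
  }
  if (!is.null(pool) && "pool" %in% names(points)) {
    points <- points |> filter(.data$pool == !!pool)
  }
  points <- points |> filter(.data$taxon_group %in% group_taxa(group))

  n <- nrow(points)
  if (n < 2) {
    abort(sprintf("cannot fit power law for group %s: %d point(s), need >= 2",
                  group, n), class = "dinofactor_fit_error")
  }
  if (diff(range(points$log10_carbon)) == 0) {
    abort(sprintf("cannot fit power law for group %s: zero variance in log10 carbon",
                  group), class = "dinofactor_fit_error")
  }

  fit <- lm(log10_transcripts ~ log10_carbon, data = points)
  sm <- summary(fit)
  b0 <- unname(coef(fit)[1])
  b1 <- unname(coef(fit)[2])
  a <- 10^b0
  if (n > 2) {
    se_b0 <- sm$coefficients["(Intercept)", "Std. Error"]
    se_b1 <- sm$coefficients["log10_carbon", "Std. Error"]
    se_a <- log(10) * a * se_b0
  } else {
    se_a <- se_b1 <- NA_real_
  }
  power_law_fit(
    intercept_a = a, slope_b = b1, se_a = se_a, se_b = se_b1,
    n_points = n, r_squared = sm$r.squared,
    group = group, pool = pool %||% NA_character_, cruise = cruise,
    model = fit
  )
}

#' Compare linear, log-log and nonlinear transcript-carbon models by AIC
#'
#' Fits three candidate models to the matched points: (i) OLS of
#' transcripts on carbon on the untransformed scale, (ii) OLS of log10
#' transcripts on log10 carbon, (iii) nonlinear least squares of
#' `T = a * C^b` on the linear scale. Each is scored by Gaussian AIC
#' with k = 3 (two coefficients plus the error variance). The log-log
#' AIC is computed for the response actually fit (log10 T); AICs across
#' response scales are reported side by side but are not
#' likelihood-comparable in the strict sense.
#'
#' @param points Matched point tibble (columns `carbon`, `transcripts`).
#' @param pool Optional pool filter.
#' @return An object of class `model_comparison`: a list with a `table`
#'   tibble (`model`, `aic`, `response_scale`) and `best_model`.
#' @export
compare_models <- function(points, pool = NULL) {
  check_columns(points, c("carbon", "transcripts"), "points")
  if (!is.null(pool) && "pool" %in% names(points)) {
    points <- points |> filter(.data$pool == !!pool)
  }
  if (nrow(points) < 4) {
    abort(sprintf("model comparison needs >= 4 points, got %d", nrow(points)),
          class = "dinofactor_fit_error")
  }
  dat <- points |>
    mutate(log10_carbon = log10(.data$carbon),
           log10_transcripts = log10(.data$transcripts))

  fit_linear <- lm(transcripts ~ carbon, data = dat)
  fit_loglog <- lm(log10_transcripts ~ log10_carbon, data = dat)
  aic_nonlinear <- tryCatch({
    start <- list(a = 10^unname(coef(fit_loglog)[1]),
                  b = unname(coef(fit_loglog)[2]))
    fit_nls <- minpack.lm::nlsLM(transcripts ~ a * carbon^b, data = dat,
                                 start = start)
    AIC(fit_nls)
  }, error = function(e) {
    warn(sprintf("nonlinear power-law fit failed (%s); AIC set to Inf",
                 conditionMessage(e)))
    Inf
  })

  table <- tibble(
    model = c("linear", "loglog", "nonlinear"),
    aic = c(AIC(fit_linear), AIC(fit_loglog), aic_nonlinear),
    response_scale = c("T", "log10 T", "T")
  )
  structure(
    list(table = table, best_model = table$model[which.min(table$aic)]),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("AIC model comparison (k = 3, Gaussian likelihood)\n")
  print(x$table)
  cat("best model:", x$best_model, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.model_comparison <- function(x, ...) x$table

# connected-components merge of taxa whose pairwise adjusted p >= alpha
merge_taxon_groups <- function(taxa, pairwise, alpha = 0.05) {
  parent <- setNames(seq_along(taxa), taxa)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  keep <- pairwise$adj_p_value >= alpha
  for (k in which(keep)) {
    ri <- find_root(match(pairwise$taxon_1[k], taxa))
    rj <- find_root(match(pairwise$taxon_2[k], taxa))
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_along(taxa), find_root, integer(1))
  labels <- match(roots, unique(roots))
  tibble(taxon_group = taxa, group = paste0("group", labels))
}

#' ANCOVA of transcripts on carbon with a taxonomy term
#'
#' Fits the common-slope model
#' `log10 T = mu + beta * log10 C + taxon + error` and tests whether
#' carbon concentration predicts transcript concentration and whether
#' taxonomy shifts transcripts per unit carbon, via partial F-tests.
#' Pairwise Tukey honest-significant-difference comparisons of the
#' carbon-adjusted taxon means then partition the taxa: pairs whose
#' adjusted p-value is at least `alpha` are merged into one group.
#'
#' @param points Matched point tibble (columns `taxon_group`,
#'   `log10_carbon`, `log10_transcripts`). Rows labelled `"other"` are
#'   excluded.
#' @param pool Optional pool filter.
#' @param alpha Significance level for the pairwise partition.
#' @param pairwise If `FALSE`, skip the Tukey comparisons (useful for
#'   simulation studies of the F-tests alone).
#' @return An object of class `ancova_result`: list with `p_carbon`,
#'   `p_taxon`, `pairwise` (tibble of taxon pairs with Tukey-adjusted
#'   p-values, or `NULL`), `groups` (tibble mapping each taxon to a
#'   group label, or `NULL`) and `model` (the `lm` fit).
#' @export
ancova_taxa <- function(points, pool = NULL, alpha = 0.05, pairwise = TRUE) {
  check_columns(points, c("taxon_group", "log10_carbon", "log10_transcripts"),
                "points")
  if (!is.null(pool) && "pool" %in% names(points)) {
    points <- points |> filter(.data$pool == !!pool)
  }
  points <- points |> filter(.data$taxon_group != "other")
  tab <- table(points$taxon_group)
  if (length(tab) < 2) {
    abort("ANCOVA needs at least 2 taxon groups",
          class = "dinofactor_fit_error")
  }
  if (any(tab < 3)) {
    abort(sprintf("ANCOVA needs >= 3 points per taxon; too few for: %s",
                  paste(names(tab)[tab < 3], collapse = ", ")),
          class = "dinofactor_fit_error")
  }
  points$taxon_group <- factor(points$taxon_group)

  fit <- lm(log10_transcripts ~ log10_carbon + taxon_group, data = points)
  dr <- drop1(fit, test = "F")
  p_carbon <- dr["log10_carbon", "Pr(>F)"]
  p_taxon <- dr["taxon_group", "Pr(>F)"]

  pw <- groups <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, "taxon_group")
    cmp <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                                 adjust = "tukey"))
    parts <- strsplit(as.character(cmp$contrast), " - ", fixed = TRUE)
    pw <- tibble(
      taxon_1 = vapply(parts, `[`, "", 1),
      taxon_2 = vapply(parts, `[`, "", 2),
      estimate = cmp$estimate,
      adj_p_value = cmp$p.value
    )
    groups <- merge_taxon_groups(levels(points$taxon_group), pw, alpha)
  }

  structure(
    list(p_carbon = p_carbon, p_taxon = p_taxon,
         pairwise = pw, groups = groups, model = fit),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: log10 T ~ log10 C + taxon (common slope)\n  p(carbon) = %.3g   p(taxon) = %.3g\n",
              x$p_carbon, x$p_taxon))
  if (!is.null(x$groups)) {
    cat("Tukey partition:\n")
    print(x$groups)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ancova_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble(term = c("log10_carbon", "taxon_group"),
           p.value = c(x$p_carbon, x$p_taxon))
  } else {
    x$pairwise
  }
}

#' Dinoflagellate transcript-per-carbon scaling factor
#'
#' The Dino-factor is the fold elevation of dinoflagellate transcripts
#' per unit carbon relative to the pooled other taxa, estimated as the
#' ratio of the two power-law intercepts, i.e. the ratio of predicted
#' transcript concentrations at `C = 1` ug C L^-1. Its standard error
#' combines the two relative intercept SEs in quadrature:
#' `se = estimate * sqrt((se_a_dino / a_dino)^2 + (se_a_other / a_other)^2)`.
#' When either fit used only two points its SE is unavailable and the
#' factor's SE is reported as `NA`.
#'
#' @param fit_dino [power_law_fit()] for the Dinoflagellate group.
#' @param fit_other [power_law_fit()] for the pooled non-Dinoflagellate
#'   group, on the same pool and cruise.
#' @return An object of class `scaling_factor`: list with `estimate`
#'   (fold), `se`, `method = "intercept_ratio"`, `pool`, `cruise`.
#' @export
#' @examples
#' d <- power_law_fit(42.82, 0.98, se_a = 3.18, n_points = 10)
#' o <- power_law_fit(6.64, 0.90, se_a = 0.70, n_points = 40)
#' dino_factor(d, o)
dino_factor <- function(fit_dino, fit_other) {
  stopifnot(inherits(fit_dino, "power_law_fit"),
            inherits(fit_other, "power_law_fit"))
  if (!is.na(fit_dino$pool) && !is.na(fit_other$pool) &&
      fit_dino$pool != fit_other$pool) {
    abort("fits are for different mRNA pools")
  }
  if (fit_dino$intercept_a <= 0 || fit_other$intercept_a <= 0) {
    abort("intercepts must be > 0")
  }
  estimate <- fit_dino$intercept_a / fit_other$intercept_a
  n2 <- (!is.na(fit_dino$n_points) && fit_dino$n_points <= 2) ||
    (!is.na(fit_other$n_points) && fit_other$n_points <= 2)
  se <- if (n2 || is.na(fit_dino$se_a) || is.na(fit_other$se_a)) {
    NA_real_
  } else {
    estimate * sqrt((fit_dino$se_a / fit_dino$intercept_a)^2 +
                      (fit_other$se_a / fit_other$intercept_a)^2)
  }
  structure(
    list(estimate = estimate, se = se, method = "intercept_ratio",
         pool = fit_dino$pool %||% NA_character_,
         cruise = fit_dino$cruise %||% NA_character_),
    class = "scaling_factor"
  )
}

#' Dino-factor from the ANCOVA common-slope taxonomy offset
#'
#' Alternative estimator of the Dinoflagellate scaling factor: fit the
#' common-slope model `log10 T = mu + beta * log10 C + dino + error`,
#' where `dino` indicates Dinoflagellata versus all other canonical
#' taxa pooled; the factor is `10^offset` with delta-method SE
#' `ln(10) * estimate * se_offset`. Unlike the intercept ratio it
#' constrains both groups to one slope, so the two estimators differ
#' when the group slopes differ.
#'
#' @param points Matched point tibble.
#' @param pool Optional pool filter.
#' @param cruise Label stored on the result.
#' @return A `scaling_factor` object with `method = "common_slope_offset"`.
#' @export
dino_factor_offset <- function(points, pool = NULL, cruise = NA_character_) {
  check_columns(points, c("taxon_group", "log10_carbon", "log10_transcripts"),
                "points")
  if (!is.null(pool) && "pool" %in% names(points)) {
    points <- points |> filter(.data$pool == !!pool)
  }
  points <- points |>
    filter(.data$taxon_group %in% taxon_levels()) |>
    mutate(dino = .data$taxon_group == "Dinoflagellata")
  if (sum(points$dino) < 2 || sum(!points$dino) < 2) {
    abort("need >= 2 points in each of the dino and non-dino groups",
          class = "dinofactor_fit_error")
  }
  fit <- lm(log10_transcripts ~ log10_carbon + dino, data = points)
  sm <- summary(fit)$coefficients
  offset <- sm["dinoTRUE", "Estimate"]
  se_off <- sm["dinoTRUE", "Std. Error"]
  estimate <- 10^offset
  structure(
    list(estimate = estimate, se = log(10) * estimate * se_off,
         method = "common_slope_offset",
         pool = pool %||% NA_character_, cruise = cruise),
    class = "scaling_factor"
  )
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("Dino-factor = %.3f (SE %.3f)  [method: %s, pool: %s]\n",
              x$estimate, x$se, x$method, x$pool))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scaling_factor <- function(x, ...) {
  tibble(estimate = x$estimate, std.error = x$se, method = x$method,
         pool = x$pool, cruise = x$cruise)
}

#' Assemble the calibration report table
#'
#' Lays out per-group power-law fits and Dino-factors in the standard
#' report shape: one row per cruise x pool x group with intercept,
#' slope, their SEs, N, R^2, and the Dino-factor attached to the
#' Dinoflagellate row of each cruise x pool.
#'
#' @param fits List of [power_law_fit()] objects.
#' @param factors List of `scaling_factor` objects (may be empty).
#' @return Report tibble with columns `cruise`, `pool`, `group`,
#'   `intercept_a`, `intercept_se`, `slope_b`, `slope_se`, `n`,
#'   `r_squared`, `dino_factor`, `dino_factor_se`.
#' @export
build_table1 <- function(fits, factors = list()) {
  rows <- map_dfr(fits, function(f) {
    tibble(cruise = f$cruise, pool = f$pool, group = f$group,
           intercept_a = f$intercept_a, intercept_se = f$se_a,
           slope_b = f$slope_b, slope_se = f$se_b,
           n = f$n_points, r_squared = f$r_squared)
  })
  rows$dino_factor <- NA_real_
  rows$dino_factor_se <- NA_real_
  for (fc in factors) {
    i <- which(rows$group == "Dinoflagellate" &
                 (is.na(fc$pool) | rows$pool == fc$pool) &
                 (is.na(fc$cruise) | rows$cruise == fc$cruise))
    rows$dino_factor[i] <- fc$estimate
    rows$dino_factor_se[i] <- fc$se
  }
  rows |> arrange(.data$cruise, .data$pool, .data$group != "Dinoflagellate")
}

#' Run the full calibration on matched points
#'
#' For each requested mRNA pool: fits the Dinoflagellate and pooled
#' non-Dinoflagellate power laws, estimates the Dino-factor, compares
#' model families by AIC on the all-taxa points, and runs the taxonomy
#' ANCOVA. Convenience wrapper producing a `calibration` object.
#'
#' @param points Matched point tibble from [match_samples()].
#' @param pools Character vector of pools to calibrate (defaults to the
#'   pools present in `points`).
#' @param cruise Run label.
#' @param factor_method `"intercept_ratio"` (default) or
#'   `"common_slope_offset"`.
#' @return An object of class `calibration`: list with `fits`,
#'   `factors`, `model_comparison`, `ancova`, `table` (the report from
#'   [build_table1()]) and `points`.
#' @export
calibrate <- function(points, pools = NULL, cruise = "synthetic",
                      factor_method = c("intercept_ratio",
                                        "common_slope_offset")) {
  factor_method <- match.arg(factor_method)
  if (!"pool" %in% names(points)) points$pool <- "total"
  pools <- pools %||% sort(unique(points$pool))

  fits <- list()
  factors <- list()
  comparisons <- list()
  ancovas <- list()
  for (p in pools) {
    fd <- fit_loglog(points, group = "Dinoflagellate", pool = p,
                     cruise = cruise)
    fo <- fit_loglog(points, group = "non-Dinoflagellate", pool = p,
                     cruise = cruise)
    fits[[paste(p, "Dinoflagellate", sep = ".")]] <- fd
    fits[[paste(p, "non-Dinoflagellate", sep = ".")]] <- fo
    factors[[p]] <- if (factor_method == "intercept_ratio") {
      dino_factor(fd, fo)
    } else {
      dino_factor_offset(points, pool = p, cruise = cruise)
    }
    comparisons[[p]] <- compare_models(points, pool = p)
    ancovas[[p]] <- tryCatch(
      ancova_taxa(points, pool = p),
      dinofactor_fit_error = function(e) NULL
    )
  }
  structure(
    list(fits = fits, factors = factors, model_comparison = comparisons,
         ancova = ancovas, table = build_table1(fits, factors),
         points = points, cruise = cruise),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Transcript-to-carbon calibration [%s]\n", x$cruise))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.calibration <- function(x, ...) {
  map_dfr(names(x$factors), function(p) {
    tibble(pool = p,
           dino_factor = x$factors[[p]]$estimate,
           dino_factor_se = x$factors[[p]]$se,
           best_model = x$model_comparison[[p]]$best_model,
           p_carbon = x$ancova[[p]]$p_carbon %||% NA_real_,
           p_taxon = x$ancova[[p]]$p_taxon %||% NA_real_)
  })
}
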