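test_that("noiseless power-law data is fit exactly", {
  pts <- power_law_points(a = 2, b = 1, log10_c = seq(-1, 1, 0.25))
  fit <- suppressWarnings(fit_loglog(pts, group = "Dinoflagellate"))
  expect_equal(fit$intercept_a, 2, tolerance = 1e-12)
  expect_equal(fit$slope_b, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("three-point fit matches the hand-worked OLS solution", {
  # (0, 0.1), (1, 0.9), (2, 2.0): Sxx = 2, Sxy = 1.9 -> slope 0.95,
  # intercept 1.0 - 0.95 * 1 = 0.05
  pts <- tibble::tibble(
    taxon_group = "Dinoflagellata", pool = "total",
    log10_carbon = c(0, 1, 2), log10_transcripts = c(0.1, 0.9, 2.0)
  )
  fit <- fit_loglog(pts, group = "Dinoflagellate")
  expect_equal(fit$slope_b, 0.95, tolerance = 1e-12)
  expect_equal(log10(fit$intercept_a), 0.05, tolerance = 1e-12)
})

test_that("fit coefficients equal the closed-form normal equations", {
  withr::with_seed(31, {
    for (n in c(5, 20, 100)) {
      x <- runif(n, -1.5, 1.5)
      y <- 0.7 + 0.9 * x + rnorm(n, 0, 0.3)
      pts <- tibble::tibble(taxon_group = "Ciliophora",
                            log10_carbon = x, log10_transcripts = y)
      fit <- fit_loglog(pts, group = "Ciliophora")
      # independent oracle: normal equations solved directly
      slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      intercept <- mean(y) - slope * mean(x)
      expect_equal(fit$slope_b, slope, tolerance = 1e-10)
      expect_equal(log10(fit$intercept_a), intercept, tolerance = 1e-10)
    }
  })
})

test_that("degenerate fits error and two-point fits suppress SEs", {
  pts <- power_law_points(2, 1, c(0, 1))
  expect_error(fit_loglog(pts[1, ], "Dinoflagellate"),
               class = "dinofactor_fit_error")
  same_x <- power_law_points(2, 1, c(0.5, 0.5, 0.5))
  expect_error(fit_loglog(same_x, "Dinoflagellate"), "zero variance",
               class = "dinofactor_fit_error")
  two <- fit_loglog(pts, "Dinoflagellate")
  expect_equal(two$n_points, 2L)
  expect_true(is.na(two$se_a) && is.na(two$se_b))
})

test_that("intercept SE propagation follows the delta method", {
  withr::with_seed(8, {
    pts <- power_law_points(3, 1, seq(-1, 1, length.out = 12)) |>
      dplyr::mutate(log10_transcripts = log10_transcripts + rnorm(12, 0, 0.2))
    fit <- fit_loglog(pts, "Dinoflagellate")
    lmfit <- summary(lm(log10_transcripts ~ log10_carbon, data = pts))
    expect_equal(fit$se_a,
                 log(10) * 10^coef(lmfit)[1, 1] * coef(lmfit)[1, 2],
                 tolerance = 1e-12)
    expect_equal(fit$se_b, coef(lmfit)[2, 2], tolerance = 1e-12)
  })
})

test_that("AIC selects the generating model family", {
  # lognormal multiplicative noise around a power law -> log-log wins
  withr::with_seed(3, {
    lc <- runif(50, -1.5, 1)
    pts <- tibble::tibble(carbon = 10^lc,
                          transcripts = 5 * (10^lc)^1 * 10^rnorm(50, 0, 0.25))
    cmp <- compare_models(pts)
    expect_equal(cmp$best_model, "loglog")
    expect_equal(cmp$table$model[which.min(cmp$table$aic)], cmp$best_model)
  })
  # additive Gaussian noise around a straight line with a nonzero
  # offset and sub-unit response magnitudes -> linear wins
  withr::with_seed(4, {
    carbon <- runif(50, 0.2, 5)
    pts <- tibble::tibble(carbon = carbon,
                          transcripts = 0.05 + 0.1 * carbon +
                            rnorm(50, 0, 0.02))
    cmp <- suppressWarnings(compare_models(pts))
    expect_equal(cmp$best_model, "linear")
  })
  expect_error(compare_models(tibble::tibble(carbon = 1:3,
                                             transcripts = 1:3)),
               class = "dinofactor_fit_error")
})

test_that("AIC comparison is invariant to row order", {
  withr::with_seed(9, {
    lc <- runif(30, -1, 1)
    pts <- tibble::tibble(carbon = 10^lc,
                          transcripts = 4 * (10^lc) * 10^rnorm(30, 0, 0.2))
    a <- compare_models(pts)
    b <- compare_models(pts[sample(30), ])
    expect_equal(a$table$aic, b$table$aic, tolerance = 1e-8)
  })
})

test_that("ANCOVA detects taxonomy offsets and groups equivalent taxa", {
  # two taxa, 0.8 dex offset: taxonomy significant, pair separated
  withr::with_seed(11, {
    lc <- runif(20, -1, 1)
    pts <- tibble::tibble(
      taxon_group = rep(c("Dinoflagellata", "Haptophyta"), each = 10),
      log10_carbon = lc,
      log10_transcripts = lc + rep(c(0.8, 0), each = 10) + rnorm(20, 0, 0.2)
    )
    res <- ancova_taxa(pts)
    expect_lt(res$p_taxon, 0.001)
    expect_lt(res$p_carbon, 0.001)
    expect_equal(dplyr::n_distinct(res$groups$group), 2)
  })

  # five taxa, no offsets: all merged into one group (typical seeded run)
  withr::with_seed(12, {
    lc <- runif(50, -1, 1)
    pts <- tibble::tibble(
      taxon_group = rep(taxon_levels(), each = 10),
      log10_carbon = lc,
      log10_transcripts = lc + rnorm(50, 0, 0.2)
    )
    res <- ancova_taxa(pts)
    expect_equal(dplyr::n_distinct(res$groups$group), 1)
    expect_setequal(res$groups$taxon_group, taxon_levels())
  })

  # identical points under two labels: adjusted means equal, p = 1
  pts <- power_law_points(2, 1, seq(-1, 1, 0.5)) |>
    dplyr::mutate(log10_transcripts = log10_transcripts +
                    c(0.1, -0.1, 0.05, -0.05, 0))
  twin <- dplyr::bind_rows(pts,
                           dplyr::mutate(pts, taxon_group = "Haptophyta"))
  res <- ancova_taxa(twin)
  expect_gt(res$pairwise$adj_p_value, 0.999)
  expect_equal(res$pairwise$estimate, 0, tolerance = 1e-12)

  expect_error(ancova_taxa(pts), class = "dinofactor_fit_error")
})

test_that("the Dino-factor is the intercept ratio with quadrature SE", {
  # identical fits: factor 1 with sqrt(2) * relative SE
  f <- power_law_fit(10, 1, se_a = 1, n_points = 10)
  sym <- dino_factor(f, f)
  expect_equal(sym$estimate, 1.0)
  expect_equal(sym$se, sqrt(2) * 0.1)

  # SE suppressed when either fit has n = 2
  f2 <- power_law_fit(10, 1, se_a = NA_real_, n_points = 2)
  expect_true(is.na(dino_factor(f2, f)$se))

  # pools must agree
  fa <- power_law_fit(10, 1, pool = "total")
  fb <- power_law_fit(5, 1, pool = "functional")
  expect_error(dino_factor(fa, fb), "pool")
})

test_that("the common-slope offset method recovers a noiseless factor", {
  pts <- dplyr::bind_rows(
    power_law_points(16, 1, seq(-0.5, 1, length.out = 10)),
    power_law_points(2.5, 1, seq(-1, 0.5, length.out = 10),
                     taxon_group = "Haptophyta"),
    power_law_points(2.5, 1, seq(-1, 0.5, length.out = 10),
                     taxon_group = "Ciliophora")
  )
  sf <- suppressWarnings(dino_factor_offset(pts))
  expect_equal(sf$estimate, 16 / 2.5, tolerance = 1e-10)
  expect_equal(sf$method, "common_slope_offset")
})

test_that("calibration is scale invariant", {
  withr::with_seed(14, {
    lc <- runif(10, -1, 1)
    pts <- dplyr::bind_rows(
      power_law_points(16, 1, lc),
      power_law_points(2.5, 0.95, runif(20, -1.5, 0.5),
                       taxon_group = "Bacillariophyta")
    ) |>
      dplyr::mutate(log10_transcripts = log10_transcripts +
                      rnorm(dplyr::n(), 0, 0.15),
                    transcripts = 10^log10_transcripts)
    base_d <- fit_loglog(pts, "Dinoflagellate")
    base_o <- fit_loglog(pts, "non-Dinoflagellate")
    base_f <- dino_factor(base_d, base_o)

    k <- 7.3
    scaled <- pts |>
      dplyr::mutate(transcripts = transcripts * k,
                    log10_transcripts = log10(transcripts))
    sc_d <- fit_loglog(scaled, "Dinoflagellate")
    sc_o <- fit_loglog(scaled, "non-Dinoflagellate")
    expect_equal(sc_d$intercept_a, base_d$intercept_a * k, tolerance = 1e-9)
    expect_equal(sc_d$slope_b, base_d$slope_b, tolerance = 1e-9)
    expect_equal(sc_d$r_squared, base_d$r_squared, tolerance = 1e-9)
    expect_equal(dino_factor(sc_d, sc_o)$estimate, base_f$estimate,
                 tolerance = 1e-9)

    # rescaling carbon identically in both groups, with equal slopes,
    # leaves the intercept-ratio factor unchanged
    eq <- dplyr::bind_rows(
      power_law_points(16, 1, lc),
      power_law_points(2.5, 1, lc, taxon_group = "Bacillariophyta")
    )
    shifted <- eq |>
      dplyr::mutate(carbon = carbon * k, log10_carbon = log10(carbon))
    f_eq <- suppressWarnings(
      dino_factor(fit_loglog(eq, "Dinoflagellate"),
                  fit_loglog(eq, "non-Dinoflagellate")))
    f_sh <- suppressWarnings(
      dino_factor(fit_loglog(shifted, "Dinoflagellate"),
                  fit_loglog(shifted, "non-Dinoflagellate")))
    expect_equal(f_sh$estimate, f_eq$estimate, tolerance = 1e-9)
  })
})

test_that("the report table mirrors the standard layout", {
  pts <- dplyr::bind_rows(
    power_law_points(16, 1, seq(-0.5, 1, length.out = 10)),
    power_law_points(2.5, 1, seq(-1, 0.5, length.out = 10),
                     taxon_group = "Bacillariophyta"),
    power_law_points(2.5, 1, seq(-1, 0.5, length.out = 10),
                     taxon_group = "Ciliophora")
  )
  cal <- suppressWarnings(calibrate(pts, cruise = "demo"))
  expect_s3_class(cal$table, "tbl_df")
  expect_equal(nrow(cal$table), 2)  # one pool: dino + non-dino rows
  expect_equal(cal$table$group[1], "Dinoflagellate")
  expect_equal(cal$table$n[cal$table$group == "non-Dinoflagellate"], 20L)
  expect_equal(cal$table$dino_factor[1], 16 / 2.5, tolerance = 1e-9)
  expect_true(is.na(cal$table$dino_factor[2]))

  # n = 2 fits appear with suppressed SEs
  f2 <- fit_loglog(power_law_points(7, 1, c(0, 1)), "Dinoflagellate",
                   cruise = "tiny")
  tab <- build_table1(list(f2), list(dino_factor(f2, f2)))
  expect_true(is.na(tab$intercept_se) && is.na(tab$dino_factor_se))
  expect_equal(tab$n, 2L)

  # tidiers expose the same numbers
  expect_equal(tidy(cal)$intercept_a, cal$table$intercept_a)
  expect_equal(glance(cal)$dino_factor[1], 16 / 2.5, tolerance = 1e-9)
})
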