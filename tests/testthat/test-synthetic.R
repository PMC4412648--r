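test_that("land-cover generation honours class quotas", {
  # single class at proportion 1 -> uniform map
  cfg1 <- synthetic_config(seed = 1, n_rows = 10L, n_cols = 10L,
                           coarse_factor = 5L,
                           class_proportions = c(Savanna = 1))
  expect_true(all(generate_landcover(cfg1)$classes == "Savanna"))

  # 50/50 on a 10x10 grid -> exactly 50 cells each, with and without speckle
  cfg2 <- synthetic_config(seed = 2, n_rows = 10L, n_cols = 10L,
                           coarse_factor = 5L,
                           class_proportions = c(EBF = 0.5, Grass = 0.5))
  tab <- table(generate_landcover(cfg2)$classes)
  expect_equal(unname(tab[["EBF"]]), 50)
  expect_equal(unname(tab[["Grass"]]), 50)

  # default configuration: area ranking follows the study-area listing
  cfg <- tiny_config()
  tab3 <- table(generate_landcover(cfg)$classes)
  veg <- c("Savanna", "WSavanna", "OShrub", "EBF", "Grass", "Crop", "CShrub")
  counts <- as.numeric(tab3[veg])
  expect_true(all(diff(counts) < 0))   # strictly decreasing areas
  # every class within one cell of its quota
  n <- cfg$n_rows * cfg$n_cols
  for (cl in names(cfg$class_proportions)) {
    expect_lte(abs(sum(tab3[cl], na.rm = TRUE) - cfg$class_proportions[[cl]] * n), 1)
  }
  expect_error(synthetic_config(seed = 1, class_proportions = c(EBF = 0.7)),
               "sum to 1")
})

test_that("meteorology is seeded, bounded and analytic at zero noise", {
  cfg <- tiny_config(seed = 31)
  m1 <- generate_meteo(cfg, 2000L)
  m2 <- generate_meteo(cfg, 2000L)
  expect_identical(m1, m2)              # same seed -> identical stacks
  expect_false(identical(m1$sw_rad, generate_meteo(cfg, 2001L)$sw_rad))

  # noise 0: day-365 values equal the stated closed forms
  cfg0 <- tiny_config(seed = 31, noise_sd = 0)
  m0 <- generate_meteo(cfg0, 2000L)
  expect_equal(m0$sw_rad[365, 1, 1], 20 + 4 * sin(2 * pi * (365 - 80) / 365),
               tolerance = 1e-12)
  expect_equal(m0$tavg[365, 1, 1], 24 + 4 * sin(2 * pi * (365 - 20) / 365),
               tolerance = 1e-12)
  # VPD anti-correlated with the precipitation gradient: dry north > wet south
  expect_gt(mean(m0$vpd[, 1, 1]), mean(m0$vpd[, 40, 1]))

  # bounds across seeds
  for (s in 1:10) {
    m <- generate_meteo(synthetic_config(seed = s, n_rows = 10L, n_cols = 10L,
                                         coarse_factor = 5L), 2000L)
    expect_true(all(m$sw_rad >= 0))
    expect_true(all(m$vpd >= 0))
  }
})

test_that("FAPAR stacks respect bounds and the configured fill rates", {
  cfg <- tiny_config(seed = 41)
  lc <- generate_landcover(cfg)

  # fill rate 0 everywhere -> no flags
  rates0 <- cfg$cloud_fill_rate_by_class; rates0[] <- 0
  cfg0 <- tiny_config(seed = 41, cloud_fill_rate_by_class = rates0)
  expect_false(any(generate_fapar(cfg0, lc, 2000L)$filled))

  # EBF flagged-day count close to 0.65 * 365 per cell on average
  fap <- generate_fapar(cfg, lc, 2000L)
  ebf_cells <- which(lc$classes == "EBF")
  flags_per_cell <- apply(fap$filled, c(2, 3), sum)
  mean_flags <- mean(flags_per_cell[ebf_cells])
  n_ebf <- length(ebf_cells)
  tol <- 3 * sqrt(0.65 * 0.35 * 365 / n_ebf)   # 3 SE of the binomial mean
  expect_lt(abs(mean_flags - 0.65 * 365), tol)

  # bounds across seeds
  for (s in 1:10) {
    cfg_s <- synthetic_config(seed = s, n_rows = 10L, n_cols = 10L,
                              coarse_factor = 5L)
    lc_s <- generate_landcover(cfg_s)
    f <- generate_fapar(cfg_s, lc_s, 2000L)
    expect_true(all(f$fapar >= 0 & f$fapar <= 1))
  }
})

test_that("DVM products carry the prescribed per-class CUE", {
  # zero noise, one class: every coarse cell has NPP/GPP = 0.58
  cfg <- synthetic_config(seed = 51, n_rows = 20L, n_cols = 20L,
                          coarse_factor = 10L, years = 2000:2001,
                          class_proportions = c(Savanna = 1),
                          dvm_cue_by_class = c(Savanna = 0.58),
                          noise_sd = 0)
  lc <- generate_landcover(cfg)
  dvm <- generate_dvm_product(cfg, lc)
  for (y in names(dvm$gpp)) {
    expect_equal(dvm$npp[[y]]$values / dvm$gpp[[y]]$values,
                 matrix(0.58, 2, 2), tolerance = 1e-12)
  }
  # mean_cue recovers the prescription exactly at zero noise
  cue <- mean_cue(dvm$gpp, dvm$npp)
  expect_equal(unique(as.vector(cue$values)), 0.58, tolerance = 1e-12)

  # determinism
  dvm2 <- generate_dvm_product(cfg, lc)
  expect_identical(dvm$gpp[[1]]$values, dvm2$gpp[[1]]$values)
})

test_that("sites follow the gradient, the truth field and the 50% rule", {
  cfg <- tiny_config(seed = 61, noise_sd = 0, aboveground_fraction = 1,
                     sites_as_carbon = TRUE)
  lc <- generate_landcover(cfg)
  # truth: any valid field; use a DVM NPP year resampled to fine
  dvm <- generate_dvm_product(cfg, lc)
  truth <- resample_nearest(dvm$npp[[1]], lc$grid)
  truth <- harmonize_masks(truth, truth, lc)$a   # mask out Barren/Water/Urban
  sites <- generate_sites(cfg, truth)
  expect_equal(nrow(sites), 35)

  # extraction excludes exactly the masked-cell sites
  ext <- extract_at_sites(list(`2000` = truth, `2001` = truth), sites,
                          mode = "period_mean")
  expect_equal(nrow(ext$pairs), 31)
  expect_equal(nrow(ext$excluded), 4)

  # noise 0, aboveground fraction 1, carbon units: perfect recovery
  v <- validate_stats(ext$pairs$observed_gC, ext$pairs$predicted_gC)
  expect_equal(v$r, 1, tolerance = 1e-12)
  expect_equal(v$rmse, 0, tolerance = 1e-9)

  # biomass-stored twins equal carbon-stored sites after conversion
  cfg_b <- tiny_config(seed = 61, noise_sd = 0, aboveground_fraction = 1,
                       sites_as_carbon = FALSE)
  sites_b <- generate_sites(cfg_b, truth)
  expect_equal(biomass_to_carbon(sites_b$anpp, sites_b$is_carbon),
               biomass_to_carbon(sites$anpp, sites$is_carbon),
               tolerance = 1e-12)
})

test_that("rg_frac calibration hits the requested domain CUE", {
  cfg <- tiny_config(seed = 71)
  lc <- generate_landcover(cfg)
  comps <- list()
  for (y in as.character(cfg$years)) {
    met <- generate_meteo(cfg, as.integer(y))
    fap <- generate_fapar(cfg, lc, as.integer(y))
    comps[[y]] <- lue_annual(met, fap, lc)
  }
  tuned <- tune_rg_frac(comps, target = 0.46)
  expect_lt(abs(tuned$cue - 0.46), 0.005)
  expect_true(tuned$rg_frac > 0 && tuned$rg_frac < 0.999)
  # unattainable target falls back to an endpoint with a warning
  expect_warning(res <- tune_rg_frac(comps, target = 0.999), "attainable")
  expect_equal(res$rg_frac, 0)
})
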