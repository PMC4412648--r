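test_that("temperature and VPD ramps clamp and interpolate linearly", {
  p <- simple_params(tmin_min = -8, tmin_max = 8, vpd_min = 650, vpd_max = 2500)
  expect_equal(tmin_scalar(p$tmin_max + 5, p), 1)
  expect_equal(tmin_scalar(p$tmin_min - 5, p), 0)
  expect_equal(tmin_scalar(0, p), 0.5)           # midpoint of (-8, 8)
  expect_equal(vpd_scalar(0, p), 1)
  expect_equal(vpd_scalar(p$vpd_max, p), 0)
  expect_equal(vpd_scalar((650 + 2500) / 2, p), 0.5)
  # vectorized and bounded
  x <- seq(-20, 20, by = 0.5)
  expect_true(all(tmin_scalar(x, p) >= 0 & tmin_scalar(x, p) <= 1))
})

test_that("daily GPP follows the LUE equation and its monotonicities", {
  p <- simple_params(eps_max = 1)
  m <- list(sw_rad = 20, tmin = 20, vpd = 0)
  expect_equal(daily_gpp(m, list(fapar = 0.5), p), 1 * 0.45 * 20 * 0.5)
  expect_equal(daily_gpp(m, list(fapar = 0), p), 0)
  expect_equal(daily_gpp(list(sw_rad = 20, tmin = -20, vpd = 0),
                         list(fapar = 0.5), p), 0)
  # homogeneous of degree 1 in eps_max
  p2 <- simple_params(eps_max = 2.5)
  expect_equal(daily_gpp(m, list(fapar = 0.5), p2),
               2.5 * daily_gpp(m, list(fapar = 0.5), p))
  # monotone non-decreasing in radiation and fapar
  set.seed(5)
  for (i in 1:20) {
    sw <- runif(1, 0, 30); fp <- runif(1, 0, 1)
    base <- daily_gpp(list(sw_rad = sw, tmin = 20, vpd = 1000),
                      list(fapar = fp), p)
    expect_gte(daily_gpp(list(sw_rad = sw + 1, tmin = 20, vpd = 1000),
                         list(fapar = fp), p), base)
    expect_gte(daily_gpp(list(sw_rad = sw, tmin = 20, vpd = 1000),
                         list(fapar = min(1, fp + 0.05)), p), base)
  }
})

test_that("maintenance respiration scales with canopy mass and Q10", {
  p <- simple_params(sla = 10, leaf_mr_base = 0.001, froot_mr_base = 0.001,
                     froot_leaf_ratio = 1, q10 = 2)
  # no canopy, no respiration
  r0 <- maintenance_respiration_daily(list(fapar = 0), list(tavg = 25), p)
  expect_equal(r0$r_ml, 0); expect_equal(r0$r_mr, 0)
  # leaf carbon 100 g C m-2 at 20 C: LAI = 1 at fapar = 1 - exp(-0.5)
  fp <- 1 - exp(-0.5)
  r <- maintenance_respiration_daily(list(fapar = fp), list(tavg = 20), p)
  expect_equal(r$r_ml, 100 * 0.001, tolerance = 1e-12)
  # Q10 definition: +10 C multiplies respiration by q10
  r30 <- maintenance_respiration_daily(list(fapar = fp), list(tavg = 30), p)
  expect_equal(r30$r_ml / r$r_ml, 2)
  expect_equal(r30$r_mr / r$r_mr, 2)
})

test_that("PsnNet and annual NPP follow the accounting identities", {
  expect_equal(psn_net(4.5, 0, 0), 4.5)
  expect_equal(psn_net(4.5, 0.3, 0.2), 4.0)
  expect_equal(psn_net(0, 0.1, 0), -0.1)    # negative allowed at daily step

  expect_equal(annual_npp(rep(0, 365), 0, 0)$npp, 0)
  a <- annual_npp(rep(1, 365), 50, 40)
  expect_equal(a$npp, 275)
  expect_equal(a$psnnet_sum, 365)
  clamped <- annual_npp(c(10, rep(0, 364)), 15, 5)
  expect_equal(clamped$npp, 0)
  expect_equal(clamped$npp_unclamped, -10)
  expect_error(annual_npp(rep(1, 100), 0, 0), "365 or 366")
  expect_silent(annual_npp(rep(1, 366), 0, 0))
})

test_that("growing season counts days above -8 C", {
  expect_equal(growing_season(rep(15, 365))$totalg, 365)
  expect_equal(growing_season(rep(-20, 365))$totalg, 0)
  s <- growing_season(c(rep(-10, 100), rep(15, 265)))
  expect_equal(s$totalg, 265)
  expect_identical(s$mask, c(rep(FALSE, 100), rep(TRUE, 265)))
})

test_that("QC is the percentage of gap-filled growing-season days", {
  season <- rep(TRUE, 365)
  expect_equal(qc_percent(rep(FALSE, 365), season), 0)
  expect_equal(qc_percent(rep(TRUE, 365), season), 100)
  expect_equal(qc_percent(c(rep(TRUE, 73), rep(FALSE, 292)), season), 20)
  expect_true(is.na(qc_percent(rep(TRUE, 365), rep(FALSE, 365))))
  expect_error(qc_percent(rep(TRUE, 10), rep(TRUE, 11)), "length")
  # independent counting oracle over 1000 seeded random series
  set.seed(11)
  for (i in 1:1000) {
    flags <- runif(365) < 0.3
    season <- runif(365) < 0.9
    if (!any(season)) next
    nug <- 0
    for (d in 1:365) if (flags[d] && season[d]) nug <- nug + 1
    expect_equal(qc_percent(flags, season), 100 * nug / sum(season),
                 tolerance = 1e-12)
  }
})

test_that("gridded annual accumulation matches a per-cell day-loop oracle", {
  cfg <- synthetic_config(seed = 3, n_rows = 5L, n_cols = 5L,
                          coarse_factor = 5L, years = 2000L, noise_sd = 0.05)
  lc <- landcover_map(fine_grid <- grid_spec(5, 5, cell_size = 1000),
                      matrix(c(rep("EBF", 10), rep("Savanna", 15)), 5, 5))
  met <- generate_meteo(cfg, 2000L)
  fap <- generate_fapar(cfg, lc, 2000L)
  bp <- default_bplut()
  res <- lue_annual(met, fap, lc, bp)
  # independent oracle: direct formula evaluation, day by day, cell by cell
  for (i in 1:5) for (j in 1:5) {
    p <- bp[bp$class == lc$classes[i, j], ]
    gpp <- 0
    for (d in 1:365) {
      ft <- min(1, max(0, (met$tmin[d, i, j] - p$tmin_min) / (p$tmin_max - p$tmin_min)))
      fv <- min(1, max(0, (p$vpd_max - met$vpd[d, i, j]) / (p$vpd_max - p$vpd_min)))
      gpp <- gpp + p$eps_max * 0.45 * met$sw_rad[d, i, j] * fap$fapar[d, i, j] * fv * ft
    }
    expect_equal(res$gpp$values[i, j], gpp / 1000, tolerance = 1e-12)
  }
})

test_that("annual products respect npp <= psnnet_sum <= gpp and npp >= 0", {
  cfg <- tiny_config(seed = 9)
  lc <- generate_landcover(cfg)
  met <- generate_meteo(cfg, 2000L)
  fap <- generate_fapar(cfg, lc, 2000L)
  res <- lue_annual(met, fap, lc)
  ok <- res$npp$valid_mask
  expect_true(all(res$npp$values[ok] >= 0))
  # the unclamped balance respects NPP <= sum(PsnNet) <= GPP; the reported
  # NPP only rises above the balance where the annual clamp at zero bites
  expect_true(all(res$npp_unclamped$values[ok] <= res$psnnet_sum$values[ok] + 1e-12))
  expect_true(all(res$psnnet_sum$values[ok] <= res$gpp$values[ok] + 1e-12))
  expect_equal(res$npp$values[ok], pmax(0, res$npp_unclamped$values[ok]),
               tolerance = 1e-12)
  grow <- ok & res$psnnet_sum$values >= 0
  expect_true(all(res$npp$values[grow] <= res$psnnet_sum$values[grow] + 1e-12))
  expect_true(all(res$qc$values[res$qc$valid_mask] >= 0 &
                    res$qc$values[res$qc$valid_mask] <= 100))

  # CUE = 1 limit: all respiration off makes NPP equal GPP exactly
  bp0 <- default_bplut()
  bp0$leaf_mr_base <- 0; bp0$froot_mr_base <- 0
  bp0$livewood_mr_base <- 0; bp0$rg_frac <- 0
  res0 <- lue_annual(met, fap, lc, bp0)
  expect_equal(res0$npp$values[ok], res0$gpp$values[ok], tolerance = 1e-12)
})
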