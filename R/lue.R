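#' Read a biome-parameter look-up table (BPLUT)
#'
#' One row per vegetated land-cover class. Columns:
#' \describe{
#'   \item{class}{land-cover code, see [lc_classes()]}
#'   \item{eps_max}{maximum light-use efficiency, g C MJ^-1 APAR}
#'   \item{tmin_min, tmin_max}{endpoints of the minimum-temperature ramp, deg C:
#'     photosynthesis fully off at or below `tmin_min`, unconstrained at or
#'     above `tmin_max`}
#'   \item{vpd_min, vpd_max}{endpoints of the vapour-pressure-deficit ramp, Pa:
#'     unconstrained at or below `vpd_min`, fully off at or above `vpd_max`}
#'   \item{sla}{specific leaf area, m^2 leaf (kg C)^-1}
#'   \item{froot_leaf_ratio}{fine-root to leaf carbon ratio, dimensionless}
#'   \item{leaf_mr_base, froot_mr_base, livewood_mr_base}{maintenance
#'     respiration base rates, g C (g C)^-1 d^-1 at 20 deg C}
#'   \item{livewood_pool}{live-wood carbon pool, g C m^-2}
#'   \item{q10}{Q10 of maintenance respiration}
#'   \item{rg_frac}{growth respiration as a fraction of (annual net
#'     photosynthesis - other maintenance respiration), dimensionless in [0,1)}
#' }
#'
#' @param path CSV file with the columns above.
#' @return A `data.frame` of class `bplut`.
#' @export
read_bplut <- function(path) {
  bp <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("class", "eps_max", "tmin_min", "tmin_max", "vpd_min",
                "vpd_max", "sla", "froot_leaf_ratio", "leaf_mr_base",
                "froot_mr_base", "livewood_mr_base", "livewood_pool",
                "q10", "rg_frac")
  missing <- setdiff(required, names(bp))
  if (length(missing)) stop("BPLUT missing columns: ", paste(missing, collapse = ", "))
  with(bp, stopifnot(all(eps_max > 0), all(tmin_min < tmin_max),
                     all(vpd_min < vpd_max), all(q10 > 0),
                     all(rg_frac >= 0), all(rg_frac < 1)))
  class(bp) <- c("bplut", class(bp))
  bp
}

#' Default example BPLUT shipped with the package
#'
#' The shipped values are documented example configuration producing
#' plausible tropical/subtropical productivity magnitudes; they are not the
#' operational satellite-product parameter set, which users can substitute
#' via [read_bplut()].
#'
#' @return A `bplut` data.frame.
#' @export
default_bplut <- function() {
  read_bplut(system.file("extdata", "bplut_default.csv",
                         package = "luefusion", mustWork = TRUE))
}

bplut_row <- function(params) {
  # accept a bplut row (data.frame) or a plain named list
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) stop("params must be a single BPLUT row")
    params <- as.list(params)
  }
  params
}

#' Minimum-temperature scalar f(Tmin)
#'
#' Clamped linear ramp: 0 at `tmin <= tmin_min`, 1 at `tmin >= tmin_max`,
#' linear in between.
#'
#' @param tmin Daily minimum temperature, deg C (vectorized).
#' @param params A BPLUT row or named list with `tmin_min`, `tmin_max`.
#' @return Values in \[0, 1\].
#' @export
tmin_scalar <- function(tmin, params) {
  p <- bplut_row(params)
  pmin(1, pmax(0, (tmin - p$tmin_min) / (p$tmin_max - p$tmin_min)))
}

#' Vapour-pressure-deficit scalar f(VPD)
#'
#' Clamped linear ramp: 1 at `vpd <= vpd_min` (no water stress), 0 at
#' `vpd >= vpd_max` (full stomatal closure), linear in between.
#'
#' @param vpd Daytime vapour pressure deficit, Pa (vectorized).
#' @param params A BPLUT row or named list with `vpd_min`, `vpd_max`.
#' @return Values in \[0, 1\].
#' @export
vpd_scalar <- function(vpd, params) {
  p <- bplut_row(params)
  pmin(1, pmax(0, (p$vpd_max - vpd) / (p$vpd_max - p$vpd_min)))
}

#' Daily gross primary production (LUE model)
#'
#' `GPP = eps_max * 0.45 * SWrad * FAPAR * f(VPD) * f(Tmin)`, where 45% of
#' incoming shortwave radiation is taken to be photosynthetically active.
#' All arguments vectorize (scalars, vectors or matrices of one shape).
#'
#' @param meteo Named list/data.frame with `sw_rad` (MJ m^-2 d^-1), `tmin`
#'   (deg C), `vpd` (Pa). An optional `tavg` is ignored here.
#' @param fapar Named list with `fapar` (fraction of absorbed PAR, in \[0,1\]).
#' @param params A BPLUT row.
#' @return GPP in g C m^-2 d^-1 (same shape as the inputs).
#' @examples
#' p <- list(eps_max = 1, tmin_min = -8, tmin_max = 8, vpd_min = 650, vpd_max = 2500)
#' daily_gpp(list(sw_rad = 20, tmin = 20, vpd = 0), list(fapar = 0.5), p)  # 4.5
#' @export
daily_gpp <- function(meteo, fapar, params) {
  p <- bplut_row(params)
  p$eps_max * 0.45 * meteo$sw_rad * fapar$fapar *
    vpd_scalar(meteo$vpd, p) * tmin_scalar(meteo$tmin, p)
}

#' Leaf area index from FAPAR (Beer-Lambert inversion)
#'
#' `LAI = -log(1 - FAPAR) / k` with light-extinction coefficient `k`.
#' FAPAR is capped just below 1 to keep LAI finite.
#'
#' @param fapar FAPAR in \[0, 1\] (vectorized).
#' @param k Extinction coefficient, default 0.5.
#' @return LAI, m^2 m^-2.
#' @export
lai_from_fapar <- function(fapar, k = 0.5) {
  -log(1 - pmin(pmax(fapar, 0), 1 - 1e-9)) / k
}

q10_factor <- function(tavg, q10) q10^((tavg - 20) / 10)

#' Daily maintenance respiration of leaves and fine roots
#'
#' Leaf carbon is derived from FAPAR via [lai_from_fapar()] and the specific
#' leaf area (`leaf C [g C m^-2] = 1000 * LAI / sla`); fine-root carbon is
#' `froot_leaf_ratio` times leaf carbon. Each pool respires at its base rate
#' scaled by `q10^((Tavg - 20)/10)` (reference temperature 20 deg C).
#'
#' @param fapar Named list with `fapar`.
#' @param meteo Named list with `tavg` (deg C).
#' @param params A BPLUT row.
#' @return List with `r_ml` and `r_mr`, g C m^-2 d^-1.
#' @export
maintenance_respiration_daily <- function(fapar, meteo, params) {
  p <- bplut_row(params)
  leaf_c <- 1000 * lai_from_fapar(fapar$fapar) / p$sla  # g C m^-2
  qf <- q10_factor(meteo$tavg, p$q10)
  list(r_ml = leaf_c * p$leaf_mr_base * qf,
       r_mr = leaf_c * p$froot_leaf_ratio * p$froot_mr_base * qf)
}

#' Daily net photosynthesis
#'
#' `PsnNet = GPP - R_ml - R_mr`; may be negative on days when maintenance
#' respiration exceeds assimilation.
#'
#' @param gpp,r_ml,r_mr Non-negative daily fluxes, g C m^-2 d^-1.
#' @return PsnNet, g C m^-2 d^-1.
#' @export
psn_net <- function(gpp, r_ml, r_mr) gpp - r_ml - r_mr

#' Annual maintenance respiration of live wood (R_mo)
#'
#' The live-wood pool (g C m^-2, per biome) respires daily at
#' `livewood_mr_base` scaled by the Q10 factor; the annual sum is R_mo.
#'
#' @param tavg_series Daily mean temperature series, deg C.
#' @param params A BPLUT row.
#' @return R_mo in g C m^-2 yr^-1.
#' @export
annual_rmo <- function(tavg_series, params) {
  p <- bplut_row(params)
  sum(p$livewood_pool * p$livewood_mr_base * q10_factor(tavg_series, p$q10))
}

#' Annual net primary production from the daily PsnNet series
#'
#' `NPP = max(0, sum(PsnNet) - (R_mo + R_g))`; the annual product convention
#' clamps at zero, and the unclamped value is retained for diagnostics.
#'
#' @param daily_psnnet Numeric series of length 365 or 366, g C m^-2 d^-1.
#' @param r_mo Annual other-maintenance respiration, g C m^-2 yr^-1.
#' @param r_g Annual growth respiration, g C m^-2 yr^-1.
#' @return List with `npp`, `npp_unclamped` and `psnnet_sum`
#'   (all g C m^-2 yr^-1).
#' @export
annual_npp <- function(daily_psnnet, r_mo, r_g) {
  if (!length(daily_psnnet) %in% c(365L, 366L)) {
    stop("validation error: daily series must have 365 or 366 days")
  }
  if (r_mo < 0 || r_g < 0) stop("validation error: respiration must be >= 0")
  s <- sum(daily_psnnet)
  pre <- s - (r_mo + r_g)
  list(npp = max(0, pre), npp_unclamped = pre, psnnet_sum = s)
}

#' Growth respiration from annual net photosynthesis
#'
#' `R_g = rg_frac * max(0, sum(PsnNet) - R_mo)` (vectorized).
#'
#' @param psnnet_sum Annual PsnNet sum, g C m^-2 yr^-1.
#' @param r_mo Annual other-maintenance respiration, g C m^-2 yr^-1.
#' @param rg_frac Growth-respiration fraction in \[0, 1).
#' @return R_g, g C m^-2 yr^-1.
#' @export
growth_respiration <- function(psnnet_sum, r_mo, rg_frac) {
  rg_frac * pmax(0, psnnet_sum - r_mo)
}

#' Growing-season day mask
#'
#' The growing season comprises all days with Tmin above -8 deg C (also the
#' floor of the temperature ramp); in tropical domains TOTALg is 365 almost
#' everywhere.
#'
#' @param tmin_series Daily minimum temperature, length 365 or 366.
#' @return List with `mask` (logical) and `totalg` (count of TRUE days).
#' @export
growing_season <- function(tmin_series) {
  if (!length(tmin_series) %in% c(365L, 366L)) {
    stop("validation error: daily series must have 365 or 366 days")
  }
  mask <- tmin_series > -8
  list(mask = mask, totalg = sum(mask))
}

#' Gap-fill quality-control percentage
#'
#' `QC = 100 * NUg / TOTALg`, where NUg is the number of growing-season days
#' whose FAPAR input was gap-filled (unreliable or missing satellite
#' retrieval) and TOTALg the number of growing-season days. Higher QC means
#' lower input quality. Undefined (returned as `NA`) when the growing season
#' is empty.
#'
#' @param filled_flags Logical series: `TRUE` where FAPAR was gap-filled.
#' @param season_mask Logical series of the same length (growing season).
#' @return QC percent in \[0, 100\], or `NA` if `TOTALg == 0`.
#' @export
qc_percent <- function(filled_flags, season_mask) {
  if (length(filled_flags) != length(season_mask)) {
    stop("validation error: flag and season series lengths differ")
  }
  totalg <- sum(season_mask)
  if (totalg == 0) return(NA_real_)
  100 * sum(filled_flags & season_mask) / totalg
}

#' Run the LUE engine over a gridded year of drivers
#'
#' Computes per-cell annual GPP, the PsnNet sum, respiration components
#' (R_mo, R_g), clamped annual NPP and the gap-fill QC percentage. Cells
#' whose land-cover class has no BPLUT row (Barren, Water, Urban) are
#' invalid in every output.
#'
#' @param meteo List of numeric arrays `[n_days, n_rows, n_cols]`:
#'   `sw_rad`, `tmin`, `tavg`, `vpd` (see [daily_gpp()] for units).
#' @param fapar List with arrays `fapar` and logical `filled` of the same
#'   shape.
#' @param landcover A [landcover_map()].
#' @param bplut A BPLUT (`read_bplut()`/[default_bplut()]).
#' @param rg_frac_override Optional scalar overriding the per-class
#'   `rg_frac` (used by the CUE calibration, [tune_rg_frac()]).
#' @return List of [field()]s on the land-cover grid: `gpp`, `npp`,
#'   `npp_unclamped`, `psnnet_sum`, `r_mo`, `r_g` (kg C m^-2 yr^-1 except
#'   `qc`, percent), plus `totalg` (days).
#' @export
lue_annual <- function(meteo, fapar, landcover, bplut = default_bplut(),
                       rg_frac_override = NULL) {
  stopifnot(inherits(landcover, "landcover_map"))
  g <- landcover$grid
  dims <- dim(meteo$sw_rad)
  n_days <- dims[1]
  if (!all(dims[2:3] == c(g$n_rows, g$n_cols))) {
    stop("geometry error: driver arrays do not match the land-cover grid")
  }
  idx <- match(landcover$classes, bplut$class)      # NA for unparameterized
  par_m <- function(col) matrix(bplut[[col]][idx], g$n_rows, g$n_cols)
  eps <- par_m("eps_max")
  tmn0 <- par_m("tmin_min"); tmn1 <- par_m("tmin_max")
  vpd0 <- par_m("vpd_min"); vpd1 <- par_m("vpd_max")
  sla <- par_m("sla"); frr <- par_m("froot_leaf_ratio")
  lmr <- par_m("leaf_mr_base"); fmr <- par_m("froot_mr_base")
  wmr <- par_m("livewood_mr_base"); wpool <- par_m("livewood_pool")
  q10 <- par_m("q10")
  rgf <- if (is.null(rg_frac_override)) par_m("rg_frac") else rg_frac_override

  zero <- matrix(0, g$n_rows, g$n_cols)
  gpp_sum <- zero; psn_sum <- zero; rmo_sum <- zero
  for (d in seq_len(n_days)) {
    sw <- meteo$sw_rad[d, , ]; tmin <- meteo$tmin[d, , ]
    tavg <- meteo$tavg[d, , ]; vpd <- meteo$vpd[d, , ]
    fp <- fapar$fapar[d, , ]
    ftmin <- pmin(1, pmax(0, (tmin - tmn0) / (tmn1 - tmn0)))
    fvpd <- pmin(1, pmax(0, (vpd1 - vpd) / (vpd1 - vpd0)))
    gpp_d <- eps * 0.45 * sw * fp * fvpd * ftmin
    qf <- q10^((tavg - 20) / 10)
    leaf_c <- 1000 * lai_from_fapar(fp) / sla
    r_ml <- leaf_c * lmr * qf
    r_mr <- leaf_c * frr * fmr * qf
    gpp_sum <- gpp_sum + gpp_d
    psn_sum <- psn_sum + (gpp_d - r_ml - r_mr)
    rmo_sum <- rmo_sum + wpool * wmr * qf
  }
  r_g <- rgf * pmax(0, psn_sum - rmo_sum)
  npp_pre <- psn_sum - rmo_sum - r_g
  npp <- pmax(0, npp_pre)

  # QC: growing-season and fill-flag counting, vectorized over cells
  season <- meteo$tmin > -8
  totalg <- colSums(season, dims = 1)
  nug <- colSums(fapar$filled & season, dims = 1)
  qc <- ifelse(totalg > 0, 100 * nug / totalg, NA_real_)

  mask <- matrix(!is.na(idx), g$n_rows, g$n_cols)
  as_f <- function(v, units = "kg C m-2 yr-1", scale = 1e-3) {
    v <- v * scale
    m <- mask & is.finite(v)   # e.g. undefined QC where TOTALg = 0
    v[!m] <- NA_real_
    field(g, matrix(v, g$n_rows, g$n_cols), m, units = units)
  }
  list(gpp = as_f(gpp_sum),
       npp = as_f(npp),
       npp_unclamped = as_f(npp_pre),
       psnnet_sum = as_f(psn_sum),
       r_mo = as_f(rmo_sum),
       r_g = as_f(r_g),
       qc = as_f(qc, units = "percent", scale = 1),
       totalg = field(g, matrix(as.numeric(totalg), g$n_rows, g$n_cols),
                      units = "days"))
}

#' Recompute NPP from cached annual components under a new rg_frac
#'
#' Given the `psnnet_sum` and `r_mo` fields returned by [lue_annual()],
#' applies `NPP = max(0, (PsnNet_sum - R_mo) * (1 - rg_frac))` without
#' re-running the daily loop. Used by [tune_rg_frac()].
#'
#' @param components Output list of [lue_annual()].
#' @param rg_frac Growth-respiration fraction in \[0, 1).
#' @return List with fields `npp` and `r_g` (kg C m^-2 yr^-1).
#' @export
apply_rg_frac <- function(components, rg_frac) {
  s <- components$psnnet_sum; rmo <- components$r_mo
  net <- pmax(0, s$values - rmo$values)
  r_g <- rg_frac * net
  npp_pre <- s$values - rmo$values - r_g
  mask <- s$valid_mask & rmo$valid_mask
  list(npp = field(s$grid, ifelse(mask, pmax(0, npp_pre), NA_real_), mask,
                   units = "kg C m-2 yr-1"),
       r_g = field(s$grid, ifelse(mask, r_g, NA_real_), mask,
                   units = "kg C m-2 yr-1"))
}
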