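# Seeded generators for a miniature Africa-like study domain. Every
# generator derives its RNG state from cfg$seed (plus a fixed per-generator
# offset), so the full fixture set is bit-reproducible from one integer.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# mean-one multiplicative lognormal noise with relative SD `cv`
lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Default land-cover area proportions of the emulated domain
#'
#' Scaled from the study-area class extents (million km^2): Savanna 5.6,
#' WSavanna 3.9, OShrub 3.7, EBF 3.0, Grass 2.2, Crop 0.89, CShrub 0.18,
#' the four minor forest types 0.37 combined, barren 9.8, water 0.25,
#' urban 0.0536 — about 30 million km^2 in total.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  areas <- c(Savanna = 5.6, WSavanna = 3.9, OShrub = 3.7, EBF = 3.0,
             Grass = 2.2, Crop = 0.89, CShrub = 0.18,
             ENF = 0.0925, DBF = 0.0925, DNF = 0.0925, MF = 0.0925,
             Barren = 9.8, Water = 0.25, Urban = 0.0536)
  areas / sum(areas)
}

#' Configuration of the synthetic study domain
#'
#' Bundles every knob of the generators. The defaults define the study
#' conditions emulated throughout the test-suite: a 120 x 120 fine grid of
#' 1-km-style cells nested 10:1 in a coarse DVM grid, three years, class
#' areas scaled from the study-area listing, DVM carbon-use efficiencies
#' averaging ~0.58 (0.55-0.62 across classes), a LUE-side CUE calibration
#' target of 0.46, a 65% gap-fill rate for the cloudy evergreen broadleaf
#' forest, and a 200 -> 600 mm yr^-1 north-to-south precipitation gradient
#' along which validation sites are laid out.
#'
#' @param seed Integer; mandatory master seed for all generators.
#' @param n_rows,n_cols Fine-grid dimensions.
#' @param cell_size Fine cell edge, m.
#' @param coarse_factor Fine cells per coarse cell edge (must divide both
#'   grid dimensions).
#' @param years Calendar years to simulate.
#' @param class_proportions Named class -> area fraction, summing to 1.
#' @param gpp_class_means DVM annual GPP per class, kg C m^-2 yr^-1.
#' @param dvm_cue_by_class DVM NPP/GPP ratio per class, in (0, 1).
#' @param lue_cue_target Continental NPP/GPP the LUE side is calibrated to
#'   (see [tune_rg_frac()]).
#' @param cloud_fill_rate_by_class Daily probability that a cell's FAPAR is
#'   gap-filled, per class.
#' @param precip_gradient `(north, south)` annual precipitation, mm yr^-1.
#' @param noise_sd Relative SD of the multiplicative lognormal noise on
#'   fluxes and drivers (0 = deterministic).
#' @param n_sites,n_masked_sites Validation sites on valid cells / forced
#'   onto masked cells (to exercise exclusion bookkeeping).
#' @param aboveground_fraction Fraction of total NPP visible as aboveground
#'   NPP at the sites.
#' @param sites_as_carbon Store site ANPP as carbon (`TRUE`) or as dry
#'   biomass at 50% carbon (`FALSE`, the field convention).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_rows = 120L, n_cols = 120L,
                             cell_size = 1000,
                             coarse_factor = 10L,
                             years = 2000:2002,
                             class_proportions = default_class_proportions(),
                             gpp_class_means = c(
                               EBF = 1.61, ENF = 1.10, DBF = 1.21, DNF = 1.15,
                               MF = 1.18, CShrub = 0.55, OShrub = 0.30,
                               WSavanna = 1.32, Savanna = 1.00, Grass = 0.65,
                               Crop = 0.85, Barren = 0, Water = 0, Urban = 0),
                             dvm_cue_by_class = c(
                               EBF = 0.56, ENF = 0.58, DBF = 0.58, DNF = 0.58,
                               MF = 0.58, CShrub = 0.58, OShrub = 0.58,
                               WSavanna = 0.55, Savanna = 0.62, Grass = 0.60,
                               Crop = 0.58),
                             lue_cue_target = 0.46,
                             cloud_fill_rate_by_class = c(
                               EBF = 0.65, ENF = 0.40, DBF = 0.45, DNF = 0.36,
                               MF = 0.49, CShrub = 0.30, OShrub = 0.24,
                               WSavanna = 0.43, Savanna = 0.33, Grass = 0.33,
                               Crop = 0.32, Barren = 0.10, Water = 0.10,
                               Urban = 0.15),
                             precip_gradient = c(north = 200, south = 600),
                             noise_sd = 0.05,
                             n_sites = 35L, n_masked_sites = 4L,
                             aboveground_fraction = 0.6,
                             sites_as_carbon = FALSE) {
  if (missing(seed)) stop("validation error: a seed is mandatory")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("validation error: class proportions must sum to 1")
  }
  if (any(dvm_cue_by_class <= 0 | dvm_cue_by_class >= 1) ||
      lue_cue_target <= 0 || lue_cue_target >= 1) {
    stop("validation error: CUE values must lie in (0, 1)")
  }
  if (coarse_factor < 1 || n_rows %% coarse_factor != 0 ||
      n_cols %% coarse_factor != 0) {
    stop("validation error: coarse_factor must divide the grid dimensions")
  }
  cfg <- list(seed = as.integer(seed), n_rows = as.integer(n_rows),
              n_cols = as.integer(n_cols), cell_size = cell_size,
              coarse_factor = as.integer(coarse_factor),
              years = as.integer(years),
              class_proportions = class_proportions,
              gpp_class_means = gpp_class_means,
              dvm_cue_by_class = dvm_cue_by_class,
              lue_cue_target = lue_cue_target,
              cloud_fill_rate_by_class = cloud_fill_rate_by_class,
              precip_gradient = precip_gradient,
              noise_sd = noise_sd,
              n_sites = as.integer(n_sites),
              n_masked_sites = as.integer(n_masked_sites),
              aboveground_fraction = aboveground_fraction,
              sites_as_carbon = isTRUE(sites_as_carbon))
  class(cfg) <- "synthetic_config"
  cfg
}

fine_grid <- function(cfg) {
  grid_spec(cfg$n_rows, cfg$n_cols, cell_size = cfg$cell_size,
            crs_label = "synthetic-equal-area")
}

coarse_grid <- function(cfg) {
  f <- cfg$coarse_factor
  grid_spec(cfg$n_rows %/% f, cfg$n_cols %/% f,
            cell_size = cfg$cell_size * f,
            origin = c(0, cfg$n_rows * cfg$cell_size),
            crs_label = "synthetic-equal-area")
}

# north -> south band order used when laying out the land cover
lc_band_order <- function() {
  c("Barren", "OShrub", "Grass", "Savanna", "Crop", "WSavanna",
    "EBF", "MF", "DBF", "DNF", "ENF", "CShrub", "Water", "Urban")
}

#' Generate the synthetic land-cover map
#'
#' Cell counts per class are fixed by largest-remainder allocation (each
#' class within one cell of its requested fraction); classes are laid out
#' as contiguous north-to-south latitudinal bands (desert in the north,
#' forest near the "equator") and then speckled by seeded random pair
#' swaps, which preserve the counts exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param speckle Fraction of cells taking part in randomizing swaps.
#' @return A [landcover_map()] on the fine grid.
#' @export
generate_landcover <- function(cfg, speckle = 0.1) {
  p <- cfg$class_proportions
  n <- cfg$n_rows * cfg$n_cols
  quota <- floor(p * n)
  rem <- n - sum(quota)
  if (rem > 0) {
    frac <- p * n - floor(p * n)
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  ord <- intersect(lc_band_order(), names(quota)[quota > 0])
  cls_seq <- unlist(lapply(ord, function(cl) rep(cl, quota[[cl]])))
  # row-major fill so bands run east-west
  m <- matrix(cls_seq, cfg$n_rows, cfg$n_cols, byrow = TRUE)
  set.seed(derive_seed(cfg$seed, 1L))
  n_swap <- floor(speckle * n / 2)
  if (n_swap > 0) {
    # disjoint pairs, so the swaps are a permutation and preserve counts
    perm <- sample.int(n, 2L * n_swap)
    i <- perm[seq_len(n_swap)]; j <- perm[n_swap + seq_len(n_swap)]
    tmp <- m[i]; m[i] <- m[j]; m[j] <- tmp
  }
  landcover_map(fine_grid(cfg), m)
}

precip_by_row <- function(cfg) {
  g <- cfg$precip_gradient
  g[[1]] + (g[[2]] - g[[1]]) * (seq_len(cfg$n_rows) - 0.5) / cfg$n_rows
}

#' Generate one year of daily meteorology
#'
#' Deterministic seasonal sinusoids plus optional multiplicative noise:
#' \itemize{
#'   \item `sw_rad(t) = 20 + 4 sin(2 pi (t - 80) / 365)` MJ m^-2 d^-1
#'   \item `tavg(t) = 24 + 4 sin(2 pi (t - 20) / 365)` deg C, `tmin = tavg - 10`
#'   \item `vpd(t, row) = (600 + 2800 d(row)) (1 + 0.25 sin(2 pi (t - 260) / 365))` Pa
#' }
#' where `d(row)` is the dryness index, 1 at the dry northern edge and 0 at
#' the wet southern edge of the precipitation gradient. All fields are
#' clamped to their physical bounds (`sw_rad >= 0`, `vpd >= 0`); in this
#' tropical domain Tmin never approaches the -8 deg C growing-season cutoff.
#'
#' @param cfg A [synthetic_config()].
#' @param year Calendar year (selects the noise stream; the deterministic
#'   part is identical across years).
#' @return List of arrays `[365, n_rows, n_cols]`: `sw_rad`, `tmin`,
#'   `tavg`, `vpd`.
#' @export
generate_meteo <- function(cfg, year) {
  set.seed(derive_seed(cfg$seed, 100L + match(year, cfg$years)))
  nd <- 365L; nr <- cfg$n_rows; nc <- cfg$n_cols
  t <- seq_len(nd)
  sw_t <- 20 + 4 * sin(2 * pi * (t - 80) / 365)
  ta_t <- 24 + 4 * sin(2 * pi * (t - 20) / 365)
  p <- precip_by_row(cfg)
  dry <- if (diff(range(p)) > 0) (max(p) - p) / diff(range(p)) else rep(0.5, nr)
  vpd_base <- 600 + 2800 * dry                       # per row
  vpd_season <- 1 + 0.25 * sin(2 * pi * (t - 260) / 365)
  mk <- function(day_vec) array(rep(day_vec, nr * nc), c(nd, nr, nc))
  sw <- mk(sw_t) * array(lognorm_noise(nd * nr * nc, cfg$noise_sd), c(nd, nr, nc))
  sw <- pmax(sw, 0)
  tavg <- mk(ta_t) + if (cfg$noise_sd > 0) {
    array(stats::rnorm(nd * nr * nc, 0, 10 * cfg$noise_sd), c(nd, nr, nc))
  } else 0
  vpd <- outer(vpd_season, vpd_base)                 # [day, row]
  vpd <- array(rep(as.vector(vpd), nc), c(nd, nr, nc))
  vpd <- vpd * array(lognorm_noise(nd * nr * nc, cfg$noise_sd), c(nd, nr, nc))
  vpd <- pmax(vpd, 0)
  list(sw_rad = sw, tmin = tavg - 10, tavg = tavg, vpd = vpd)
}

fapar_max_by_class <- function() {
  c(EBF = 0.90, ENF = 0.78, DBF = 0.78, DNF = 0.75, MF = 0.80,
    CShrub = 0.45, OShrub = 0.30, WSavanna = 0.75, Savanna = 0.65,
    Grass = 0.55, Crop = 0.60, Barren = 0.05, Water = 0, Urban = 0.10)
}

#' Generate one year of daily FAPAR with cloud-driven gap filling
#'
#' The clear-sky seasonal curve per class is
#' `fapar(t) = fmax * (0.75 + 0.25 sin(2 pi (t - 120) / 365))`, bounded in
#' \[0, 1\]. Each cell-day is flagged as gap-filled with the class's cloud
#' fill probability; flagged days carry the smooth seasonal value (the
#' stand-in for an interpolated fill), unflagged days carry the seasonal
#' value plus noise.
#'
#' @param cfg A [synthetic_config()].
#' @param landcover The [generate_landcover()] map.
#' @param year Calendar year (noise/flag stream).
#' @return List with array `fapar` and logical array `filled`, both
#'   `[365, n_rows, n_cols]`.
#' @export
generate_fapar <- function(cfg, landcover, year) {
  set.seed(derive_seed(cfg$seed, 200L + match(year, cfg$years)))
  nd <- 365L; nr <- cfg$n_rows; nc <- cfg$n_cols
  t <- seq_len(nd)
  season <- 0.75 + 0.25 * sin(2 * pi * (t - 120) / 365)
  fmax <- fapar_max_by_class()[as.vector(landcover$classes)]   # length nr*nc
  smooth <- outer(season, fmax)                                 # [day, cell]
  rate <- cfg$cloud_fill_rate_by_class[as.vector(landcover$classes)]
  rate[is.na(rate)] <- 0
  filled <- matrix(stats::runif(nd * nr * nc) <
                     rep(rate, each = nd), nd, nr * nc)
  noisy <- smooth * matrix(lognorm_noise(nd * nr * nc, cfg$noise_sd), nd)
  vals <- ifelse(filled, smooth, noisy)
  vals <- pmin(pmax(vals, 0), 1)
  list(fapar = array(vals, c(nd, nr, nc)),
       filled = array(filled, c(nd, nr, nc)))
}

#' Generate the coarse-grid DVM annual GPP and NPP products
#'
#' Each coarse cell takes the majority fine-grid class of its block; annual
#' GPP is the class mean (`gpp_class_means`) times a small seeded
#' interannual factor and multiplicative noise, and NPP is GPP times the
#' class's prescribed carbon-use efficiency (`dvm_cue_by_class`) with
#' independent noise of half the relative SD. At zero noise the per-cell
#' NPP/GPP ratio equals the prescription exactly. Classes without a CUE
#' prescription (Barren, Water, Urban) carry zero GPP and NPP.
#'
#' @param cfg A [synthetic_config()].
#' @param landcover The fine-grid [landcover_map()].
#' @return List with named lists `gpp` and `npp` of coarse [field()]s keyed
#'   by year, and `majority_class` (character matrix).
#' @export
generate_dvm_product <- function(cfg, landcover) {
  cg <- coarse_grid(cfg)
  f <- cfg$coarse_factor
  maj <- matrix(NA_character_, cg$n_rows, cg$n_cols)
  for (i in seq_len(cg$n_rows)) {
    for (j in seq_len(cg$n_cols)) {
      blk <- landcover$classes[((i - 1) * f + 1):(i * f),
                               ((j - 1) * f + 1):(j * f)]
      tab <- table(blk)
      maj[i, j] <- names(tab)[which.max(tab)]
    }
  }
  gm <- cfg$gpp_class_means[maj]; gm[is.na(gm)] <- 0
  cue <- cfg$dvm_cue_by_class[maj]; cue[is.na(cue)] <- 0
  gpp <- list(); npp <- list()
  for (k in seq_along(cfg$years)) {
    y <- cfg$years[k]
    set.seed(derive_seed(cfg$seed, 300L + k))
    yf <- 1 + 0.03 * sin(2 * pi * k / max(3, length(cfg$years)))
    g_vals <- gm * yf * lognorm_noise(length(gm), cfg$noise_sd)
    n_vals <- g_vals * cue * lognorm_noise(length(gm), cfg$noise_sd / 2)
    gpp[[as.character(y)]] <- field(cg, matrix(g_vals, cg$n_rows, cg$n_cols),
                                    units = "kg C m-2 yr-1")
    npp[[as.character(y)]] <- field(cg, matrix(n_vals, cg$n_rows, cg$n_cols),
                                    units = "kg C m-2 yr-1")
  }
  list(gpp = gpp, npp = npp, majority_class = maj)
}

#' Calibrate the growth-respiration fraction to a target domain CUE
#'
#' One-dimensional bisection on a global `rg_frac` override: given the
#' cached annual components from [lue_annual()] (one list per year), finds
#' the growth-respiration fraction at which the domain NPP/GPP ratio equals
#' `target`. The domain CUE is monotone decreasing in `rg_frac`, so
#' bisection on \[0, 0.999\] converges unconditionally; if the target is
#' outside the attainable range the nearest endpoint is returned with a
#' warning.
#'
#' @param components_by_year List of [lue_annual()] outputs, one per year.
#' @param target Target domain NPP/GPP ratio in (0, 1).
#' @param tol Bisection tolerance on `rg_frac`.
#' @return List with `rg_frac`, `cue` (achieved), `iterations`.
#' @export
tune_rg_frac <- function(components_by_year, target, tol = 1e-3) {
  cue_of <- function(rg) {
    tot_n <- 0; tot_g <- 0
    for (comp in components_by_year) {
      npp <- apply_rg_frac(comp, rg)$npp
      tot_n <- tot_n + sum(npp$values[npp$valid_mask])
      tot_g <- tot_g + sum(comp$gpp$values[comp$gpp$valid_mask])
    }
    tot_n / tot_g
  }
  lo <- 0; hi <- 0.999
  c_lo <- cue_of(lo); c_hi <- cue_of(hi)
  if (target > c_lo) {
    warning("target CUE above attainable range; returning rg_frac = 0")
    return(list(rg_frac = lo, cue = c_lo, iterations = 0L))
  }
  if (target < c_hi) {
    warning("target CUE below attainable range; returning rg_frac = 0.999")
    return(list(rg_frac = hi, cue = c_hi, iterations = 0L))
  }
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cue_of(mid) >= target) lo <- mid else hi <- mid
    it <- it + 1L
  }
  mid <- (lo + hi) / 2
  list(rg_frac = mid, cue = cue_of(mid), iterations = it)
}

#' Generate in-situ validation sites along the precipitation gradient
#'
#' Sites are placed on valid cells spread evenly north to south (the
#' emulated rainfall gradient) at random columns; observed aboveground NPP
#' is `aboveground_fraction * cell NPP * (1 + noise)`, stored as dry
#' biomass (twice the carbon value, per the 50%-carbon rule) unless
#' `cfg$sites_as_carbon`. `n_masked_sites` additional sites are placed on
#' invalid cells to exercise the exclusion bookkeeping; their "observed"
#' values are drawn near the valid-site mean.
#'
#' @param cfg A [synthetic_config()].
#' @param npp_truth A fine-grid [field()] of NPP (kg C m^-2 yr^-1) acting
#'   as the underlying truth.
#' @return Site `data.frame` (see [read_sites()]).
#' @export
generate_sites <- function(cfg, npp_truth) {
  stopifnot(inherits(npp_truth, "field"))
  set.seed(derive_seed(cfg$seed, 400L))
  g <- npp_truth$grid
  n_ok <- cfg$n_sites - cfg$n_masked_sites
  rows <- round(seq(1, g$n_rows, length.out = n_ok))
  pick <- function(r, want_valid) {
    cand <- which(npp_truth$valid_mask[r, ] == want_valid)
    ring <- 0L
    while (!length(cand) && ring < g$n_rows) {     # walk to a nearby row
      ring <- ring + 1L
      for (rr in unique(pmin(pmax(c(r - ring, r + ring), 1L), g$n_rows))) {
        cand <- which(npp_truth$valid_mask[rr, ] == want_valid)
        if (length(cand)) { r <- rr; break }
      }
    }
    if (!length(cand)) return(NULL)
    c(r, cand[sample.int(length(cand), 1L)])
  }
  cells <- lapply(rows, pick, want_valid = TRUE)
  masked_rows <- sample.int(g$n_rows, cfg$n_masked_sites, replace = TRUE)
  cells_bad <- lapply(masked_rows, pick, want_valid = FALSE)
  cells_bad <- cells_bad[!vapply(cells_bad, is.null, logical(1))]
  all_cells <- c(cells, cells_bad)
  n <- length(all_cells)
  truth_g <- vapply(all_cells, function(rc) {
    v <- npp_truth$values[rc[1], rc[2]]
    if (is.na(v)) NA_real_ else v * 1000           # kg -> g C m^-2
  }, numeric(1))
  mean_ok <- mean(truth_g, na.rm = TRUE)
  truth_g[is.na(truth_g)] <- mean_ok
  obs_c <- cfg$aboveground_fraction * truth_g * lognorm_noise(n, cfg$noise_sd)
  anpp <- if (cfg$sites_as_carbon) obs_c else obs_c / 0.5
  data.frame(
    site_id = sprintf("site_%02d", seq_len(n)),
    lon = vapply(all_cells, function(rc) g$origin[1] + (rc[2] - 0.5) * g$cell_size,
                 numeric(1)),
    lat = vapply(all_cells, function(rc) g$origin[2] - (rc[1] - 0.5) * g$cell_size,
                 numeric(1)),
    year = sample(cfg$years, n, replace = TRUE),
    anpp = anpp,
    is_carbon = cfg$sites_as_carbon,
    stringsAsFactors = FALSE)
}
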