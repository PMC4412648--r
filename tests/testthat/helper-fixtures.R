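# Small in-code fixtures shared across test files.

# a grid of n x m km-style cells (1e6 m^2 each)
km_grid <- function(nr, nc) grid_spec(nr, nc, cell_size = 1000)

# uniform single-class land cover
uniform_lc <- function(grid, class = "Savanna") {
  landcover_map(grid, matrix(class, grid$n_rows, grid$n_cols))
}

# land cover split into horizontal bands of equal height
banded_lc <- function(grid, classes) {
  stopifnot(grid$n_rows %% length(classes) == 0)
  h <- grid$n_rows / length(classes)
  landcover_map(grid, matrix(rep(classes, each = h), grid$n_rows, grid$n_cols))
}

# seeded random positive field
random_field <- function(grid, seed = 42, units = "kg C m-2 yr-1") {
  set.seed(seed)
  field(grid, matrix(runif(grid$n_rows * grid$n_cols, 0.1, 3),
                     grid$n_rows, grid$n_cols), units = units)
}

# single-row BPLUT with neutral scalars for hand-arithmetic tests
simple_params <- function(eps_max = 1, tmin_min = -8, tmin_max = 8,
                          vpd_min = 650, vpd_max = 2500, sla = 10,
                          froot_leaf_ratio = 1, leaf_mr_base = 0.001,
                          froot_mr_base = 0.001, livewood_mr_base = 0,
                          livewood_pool = 0, q10 = 2, rg_frac = 0.25) {
  list(eps_max = eps_max, tmin_min = tmin_min, tmin_max = tmin_max,
       vpd_min = vpd_min, vpd_max = vpd_max, sla = sla,
       froot_leaf_ratio = froot_leaf_ratio, leaf_mr_base = leaf_mr_base,
       froot_mr_base = froot_mr_base, livewood_mr_base = livewood_mr_base,
       livewood_pool = livewood_pool, q10 = q10, rg_frac = rg_frac)
}

# tiny synthetic configuration for fast end-to-end runs
tiny_config <- function(seed = 7, ...) {
  synthetic_config(seed = seed, n_rows = 40L, n_cols = 40L,
                   coarse_factor = 5L, years = 2000:2001, ...)
}
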