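test_that("fields round-trip through the ASCII grid format exactly", {
  g <- km_grid(2, 2)
  f <- field(g, matrix(c(1.5, -2.25, 0, 1e6), 2, 2), units = "kg C m-2 yr-1")
  path <- withr::local_tempfile(fileext = ".asc")
  write_field(f, path)
  back <- read_field(path)
  expect_identical(back$values, f$values)
  expect_identical(back$valid_mask, f$valid_mask)
  expect_identical(back$units, f$units)
  expect_true(same_grid(back$grid, g))

  # mixed valid/invalid cells: mask and values preserved
  f2 <- field(g, matrix(c(1, NA, 3, 4), 2, 2))
  path2 <- withr::local_tempfile(fileext = ".asc")
  write_field(f2, path2)
  back2 <- read_field(path2)
  expect_identical(back2$valid_mask, f2$valid_mask)
  expect_equal(sum(back2$valid_mask), 3L)
  expect_identical(back2$values[back2$valid_mask], f2$values[f2$valid_mask])

  # 100x100 seeded random field round-trips bit-exactly
  big <- random_field(km_grid(100, 100), seed = 1)
  path3 <- withr::local_tempfile(fileext = ".asc")
  write_field(big, path3)
  expect_identical(read_field(path3)$values, big$values)
})

test_that("raster I/O rejects bad inputs", {
  expect_error(read_field(tempfile()), "I/O error")
  expect_error(read_field(tempfile(), format_tag = "netcdf"), "unsupported")
  g <- km_grid(2, 2)
  f <- uniform_field(g, 1)
  expect_error(write_field(f, tempfile(), format_tag = "geotiff"), "unsupported")
  # truncated body (not one full band) is rejected
  path <- withr::local_tempfile(fileext = ".asc")
  write_field(f, path)
  lines <- readLines(path)
  writeLines(lines[1:7], path)   # drop the second data row
  expect_error(read_field(path), "unsupported format")
  # nodata sentinel colliding with a data value is refused at write time
  expect_error(write_field(uniform_field(g, -9999), tempfile()), "sentinel")
})

test_that("nearest-neighbour resampling replicates blocks and conserves means", {
  # coarse grid == fine grid: identity
  g <- km_grid(4, 4)
  f <- random_field(g, seed = 2)
  out <- resample_nearest(f, g)
  expect_identical(out$values, f$values)

  # one coarse cell -> 2x2 block of its value; explicit loop oracle
  cg <- grid_spec(2, 2, cell_size = 2000, origin = c(0, 4000))
  fg <- grid_spec(4, 4, cell_size = 1000, origin = c(0, 4000))
  cf <- field(cg, matrix(c(1, 2, 3, NA), 2, 2), units = "kg C m-2 yr-1")
  fine <- resample_nearest(cf, fg)
  for (i in 1:4) for (j in 1:4) {
    expect_identical(fine$values[i, j],
                     cf$values[ceiling(i / 2), ceiling(j / 2)])
  }
  # invalid coarse cell -> all children invalid
  expect_false(any(fine$valid_mask[3:4, 3:4]))

  # aggregation back to the coarse grid reproduces it where children valid
  agg <- aggregate_to_coarse(fine, cg)
  expect_equal(agg$values[agg$valid_mask], cf$values[cf$valid_mask])
  expect_identical(agg$valid_mask, cf$valid_mask)

  # non-nesting grids are a geometry error
  expect_error(resample_nearest(cf, grid_spec(3, 3, cell_size = 700,
                                              origin = c(0, 4000))),
               "geometry error")
})

test_that("mask harmonization intersects validity and drops excluded classes", {
  g <- km_grid(4, 4)
  lc <- banded_lc(g, c("EBF", "Savanna", "Water", "Barren"))
  va <- matrix(1, 4, 4); va[1, 1] <- NA
  vb <- matrix(2, 4, 4); vb[2, 2] <- NA
  a <- field(g, va); b <- field(g, vb)

  # no exclusions, identical masks: unchanged
  h0 <- harmonize_masks(field(g, matrix(1, 4, 4)), field(g, matrix(2, 4, 4)),
                        lc, excluded_classes = character())
  expect_true(all(h0$a$valid_mask))

  # set-intersection oracle: minus the two invalid cells and 8 excluded cells
  h <- harmonize_masks(a, b, lc)
  expect_identical(h$a$valid_mask, h$b$valid_mask)
  expect_false(h$a$valid_mask[1, 1])
  expect_false(h$a$valid_mask[2, 2])
  expect_equal(sum(h$a$valid_mask), 16 - 2 - 8)

  # idempotence
  h2 <- harmonize_masks(h$a, h$b, lc)
  expect_identical(h2$a$values, h$a$values)
  expect_identical(h2$a$valid_mask, h$a$valid_mask)

  # valid count decreases monotonically with more excluded classes
  n_prev <- sum(harmonize_masks(a, b, lc, character())$a$valid_mask)
  for (excl in list("Water", c("Water", "Barren"),
                    c("Water", "Barren", "Savanna"))) {
    n_now <- sum(harmonize_masks(a, b, lc, excl)$a$valid_mask)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }

  expect_error(harmonize_masks(a, field(km_grid(3, 3), matrix(1, 3, 3)), lc),
               "geometry error")
})

test_that("class statistics convert kg-per-cell sums into petagrams", {
  # 0.8 kg C m-2 yr-1 over an EBF extent of 3.0 million km^2 -> 2.4 Pg
  # (single row of 3e6 cells of 1 km^2 would be slow; use bigger cells)
  g <- grid_spec(10, 10, cell_size = 1000, cell_area = 3.0e12 / 100)
  lc <- uniform_lc(g, "EBF")
  st <- class_statistics(uniform_field(g, 0.8), lc)
  expect_equal(st$total_PgC[st$class == "EBF"], 2.4)
  expect_equal(st$area_km2[st$class == "EBF"], 3.0e6)

  # zero field: all totals and means zero
  st0 <- class_statistics(uniform_field(g, 0), lc)
  expect_equal(st0$total_PgC, 0)
  expect_equal(st0$mean_kgC_m2_yr, 0)

  # empty class: mean undefined (NA), total 0
  st_empty <- class_statistics(uniform_field(g, 1), lc, classes = c("EBF", "Grass"))
  expect_true(is.na(st_empty$mean_kgC_m2_yr[st_empty$class == "Grass"]))
  expect_identical(st_empty$total_PgC[st_empty$class == "Grass"], 0)
})

test_that("class totals sum to the domain total and ignore cell order", {
  g <- km_grid(12, 12)
  lc <- banded_lc(g, c("EBF", "Savanna", "Grass"))
  f <- random_field(g, seed = 3)
  st <- class_statistics(f, lc)
  # brute-force oracle over all cells
  brute <- sum(f$values * g$cell_area) / 1e12
  expect_equal(sum(st$total_PgC), brute, tolerance = 1e-12)
  expect_equal(domain_total(st), brute, tolerance = 1e-12)
  # invariant under row/column permutation of the grid
  set.seed(4)
  pr <- sample(12); pc <- sample(12)
  fp <- field(g, f$values[pr, pc])
  lp <- landcover_map(g, lc$classes[pr, pc])
  stp <- class_statistics(fp, lp)
  expect_equal(stp$total_PgC, st$total_PgC)
  expect_equal(stp$mean_kgC_m2_yr, st$mean_kgC_m2_yr)
})

test_that("land-cover maps round-trip with their legend", {
  g <- km_grid(6, 6)
  lc <- banded_lc(g, c("EBF", "Water", "Crop"))
  path <- withr::local_tempfile(fileext = ".asc")
  write_landcover(lc, path)
  back <- read_landcover(path)
  expect_identical(back$classes, lc$classes)
  expect_error(landcover_map(g, matrix("Jungle", 6, 6)), "unknown")
})
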