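three_sites <- site_set(1:3, x = c(1, 0, -4), y = c(0, 2, 0),
                        value = c(1, 2, 3))

test_that("IDW is exact at sites and symmetric between equidistant ones", {
  s <- site_set(1:2, x = c(0, 2), y = c(0, 0), value = c(2, 4))
  expect_identical(idw_interpolate(s, 0, 0), 2)
  expect_identical(idw_interpolate(s, 2, 0), 4)
  expect_equal(idw_interpolate(s, 1, 0), 3)
  expect_equal(idw_interpolate(s, 1, 5), 3)  # still equidistant
})

test_that("the three-point worked example matches the hand-computed weight sum", {
  # distances 1, 2, 4 from the origin; power 2:
  # (1*1 + 0.25*2 + 0.0625*3) / (1 + 0.25 + 0.0625) = 1.6875/1.3125
  expect_equal(round(idw_interpolate(three_sites, 0, 0, power = 2), 4),
               1.2857)
  expect_equal(idw_interpolate(three_sites, 0, 0, power = 2),
               1.6875 / 1.3125)
})

test_that("weights sum to one and the surface never overshoots the data range", {
  # weight normalization: a constant field interpolates to that constant
  set.seed(5)
  const <- site_set(1:8, x = runif(8), y = runif(8), value = rep(3.7, 8))
  qx <- runif(40, -2, 3); qy <- runif(40, -2, 3)
  expect_equal(idw_interpolate(const, qx, qy), rep(3.7, 40),
               tolerance = 1e-12)
  # boundedness for arbitrary values, powers and query points
  for (p in c(0.5, 1, 2, 3.5)) {
    vals <- runif(8, 0.151, 4.096)
    s <- site_set(1:8, x = runif(8, 0, 10), y = runif(8, 0, 10),
                  value = vals)
    z <- idw_interpolate(s, runif(60, -5, 15), runif(60, -5, 15), power = p)
    expect_true(all(z >= min(vals) - 1e-12 & z <= max(vals) + 1e-12))
  }
})

test_that("the surface is continuous away from sites and translation-invariant", {
  z1 <- idw_interpolate(three_sites, 0.5, 0.5)
  z2 <- idw_interpolate(three_sites, 0.5 + 1e-9, 0.5)
  rng <- diff(range(three_sites$value))
  expect_lt(abs(z1 - z2), 1e-6 * rng)
  shifted <- site_set(1:3, x = three_sites$x + 123.4,
                      y = three_sites$y - 56.7, value = three_sites$value)
  expect_equal(idw_interpolate(shifted, 0.5 + 123.4, 0.5 - 56.7), z1)
})

test_that("gridding applies the interpolator cellwise and stays in range", {
  one <- grid_spec(xll = 0.5, yll = -0.5, cellsize = 1, nrow = 1, ncol = 1)
  g1 <- idw_grid(three_sites, one)  # single cell centred on site 1
  expect_equal(g1$values[1, 1], 1)
  const <- site_set(1:3, x = c(0, 1, 2), y = c(0, 1, 0), value = rep(5, 3))
  g <- idw_grid(const, grid_spec(0, 0, 0.5, nrow = 6, ncol = 8))
  expect_equal(dim(g$values), c(6, 8))
  expect_equal(as.vector(g$values), rep(5, 48), tolerance = 1e-12)
  # synthetic Cd-like site set: grid bounded by the data range
  set.seed(8)
  cd <- site_set(1:21, x = runif(21, 0, 20), y = runif(21, 0, 20),
                 value = runif(21, 0.151, 4.096))
  gcd <- idw_grid(cd, grid_spec(0, 0, 1, nrow = 20, ncol = 20))
  expect_gte(min(gcd$values), 0.151)
  expect_lte(max(gcd$values), 4.096)
})

test_that("ESRI ASCII export writes the standard header and round-trips", {
  g <- idw_grid(three_sites, grid_spec(-5, -3, 0.8, nrow = 7, ncol = 9))
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "^ncols 9$")
  expect_match(lines[2], "^nrows 7$")
  expect_match(lines[3], "^xllcorner -5$")
  expect_match(lines[4], "^yllcorner -3$")
  expect_match(lines[5], "^cellsize 0.8$")
  expect_match(lines[6], "^NODATA_value -9999$")
  expect_length(lines, 6 + 7)
  back <- read_esri_ascii(path)
  expect_equal(back$values, g$values, tolerance = 1e-9)
  expect_equal(back$cellsize, g$cellsize)
  # long-format export carries cell centres
  df <- grid_to_df(g)
  expect_equal(nrow(df), 63)
  expect_equal(df$x[1], -5 + 0.4)
  expect_equal(df$y[1], -3 + 7 * 0.8 - 0.4)
})

test_that("degenerate inputs are refused and lon/lat input warns", {
  expect_error(idw_interpolate(data.frame(), 0, 0), "non-empty")
  expect_error(site_set(1:2, x = c(0, 0), y = c(0, 0), value = c(1, 2)),
               "unique")
  expect_error(site_set(1, x = 0, y = 0, value = -1), "non-negative")
  expect_error(idw_interpolate(three_sites, 0, 0, power = 0), "power")
  expect_warning(project_lonlat(c(52.5, 52.6), c(29.6, 29.7)),
                 "equirectangular")
})
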