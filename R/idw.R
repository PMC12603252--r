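#' Build a set of measurement sites for spatial interpolation
#'
#' @param id Site identifiers.
#' @param x,y Planar coordinates (any consistent length unit). Longitude /
#'   latitude pairs can be converted first with [project_lonlat()].
#' @param value Measured values (mg·kg⁻¹), non-negative.
#' @return A data.frame of class `site_set` with columns `id`, `x`, `y`,
#'   `value`.
#' @export
site_set <- function(id, x, y, value) {
  if (length(x) == 0L) stop("a site set needs at least one site",
                            call. = FALSE)
  if (length(unique(paste(x, y))) != length(x))
    stop("site coordinates must be unique", call. = FALSE)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
    stop("site values must be finite and non-negative", call. = FALSE)
  stopifnot(length(id) == length(x), length(y) == length(x),
            length(value) == length(x))
  structure(data.frame(id = id, x = x, y = y, value = value),
            class = c("site_set", "data.frame"))
}

#' Project longitude/latitude to local planar coordinates
#'
#' Equirectangular projection about the centroid latitude, returning
#' kilometres east/north. Adequate for the city-scale extents this package
#' interpolates over; a warning notes the approximation.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @return A list with planar `x`, `y` in km.
#' @export
project_lonlat <- function(lon, lat) {
  warning("lon/lat input projected with a local equirectangular ",
          "approximation; distances are approximate", call. = FALSE)
  r_earth <- 6371
  lat0 <- mean(lat) * pi / 180
  list(x = r_earth * cos(lat0) * lon * pi / 180,
       y = r_earth * lat * pi / 180)
}

#' Inverse-distance-weighted interpolation at query points
#'
#' Estimates the value at unsampled locations as the weighted mean of all
#' site values, with weights proportional to Euclidean distance to the power
#' `-power`. The interpolator is exact at site locations (zero distance
#' short-circuits to that site's value) and bounded by the range of the site
#' values.
#'
#' @param sites A [site_set()] (or data.frame with `x`, `y`, `value`).
#' @param x,y Query coordinates (vectors of equal length).
#' @param power Positive distance-decay exponent; default 2.
#' @return Interpolated value(s).
#' @examples
#' s <- site_set(1:2, x = c(0, 2), y = c(0, 0), value = c(2, 4))
#' idw_interpolate(s, 1, 0)  # 3: equidistant
#' @export
idw_interpolate <- function(sites, x, y, power = 2) {
  if (!is.data.frame(sites) || nrow(sites) == 0L)
    stop("'sites' must be a non-empty site set", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || power <= 0)
    stop("'power' must be a single positive number", call. = FALSE)
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(k) {
    d <- sqrt((sites$x - x[k])^2 + (sites$y - y[k])^2)
    hit <- which(d == 0)
    if (length(hit)) return(sites$value[hit[1L]])
    w <- d^(-power)
    sum(w * sites$value) / sum(w)
  }, numeric(1))
}

#' Define a regular raster grid
#'
#' Cells are square, cell-centre sampled, stored row-major from the top-left
#' corner (row 1 is the northernmost row). `xll`/`yll` are the coordinates
#' of the lower-left corner of the grid extent.
#'
#' @param xll,yll Lower-left corner of the grid extent.
#' @param cellsize Cell edge length (> 0).
#' @param nrow,ncol Grid dimensions (>= 1).
#' @param nodata No-data sentinel written by [write_esri_ascii()].
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(xll, yll, cellsize, nrow, ncol, nodata = -9999) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 nodata = nodata),
            class = "grid_spec")
}

# Cell-centre coordinates; row 1 = top row.
grid_centres <- function(spec) {
  xs <- spec$xll + (seq_len(spec$ncol) - 0.5) * spec$cellsize
  ys <- spec$yll + (spec$nrow - seq_len(spec$nrow) + 0.5) * spec$cellsize
  list(x = xs, y = ys)
}

#' Interpolate a site set onto a regular grid
#'
#' Applies [idw_interpolate()] at every cell centre of the grid.
#'
#' @inheritParams idw_interpolate
#' @param spec A [grid_spec()].
#' @return An object of class `raster_grid`: the `grid_spec` fields plus a
#'   `values` matrix (`nrow` x `ncol`, row 1 = top).
#' @export
idw_grid <- function(sites, spec, power = 2) {
  stopifnot(inherits(spec, "grid_spec"))
  ctr <- grid_centres(spec)
  vals <- matrix(NA_real_, spec$nrow, spec$ncol)
  for (r in seq_len(spec$nrow))
    vals[r, ] <- idw_interpolate(sites, ctr$x, rep(ctr$y[r], spec$ncol),
                                 power)
  structure(c(unclass(spec), list(values = vals)), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells of %.4g, lower-left (%.4g, %.4g)\n",
    x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Write a raster grid as an ESRI ASCII grid (.asc)
#'
#' Standard six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows north to south.
#'
#' @param grid A [idw_grid()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", grid$nodata)), con)
  vals <- grid$values
  vals[!is.finite(vals)] <- grid$nodata
  for (r in seq_len(grid$nrow))
    writeLines(paste(format(vals[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_esri_ascii()] (or any
#'   standard ESRI ASCII grid with an `xllcorner`-style header).
#' @return A `raster_grid`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  spec <- grid_spec(h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
                    h[["nrows"]], h[["ncols"]], h[["nodata_value"]])
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == spec$nodata] <- NA_real_
  structure(c(unclass(spec), list(values = vals)), class = "raster_grid")
}

#' Long-format export of a raster grid
#'
#' @param grid A `raster_grid`.
#' @return data.frame with `row`, `col`, cell-centre `x`, `y` and `value`.
#' @export
grid_to_df <- function(grid) {
  ctr <- grid_centres(grid)
  data.frame(
    row = rep(seq_len(grid$nrow), each = grid$ncol),
    col = rep(seq_len(grid$ncol), times = grid$nrow),
    x = rep(ctr$x, times = grid$nrow),
    y = rep(ctr$y, each = grid$ncol),
    value = as.vector(t(grid$values))
  )
}
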