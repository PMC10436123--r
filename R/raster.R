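#' NDVI raster container
#'
#' A georeferenced grid of vegetation-index values on WGS84 lon/lat with
#' square cells. Row 1 of `values` is the northernmost row (the usual raster
#' layout); `NA` cells are nodata. Every non-nodata value must lie in
#' \eqn{[-1, 1]}.
#'
#' @param values numeric matrix, row 1 = north.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid.
#' @param cellsize cell edge length in decimal degrees.
#' @return an object of class `ndvi_raster`.
#' @export
ndvi_raster <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  v <- values[is.finite(values)]
  if (length(v) && (min(v) < -1 || max(v) > 1))
    stop("NDVI values must lie in [-1, 1]")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 crs = "WGS84"),
            class = "ndvi_raster")
}

#' @export
print.ndvi_raster <- function(x, ...) {
  cat(sprintf("<ndvi_raster> %d x %d cells, %.6g deg, origin (%.5f, %.5f)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @rdname ndvi_raster
#' @param raster an `ndvi_raster` or `band_pair`.
#' @return `raster_extent()`: named vector xmin/xmax/ymin/ymax (degrees).
#' @export
raster_extent <- function(raster) {
  d <- dim(raster_grid(raster))
  c(xmin = raster$xll, xmax = raster$xll + d[2] * raster$cellsize,
    ymin = raster$yll, ymax = raster$yll + d[1] * raster$cellsize)
}

raster_grid <- function(raster) {
  if (inherits(raster, "band_pair")) raster$nir else raster$values
}

#' Reflectance band pair
#'
#' Near-infrared and visible reflectance grids sharing one geotransform; the
#' raw satellite product that [compute_ndvi()] turns into an NDVI surface.
#' Reflectances are unitless and nonnegative.
#'
#' @param nir,vis numeric matrices of identical shape (row 1 = north).
#' @inheritParams ndvi_raster
#' @export
band_pair <- function(nir, vis, xll, yll, cellsize) {
  stopifnot(is.matrix(nir), is.matrix(vis))
  if (!identical(dim(nir), dim(vis)))
    stop("NIR and VIS grids must have identical shape")
  if (any(nir < 0, na.rm = TRUE) || any(vis < 0, na.rm = TRUE))
    stop("reflectances must be nonnegative")
  structure(list(nir = nir, vis = vis, xll = xll, yll = yll,
                 cellsize = cellsize, crs = "WGS84"),
            class = "band_pair")
}

#' Compute NDVI from a band pair
#'
#' Cellwise normalized difference vegetation index
#' \deqn{NDVI = (NIR - VIS) / (NIR + VIS),}
#' the standard vegetation-density proxy: near \eqn{1} over dense vegetation,
#' near \eqn{0} over bare ground, negative over water. Cells with
#' \eqn{NIR + VIS = 0} carry no radiometric information and become nodata.
#' For nonnegative reflectances the output always lies in \eqn{[-1, 1]}.
#'
#' @param bands a [band_pair()].
#' @return an [ndvi_raster()] with the same geotransform.
#' @export
compute_ndvi <- function(bands) {
  if (!inherits(bands, "band_pair")) stop("`bands` must be a band_pair")
  s <- bands$nir + bands$vis
  out <- (bands$nir - bands$vis) / s
  out[!is.na(s) & s == 0] <- NA_real_
  ndvi_raster(out, bands$xll, bands$yll, bands$cellsize)
}

#' Sample a raster at point locations
#'
#' Nearest-cell lookup under the pixel-is-area convention: a point belongs to
#' the cell whose half-open bounds contain it, closed on the lower (south/west)
#' edge and open on the upper, so a point exactly on an interior boundary falls
#' in the cell with the larger index along the increasing axis. Points outside
#' the raster extent are reported as `"outside"`, distinct from `"nodata"`
#' cells inside it.
#'
#' @param raster an [ndvi_raster()].
#' @param lon,lat numeric vectors of WGS84 coordinates (recycled to a common
#'   length).
#' @return data.frame with columns `value` (numeric, `NA` unless status is
#'   `"ok"`) and `status` (`"ok"`, `"nodata"`, `"outside"`).
#' @export
sample_raster <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "ndvi_raster"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  col <- floor((lon - raster$xll) / raster$cellsize) + 1
  row_s <- floor((lat - raster$yll) / raster$cellsize) + 1  # 1 = south row
  inside <- col >= 1 & col <= nc & row_s >= 1 & row_s <= nr &
    !is.na(col) & !is.na(row_s)
  value <- rep(NA_real_, n)
  status <- rep("outside", n)
  if (any(inside)) {
    row <- nr - row_s[inside] + 1  # matrix row 1 = north
    v <- raster$values[cbind(row, col[inside])]
    value[inside] <- v
    status[inside] <- ifelse(is.na(v), "nodata", "ok")
    value[inside][is.na(v)] <- NA_real_
  }
  data.frame(value = value, status = status, stringsAsFactors = FALSE)
}

#' Read / write a plain-text (ESRI ASCII) grid
#'
#' The portable text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' whitespace-separated values, northernmost row first.
#'
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `read_ascii_grid()`: an [ndvi_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val["ncols"]); nr <- as.integer(val["nrows"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) stop("grid body does not match header dimensions")
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  ndvi_raster(m, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}

#' @rdname read_ascii_grid
#' @inheritParams sample_raster
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "ndvi_raster"))
  m <- raster$values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", sprintf("%.17g", raster$xll)),
           paste("yllcorner", sprintf("%.17g", raster$yll)),
           paste("cellsize", sprintf("%.17g", raster$cellsize)),
           paste("NODATA_value", nodata))
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
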