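# Gridded rasters in geographic (WGS84) coordinates, stored as plain
# matrices with row 1 the northernmost row (ESRI ASCII row order).

#' Construct a raster grid
#'
#' A `raster_grid` holds one gridded variable on a regular
#' longitude/latitude lattice: a numeric matrix (row 1 = north), the
#' lower-left corner of the footprint, the (square) cell size in decimal
#' degrees, and a nodata sentinel. Nodata cells are stored as `NA`.
#'
#' @param values numeric matrix, row 1 the northernmost row
#' @param x_ll longitude of the lower-left corner (degrees)
#' @param y_ll latitude of the lower-left corner (degrees)
#' @param cell_size cell edge in decimal degrees (square cells)
#' @param nodata_value sentinel written to file for `NA` cells
#' @return an object of class `raster_grid`
#' @export
raster_grid <- function(values, x_ll, y_ll, cell_size, nodata_value = -9999) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cell_size > 0)
  if (x_ll < -180 || y_ll < -90 ||
      x_ll + ncol(values) * cell_size > 180 + 1e-9 ||
      y_ll + nrow(values) * cell_size > 90 + 1e-9) {
    stop("grid footprint must lie within [-180,180] x [-90,90]")
  }
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) stop("grid values must be finite or NA (nodata)")
  structure(
    list(
      n_rows = nrow(values), n_cols = ncol(values),
      x_ll = x_ll, y_ll = y_ll, cell_size = cell_size,
      nodata_value = nodata_value, values = values
    ),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "raster_grid: %d x %d cells, cell %g deg, ll corner (%g, %g), %d nodata\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll, sum(is.na(x$values))
  ))
  invisible(x)
}

same_geometry <- function(a, b, check_mask = TRUE) {
  ok <- a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$x_ll, b$x_ll)) && isTRUE(all.equal(a$y_ll, b$y_ll)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
  if (ok && check_mask) ok <- identical(is.na(a$values), is.na(b$values))
  ok
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-key header (`ncols`, `nrows`, `xllcorner` or
#' `xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, `NODATA_value`; any
#' case) followed by `nrows` rows of values, north first. The `xllcenter`
#' dialect is converted to the corner convention by subtracting half a
#' cell. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path path to a `.asc` file
#' @return a [raster_grid]
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[a-zA-Z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      header[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_header <- n_header + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  for (key in need) {
    if (is.null(header[[key]])) stop("malformed ESRI ASCII header: missing key '", key, "'")
  }
  cs <- header$cellsize
  if (!is.null(header$xllcorner)) {
    x_ll <- header$xllcorner
  } else if (!is.null(header$xllcenter)) {
    x_ll <- header$xllcenter - cs / 2
  } else {
    stop("malformed ESRI ASCII header: missing key 'xllcorner'")
  }
  if (!is.null(header$yllcorner)) {
    y_ll <- header$yllcorner
  } else if (!is.null(header$yllcenter)) {
    y_ll <- header$yllcenter - cs / 2
  } else {
    stop("malformed ESRI ASCII header: missing key 'yllcorner'")
  }
  nr <- as.integer(header$nrows)
  nc <- as.integer(header$ncols)
  vals <- scan(text = paste(lines[-seq_len(n_header)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("truncated ESRI ASCII grid: expected %d values, found %d",
                 nr * nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == header$nodata_value] <- NA
  raster_grid(m, x_ll, y_ll, cs, nodata_value = header$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Emits the standard 6-line header (corner convention) then rows
#' north-to-south; `NA` cells are written as the grid's nodata sentinel.
#'
#' @param grid a [raster_grid]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata_value
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x_ll),
    sprintf("yllcorner %.10g", grid$y_ll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata_value)
  )
  body <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 15),
                                        collapse = " "))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ESRI ASCII grid to: ", path)
  invisible(path)
}

#' Cell index of a point
#'
#' Assigns points to cells with half-open intervals
#' `[west, east) x [south, north)`; points exactly on the far (east/north)
#' edge of the grid fall outside. Returns 1-based `(row, col)` with row 1
#' the northernmost row, or `NA` for points outside the footprint.
#'
#' @param grid a [raster_grid]
#' @param lon,lat point coordinates (degrees)
#' @return integer matrix with columns `row`, `col`
#' @export
cell_index <- function(grid, lon, lat) {
  j <- floor((lon - grid$x_ll) / grid$cell_size)        # 0-based from west
  i_s <- floor((lat - grid$y_ll) / grid$cell_size)      # 0-based from south
  i <- grid$n_rows - 1 - i_s                            # 0-based from north
  outside <- j < 0 | j >= grid$n_cols | i_s < 0 | i_s >= grid$n_rows
  i[outside] <- NA_integer_
  j[outside] <- NA_integer_
  cbind(row = as.integer(i) + 1L, col = as.integer(j) + 1L)
}

#' Cell-center coordinates
#'
#' @param grid a [raster_grid]
#' @param row,col 1-based indices (row 1 = north)
#' @return matrix with columns `longitude`, `latitude`
#' @export
cell_center <- function(grid, row, col) {
  cbind(
    longitude = grid$x_ll + (col - 0.5) * grid$cell_size,
    latitude = grid$y_ll + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}

#' Spherical cell areas by row
#'
#' Area of one cell in each row on the authalic sphere
#' (R = 6371.0088 km): `R^2 * dlon * (sin(lat_n) - sin(lat_s))`, constant
#' within a row since cells in a row share the latitude band.
#'
#' @param grid a [raster_grid]
#' @return numeric vector of length `n_rows` (km^2), row 1 = north
#' @export
cell_areas <- function(grid) {
  R <- 6371.0088
  lat_top <- grid$y_ll + grid$n_rows * grid$cell_size
  if (lat_top > 90 + 1e-9 || grid$y_ll < -90 - 1e-9) {
    stop("grid rows extend past a pole")
  }
  i <- seq_len(grid$n_rows)
  lat_n <- (grid$y_ll + (grid$n_rows - i + 1) * grid$cell_size) * pi / 180
  lat_s <- (grid$y_ll + (grid$n_rows - i) * grid$cell_size) * pi / 180
  R^2 * (grid$cell_size * pi / 180) * (sin(lat_n) - sin(lat_s))
}

# Matrix of per-cell areas (n_rows x n_cols), for area-weighted sums.
cell_area_matrix <- function(grid) {
  matrix(cell_areas(grid), nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Construct an environmental layer stack
#'
#' An ordered, named collection of [raster_grid] layers sharing one
#' geometry and nodata mask, labelled with its climate scenario.
#'
#' @param layers named list of [raster_grid]
#' @param scenario_label text label, e.g. `"current"` or `"2050s-SSP1-2.6"`
#' @return an object of class `env_stack`
#' @export
env_stack <- function(layers, scenario_label = "current") {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all layers must be named")
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "raster_grid")) stop("layer '", nm, "' is not a raster_grid")
    if (!same_geometry(ref, layers[[nm]])) {
      stop("layer '", nm, "' does not share the stack geometry/nodata mask")
    }
  }
  structure(list(layers = layers, scenario_label = scenario_label),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack '%s': %d layers (%s), %d x %d cells\n",
              x$scenario_label, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              x$layers[[1]]$n_rows, x$layers[[1]]$n_cols))
  invisible(x)
}

# Linear indices (into the value matrix) of non-nodata cells.
valid_cells <- function(grid) which(!is.na(grid$values))

# Extract an N x V matrix of layer values at the given linear cell indices.
extract_values <- function(stack, cells) {
  out <- vapply(stack$layers, function(g) g$values[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  colnames(out) <- names(stack$layers)
  out
}

# Linear cell indices of an occurrence set on a grid.
occ_cell_indices <- function(grid, occ) {
  idx <- cell_index(grid, occ$records$longitude, occ$records$latitude)
  (idx[, "col"] - 1L) * grid$n_rows + idx[, "row"]
}
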