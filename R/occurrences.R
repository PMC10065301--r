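# Presence records: CSV input, validation against a grid, per-cell thinning.

#' Construct an occurrence set
#'
#' @param longitude,latitude numeric vectors (WGS84 decimal degrees)
#' @param thinned whether the set is already thinned to one record per cell
#' @return an object of class `occurrence_set`
#' @export
occurrence_set <- function(longitude, latitude, thinned = FALSE) {
  stopifnot(length(longitude) == length(latitude))
  structure(
    list(
      records = data.frame(longitude = as.numeric(longitude),
                           latitude = as.numeric(latitude)),
      crs = "WGS84", thinned = isTRUE(thinned)
    ),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records (%s)\n", nrow(x$records),
              if (x$thinned) "thinned" else "unthinned"))
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' Expects a header with columns `species`, `longitude`, `latitude`
#' (longitude before latitude, the MaxEnt samples-file convention).
#' Records with unparseable or out-of-domain coordinates (|lat| > 90,
#' |lon| > 180), outside the grid footprint, or on nodata cells are
#' dropped; the drop count is reported via `message()`.
#'
#' @param path CSV path
#' @param grid the [raster_grid] defining the study footprint
#' @return an [occurrence_set] (unthinned)
#' @export
read_occurrences <- function(path, grid) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "))
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  n0 <- nrow(df)
  ok <- is.finite(lon) & is.finite(lat) & abs(lon) <= 180 & abs(lat) <= 90
  idx <- cell_index(grid, ifelse(ok, lon, NA), ifelse(ok, lat, NA))
  inside <- ok & !is.na(idx[, "row"])
  on_data <- inside
  on_data[inside] <- !is.na(grid$values[cbind(idx[inside, "row"], idx[inside, "col"])])
  dropped <- n0 - sum(on_data)
  if (dropped > 0) message(dropped, " occurrence record(s) dropped (invalid, outside footprint, or nodata)")
  if (!any(on_data)) stop("no valid occurrence records remain after filtering")
  occurrence_set(lon[on_data], lat[on_data])
}

#' Write occurrence records to CSV
#'
#' @param occ an [occurrence_set]
#' @param path output path
#' @param species species label written to the `species` column
#' @return `path`, invisibly
#' @export
write_occurrences <- function(occ, path, species = "species") {
  utils::write.csv(
    data.frame(species = species,
               longitude = occ$records$longitude,
               latitude = occ$records$latitude),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Thin occurrences to one record per grid cell
#'
#' Keeps the first record (in input order) of each occupied cell, so
#' repeated presences within a cell carry no extra weight. Idempotent.
#'
#' @param occ an [occurrence_set]
#' @param grid the [raster_grid] whose cells define uniqueness
#' @return a thinned [occurrence_set]
#' @export
thin_per_cell <- function(occ, grid) {
  idx <- cell_index(grid, occ$records$longitude, occ$records$latitude)
  if (anyNA(idx)) stop("occurrences must be validated against the grid before thinning")
  key <- paste(idx[, "row"], idx[, "col"])
  keep <- !duplicated(key)
  occurrence_set(occ$records$longitude[keep], occ$records$latitude[keep],
                 thinned = TRUE)
}
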