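# Temporal comparison of suitability maps: stable/expand/shrink overlays,
# class-transition accounting, and centroid trajectories of the most
# suitable habitat on the sphere.

CHANGE_LEVELS <- c(never = 0, stable = 1, expand = 2, shrink = 3)
EARTH_RADIUS_KM <- 6371.0088
COMPASS_8 <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Binary suitable mask
#'
#' `TRUE` where the class is poor, moderate or most suitable.
#'
#' @param classified a [classify] result
#' @return logical matrix (NA on nodata)
#' @export
binary_suitable <- function(classified) {
  v <- classified$classes$values
  ifelse(is.na(v), NA, v >= 1)
}

#' Stable/expand/shrink overlay
#'
#' Per-cell four-way comparison of two suitable masks on one geometry:
#' stable (both), expand (future only), shrink (current only), never
#' (neither). Conservation holds by construction: stable + shrink =
#' current-suitable, stable + expand = future-suitable.
#'
#' @param current,future logical masks from [binary_suitable] (same
#'   geometry); alternatively `classified_map`s
#' @param geometry a [raster_grid] supplying geometry when masks are
#'   plain matrices
#' @return an object of class `change_map`
#' @export
overlay_change <- function(current, future, geometry = NULL) {
  if (inherits(current, "classified_map")) {
    geometry <- current$classes
    current <- binary_suitable(current)
  }
  if (inherits(future, "classified_map")) {
    if (is.null(geometry)) geometry <- future$classes
    future <- binary_suitable(future)
  }
  if (!identical(dim(current), dim(future)) ||
      !identical(is.na(current), is.na(future))) {
    stop("overlay requires identical geometry and nodata mask")
  }
  cls <- matrix(NA_real_, nrow(current), ncol(current))
  ok <- !is.na(current)
  cls[ok] <- ifelse(current[ok] & future[ok], CHANGE_LEVELS["stable"],
             ifelse(future[ok], CHANGE_LEVELS["expand"],
             ifelse(current[ok], CHANGE_LEVELS["shrink"], CHANGE_LEVELS["never"])))
  grid <- if (is.null(geometry)) NULL else
    raster_grid(cls, geometry$x_ll, geometry$y_ll, geometry$cell_size,
                geometry$nodata_value)
  structure(list(classes = cls, grid = grid), class = "change_map")
}

#' Area proportions of a change map
#'
#' Area-weighted percentages with the conventional denominators: stable
#' and shrink relative to the current suitable area, expand relative to
#' the future suitable area. Zero denominators give `NA`.
#'
#' @param change a [overlay_change] result with geometry
#' @return named vector `stable_pct_current`, `shrink_pct_current`,
#'   `expand_pct_future`
#' @export
change_proportions <- function(change) {
  if (is.null(change$grid)) stop("change map carries no geometry for areas")
  am <- cell_area_matrix(change$grid)
  cls <- change$classes
  area_of <- function(k) sum(am[!is.na(cls) & cls == CHANGE_LEVELS[k]])
  stable <- area_of("stable"); expand <- area_of("expand"); shrink <- area_of("shrink")
  cur <- stable + shrink
  fut <- stable + expand
  c(stable_pct_current = if (cur > 0) 100 * stable / cur else NA_real_,
    shrink_pct_current = if (cur > 0) 100 * shrink / cur else NA_real_,
    expand_pct_future = if (fut > 0) 100 * expand / fut else NA_real_)
}

#' Class-transition area matrix
#'
#' 4x4 matrix of area (km^2) moving from each current class to each
#' future class; row sums equal current per-class areas and column sums
#' future per-class areas.
#'
#' @param current,future [classify] results on one geometry with equal
#'   breaks
#' @return 4x4 matrix, rows = current class, cols = future class
#' @export
class_transition <- function(current, future) {
  if (!same_geometry(current$classes, future$classes) ||
      !isTRUE(all.equal(current$breaks, future$breaks))) {
    stop("transition requires identical geometry and class breaks")
  }
  am <- cell_area_matrix(current$classes)
  vc <- current$classes$values
  vf <- future$classes$values
  M <- matrix(0, 4, 4, dimnames = list(names(CLASS_LEVELS), names(CLASS_LEVELS)))
  ok <- !is.na(vc)
  for (i in 0:3) for (j in 0:3) {
    M[i + 1, j + 1] <- sum(am[ok & vc == i & vf == j])
  }
  M
}

#' Centroid of a suitability class
#'
#' Area-weighted mean of cell-center longitude and latitude over the
#' cells of the target class.
#'
#' @param classified a [classify] result
#' @param target_class class code (default 3, most suitable)
#' @return named vector `longitude`, `latitude`
#' @export
class_centroid <- function(classified, target_class = 3) {
  g <- classified$classes
  idx <- which(!is.na(g$values) & g$values == target_class)
  if (!length(idx)) stop("target class is empty")
  rc <- cbind(row = (idx - 1L) %% g$n_rows + 1L, col = (idx - 1L) %/% g$n_rows + 1L)
  ctr <- cell_center(g, rc[, "row"], rc[, "col"])
  w <- cell_areas(g)[rc[, "row"]]
  c(longitude = sum(w * ctr[, "longitude"]) / sum(w),
    latitude = sum(w * ctr[, "latitude"]) / sum(w))
}

#' Great-circle displacement
#'
#' Haversine distance (R = 6371.0088 km), initial bearing from north
#' clockwise in `[0, 360)`, and the nearest of 8 compass sectors (45
#' degrees centered on each direction). Identical points have zero
#' distance and compass `"none"`.
#'
#' @param p1,p2 `c(longitude, latitude)` in degrees
#' @return list `distance_km`, `bearing_deg`, `compass`
#' @export
displacement <- function(p1, p2) {
  rad <- pi / 180
  lon1 <- p1[[1]] * rad; lat1 <- p1[[2]] * rad
  lon2 <- p2[[1]] * rad; lat2 <- p2[[2]] * rad
  dlat <- lat2 - lat1; dlon <- lon2 - lon1
  a <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  d <- 2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
  if (d < 1e-12) {
    return(list(distance_km = 0, bearing_deg = NA_real_, compass = "none"))
  }
  y <- sin(dlon) * cos(lat2)
  x <- cos(lat1) * sin(lat2) - sin(lat1) * cos(lat2) * cos(dlon)
  brg <- (atan2(y, x) / rad) %% 360
  sector <- COMPASS_8[(floor((brg + 22.5) / 45) %% 8) + 1]
  list(distance_km = d, bearing_deg = brg, compass = sector)
}

#' Centroid trajectory across scenarios
#'
#' Ordered centroids of the target class for a sequence of classified
#' maps, with per-segment displacement (distance, initial bearing, compass
#' sector) and the overall first-to-last displacement.
#'
#' @param maps named list of [classify] results in scenario order
#' @param target_class class code (default 3, most suitable)
#' @return object of class `centroid_track`: `points` (data frame
#'   `scenario`, `longitude`, `latitude`), `segments` (data frame `from`,
#'   `to`, `distance_km`, `bearing_deg`, `compass`), `overall`
#' @export
centroid_track <- function(maps, target_class = 3) {
  stopifnot(length(maps) >= 1)
  labels <- names(maps)
  if (is.null(labels)) labels <- paste0("scenario", seq_along(maps))
  pts <- lapply(seq_along(maps), function(i) {
    tryCatch(class_centroid(maps[[i]], target_class),
             error = function(e) stop("empty target class in scenario '", labels[i], "'"))
  })
  points <- data.frame(scenario = labels,
                       longitude = vapply(pts, `[[`, numeric(1), "longitude"),
                       latitude = vapply(pts, `[[`, numeric(1), "latitude"))
  segments <- NULL
  if (length(pts) > 1) {
    segs <- lapply(seq_len(length(pts) - 1), function(i) {
      d <- displacement(pts[[i]], pts[[i + 1]])
      data.frame(from = labels[i], to = labels[i + 1],
                 distance_km = d$distance_km, bearing_deg = d$bearing_deg,
                 compass = d$compass, stringsAsFactors = FALSE)
    })
    segments <- do.call(rbind, segs)
  }
  overall <- if (length(pts) > 1) displacement(pts[[1]], pts[[length(pts)]]) else NULL
  structure(list(points = points, segments = segments, overall = overall),
            class = "centroid_track")
}

#' @export
print.centroid_track <- function(x, ...) {
  cat("centroid_track:\n")
  print(x$points, row.names = FALSE)
  if (!is.null(x$segments)) print(x$segments, row.names = FALSE)
  invisible(x)
}
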