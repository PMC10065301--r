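# From continuous suitability to the four-class zoning and its
# spherical-geometry area accounting.

CLASS_LEVELS <- c(unsuitable = 0, poor = 1, moderate = 2, most = 3)

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every distinct observed score as a candidate threshold `t`
#' (background treated as pseudo-absence): sensitivity is the fraction of
#' presences with score >= t, specificity the fraction of background with
#' score < t. Returns the candidate maximizing their sum; ties go to the
#' smallest threshold. Constant scores degenerate to that constant, with a
#' warning.
#'
#' @param scores_presence,scores_background numeric score vectors
#' @return the threshold P
#' @export
max_sss_threshold <- function(scores_presence, scores_background) {
  stopifnot(length(scores_presence) >= 1, length(scores_background) >= 1)
  cand <- sort(unique(c(scores_presence, scores_background)))
  if (length(cand) == 1) {
    warning("all scores identical; returning the constant as threshold")
    return(cand)
  }
  sens <- vapply(cand, function(t) mean(scores_presence >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores_background < t), numeric(1))
  ss <- sens + spec
  cand[which(ss >= max(ss) - 1e-12)[1]]
}

#' Classify a suitability surface
#'
#' Four classes from the threshold `P` and the fixed breaks: below `P` is
#' unsuitable (0); otherwise `[P, 0.33)` poor (1), `[0.33, 0.66)` moderate
#' (2), `[0.66, 1]` most suitable (3). If `P >= breaks[1]` the poor class
#' is structurally empty (a message is emitted). Nodata is preserved.
#'
#' @param suitability a [raster_grid] with values in `[0, 1]`
#' @param P threshold in (0, 1)
#' @param breaks the two upper class breaks, strictly increasing in (0,1)
#' @return an object of class `classified_map`
#' @export
classify <- function(suitability, P, breaks = c(0.33, 0.66)) {
  stopifnot(inherits(suitability, "raster_grid"), P > 0, P < 1,
            length(breaks) == 2, breaks[1] < breaks[2])
  if (P >= breaks[1]) message("threshold P >= ", breaks[1], ": the poor class is structurally empty")
  v <- suitability$values
  cls <- ifelse(is.na(v), NA_real_,
         ifelse(v < P, 0, ifelse(v < breaks[1], 1, ifelse(v < breaks[2], 2, 3))))
  structure(
    list(classes = raster_grid(cls, suitability$x_ll, suitability$y_ll,
                               suitability$cell_size, suitability$nodata_value),
         threshold_P = P, breaks = breaks),
    class = "classified_map"
  )
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- table(factor(x$classes$values, levels = 0:3,
                      labels = names(CLASS_LEVELS)))
  cat(sprintf("classified_map (P = %.4g, breaks %.2f/%.2f): %s\n",
              x$threshold_P, x$breaks[1], x$breaks[2],
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# Per-class areas in km^2 from a classified map.
class_area_km2 <- function(classified) {
  am <- cell_area_matrix(classified$classes)
  v <- classified$classes$values
  vapply(CLASS_LEVELS, function(k) sum(am[!is.na(v) & v == k]), numeric(1))
}

#' Area report for a classified map
#'
#' Per-class areas in 10^4 km^2 (spherical cell areas), the total suitable
#' area (poor + moderate + most), each class's share of the total suitable
#' area (%), and — when a baseline report is supplied — the percent change
#' of each area versus the baseline. Printed-style values use
#' half-away-from-zero rounding to 2 decimals (trailing zero dropped).
#'
#' @param classified a [classify] result, or a precomputed report for
#'   `areas` (see `from_areas`)
#' @param baseline optional baseline `area_report` for percent changes
#' @return an object of class `area_report`: `areas` (named, 10^4 km^2,
#'   incl. `total_suitable`), `shares` (%), `changes` (% vs baseline or
#'   `NULL`)
#' @export
area_report <- function(classified, baseline = NULL) {
  a4 <- class_area_km2(classified) / 1e4
  report_from_areas(a4["poor"], a4["moderate"], a4["most"],
                    unsuitable = a4["unsuitable"], baseline = baseline)
}

#' Percent change of an area versus a baseline
#'
#' The change rule used throughout the area reports:
#' `100 * (area - baseline) / baseline`.
#'
#' @param area,baseline areas in any common unit
#' @return percent change (NA for a zero/invalid baseline)
#' @export
percent_change <- function(area, baseline) {
  if (!is.finite(baseline) || baseline == 0) return(NA_real_)
  100 * (area - baseline) / baseline
}

#' Area report from stated class areas
#'
#' Builds the same report directly from per-class areas in 10^4 km^2
#' (e.g. a published table) without a map.
#'
#' @param poor,moderate,most class areas in 10^4 km^2
#' @param unsuitable optional unsuitable-class area
#' @param baseline optional baseline `area_report`
#' @return an `area_report`
#' @export
report_from_areas <- function(poor, moderate, most, unsuitable = NA,
                              baseline = NULL) {
  total <- poor + moderate + most
  areas <- c(unsuitable = unname(unsuitable), poor = unname(poor),
             moderate = unname(moderate), most = unname(most),
             total_suitable = unname(total))
  shares <- 100 * c(poor = unname(poor), moderate = unname(moderate),
                    most = unname(most)) / total
  changes <- NULL
  if (!is.null(baseline)) {
    keys <- c("poor", "moderate", "most", "total_suitable")
    changes <- vapply(keys, function(k) {
      percent_change(areas[[k]], baseline$areas[[k]])
    }, numeric(1))
  }
  structure(list(areas = areas, shares = shares, changes = changes,
                 rounding = "half-away-from-zero, 2 decimals"),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("area_report (10^4 km^2):\n")
  for (k in c("most", "moderate", "poor", "total_suitable")) {
    cat(sprintf("  %-15s %8s", k, format_percent(x$areas[[k]])))
    if (k != "total_suitable") cat(sprintf("  share %s%%", format_percent(x$shares[[k]])))
    if (!is.null(x$changes) && is.finite(x$changes[[k]])) {
      cat(sprintf("  change %s%%", format_percent(x$changes[[k]])))
    }
    cat("\n")
  }
  invisible(x)
}
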