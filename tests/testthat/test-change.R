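# Overlays, transitions, centroids and spherical displacement.

classified_from <- function(vals, P = 0.25, x_ll = 0, y_ll = 0, cs = 1) {
  classify(raster_grid(vals, x_ll, y_ll, cs), P)
}

test_that("binary mask conserves the suitable classes", {
  cm <- classified_from(matrix(c(0.1, 0.3, 0.5, 0.9), 1, 4), P = 0.25)
  m <- binary_suitable(cm)
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(sum(m), sum(cm$classes$values >= 1))
})

test_that("overlay obeys the conservation identities and brute force", {
  cur <- classified_from(matrix(c(0.1, 0.3, 0.5, 0.9), 1, 4))
  # future = current: all suitable cells stable
  ov <- overlay_change(cur, cur)
  expect_equal(sum(ov$classes == 1), 3)
  expect_equal(sum(ov$classes %in% c(2, 3)), 0)
  # disjoint masks: no stable cells
  fut <- classified_from(matrix(c(0.9, 0.1, 0.1, 0.1), 1, 4))
  ov2 <- overlay_change(cur, fut)
  expect_equal(sum(ov2$classes == 1), 0)
  # random 30x30 masks: counts equal per-cell truth-table evaluation
  set.seed(77)
  g <- raster_grid(matrix(runif(900), 30, 30), 0, 0, 0.1)
  g2 <- raster_grid(matrix(runif(900), 30, 30), 0, 0, 0.1)
  c1 <- classify(g, 0.5); c2 <- classify(g2, 0.5)
  ov3 <- overlay_change(c1, c2)
  a <- g$values >= 0.5; b <- g2$values >= 0.5
  expect_equal(sum(ov3$classes == 1), sum(a & b))
  expect_equal(sum(ov3$classes == 2), sum(!a & b))
  expect_equal(sum(ov3$classes == 3), sum(a & !b))
  expect_equal(sum(ov3$classes == 0), sum(!a & !b))
  # conservation: stable + shrink = current, stable + expand = future
  expect_equal(sum(ov3$classes %in% c(1, 3)), sum(a))
  expect_equal(sum(ov3$classes %in% c(1, 2)), sum(b))
  # geometry mismatch
  g3 <- raster_grid(matrix(runif(100), 10, 10), 0, 0, 0.1)
  expect_error(overlay_change(c1, classify(g3, 0.5)), "geometry")
})

test_that("change proportions use the named denominators", {
  # 4 equal-area cells (one latitude row): current {a,b,c}, future {b,c,d}
  cur <- classified_from(matrix(c(0.5, 0.5, 0.5, 0.1), 1, 4), P = 0.25)
  fut <- classified_from(matrix(c(0.1, 0.5, 0.5, 0.5), 1, 4), P = 0.25)
  pr <- change_proportions(overlay_change(cur, fut))
  expect_equal(unname(pr["stable_pct_current"]), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(unname(pr["shrink_pct_current"]), 100 * 1 / 3, tolerance = 1e-12)
  expect_equal(unname(pr["expand_pct_future"]), 100 * 1 / 3, tolerance = 1e-12)
  # identity: 100% stable, stable% + shrink% = 100
  pr2 <- change_proportions(overlay_change(cur, cur))
  expect_equal(unname(pr2), c(100, 0, 0))
  expect_equal(sum(pr[c("stable_pct_current", "shrink_pct_current")]), 100)
})

test_that("transition matrices tally per-cell moves with exact marginals", {
  cur <- classified_from(matrix(c(0.1, 0.3, 0.5, 0.9, 0.7, 0.2, 0.4, 0.05, 0.5), 3, 3))
  # identical maps: diagonal
  M0 <- class_transition(cur, cur)
  expect_equal(M0, diag(diag(M0)), ignore_attr = TRUE)
  fut <- classified_from(matrix(c(0.9, 0.1, 0.5, 0.2, 0.7, 0.7, 0.4, 0.5, 0.05), 3, 3))
  M <- class_transition(cur, fut)
  am <- sdmax:::cell_area_matrix(cur$classes)
  # brute-force per-cell tally
  B <- matrix(0, 4, 4)
  for (i in 1:3) for (j in 1:3) {
    B[cur$classes$values[i, j] + 1, fut$classes$values[i, j] + 1] <-
      B[cur$classes$values[i, j] + 1, fut$classes$values[i, j] + 1] + am[i, j]
  }
  expect_equal(unname(M), B)
  # marginals equal the two maps' per-class areas
  expect_equal(unname(rowSums(M)), unname(sdmax:::class_area_km2(cur)))
  expect_equal(unname(colSums(M)), unname(sdmax:::class_area_km2(fut)))
})

test_that("class centroids are area-weighted and ignore other classes", {
  # single most-suitable cell: its center
  v <- matrix(0.1, 3, 3); v[2, 3] <- 0.9
  cm <- classified_from(v, P = 0.25, x_ll = 10, y_ll = 40, cs = 0.5)
  ctr <- class_centroid(cm, 3)
  expect_equal(unname(ctr), unname(cell_center(cm$classes, 2, 3)[1, ]))
  # symmetric pattern about a meridian: centroid longitude on the meridian
  v2 <- matrix(0.1, 3, 5); v2[2, c(1, 5)] <- 0.9
  cm2 <- classified_from(v2, P = 0.25, x_ll = 10, y_ll = 40, cs = 0.5)
  expect_equal(unname(class_centroid(cm2, 3)["longitude"]), 10 + 2.5 * 0.5)
  # 5 cells in one row (equal areas): plain mean of centers
  v3 <- matrix(0.1, 1, 7); v3[1, c(1, 2, 3, 5, 7)] <- 0.9
  cm3 <- classified_from(v3, P = 0.25, x_ll = 0, y_ll = 0, cs = 1)
  ctrs <- cell_center(cm3$classes, rep(1, 5), c(1, 2, 3, 5, 7))
  expect_equal(unname(class_centroid(cm3, 3)["longitude"]),
               mean(ctrs[, "longitude"]))
  # relabeling other classes leaves the centroid unchanged
  v4 <- v3; v4[1, 4] <- 0.5   # moderate instead of unsuitable
  cm4 <- classified_from(v4, P = 0.25, x_ll = 0, y_ll = 0, cs = 1)
  expect_equal(class_centroid(cm4, 3), class_centroid(cm3, 3))
  expect_error(class_centroid(cm3, 2), "empty")
})

test_that("displacement matches closed forms and the geosphere oracle", {
  # identical points
  d0 <- displacement(c(105.9, 26.68), c(105.9, 26.68))
  expect_equal(d0$distance_km, 0)
  expect_equal(d0$compass, "none")
  # due north by one degree: bearing 0, ~111.2 km
  d1 <- displacement(c(105.9, 26.68), c(105.9, 27.68))
  expect_equal(d1$bearing_deg, 0)
  expect_equal(d1$compass, "N")
  expect_equal(d1$distance_km, 111.2, tolerance = 1e-4)
  expect_equal(d1$distance_km, 6371.0088 * pi / 180, tolerance = 1e-12)
  # the published current -> 2050s SSP1-2.6 move is to the northeast
  d2 <- displacement(c(105.9, 26.68), c(106.22, 27.23))
  expect_equal(d2$compass, "NE")
  # independent oracle on random pairs
  skip_if_not_installed("geosphere")
  set.seed(13)
  for (i in 1:20) {
    p1 <- c(runif(1, -170, 170), runif(1, -80, 80))
    p2 <- c(runif(1, -170, 170), runif(1, -80, 80))
    d <- displacement(p1, p2)
    expect_equal(d$distance_km,
                 geosphere::distHaversine(p1, p2, r = 6371.0088), tolerance = 1e-9)
    expect_equal(d$bearing_deg,
                 geosphere::bearing(p1, p2, a = 6371.0088, f = 0) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("haversine distance is symmetric and satisfies the triangle inequality", {
  set.seed(29)
  for (i in 1:20) {
    p <- lapply(1:3, function(j) c(runif(1, -179, 179), runif(1, -89, 89)))
    dab <- displacement(p[[1]], p[[2]])$distance_km
    dba <- displacement(p[[2]], p[[1]])$distance_km
    dbc <- displacement(p[[2]], p[[3]])$distance_km
    dac <- displacement(p[[1]], p[[3]])$distance_km
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("centroid tracks chain segments across scenarios", {
  v <- matrix(0.1, 3, 5); v[2, 2] <- 0.9
  m1 <- classified_from(v, P = 0.25, cs = 0.5, y_ll = 20)
  v2 <- matrix(0.1, 3, 5); v2[2, 4] <- 0.9
  m2 <- classified_from(v2, P = 0.25, cs = 0.5, y_ll = 20)
  # single map: one point, no segments
  tr1 <- centroid_track(list(current = m1))
  expect_equal(nrow(tr1$points), 1)
  expect_null(tr1$segments)
  # identical maps: all segments 0 km
  tr0 <- centroid_track(list(a = m1, b = m1, c = m1))
  expect_equal(tr0$segments$distance_km, c(0, 0))
  # eastward move
  tr <- centroid_track(list(current = m1, future = m2))
  expect_equal(tr$segments$compass, "E")
  expect_equal(tr$overall$bearing_deg, 90, tolerance = 1)
  # empty most class errors with the scenario name
  v3 <- matrix(0.1, 3, 5)
  m3 <- classified_from(v3, P = 0.25, cs = 0.5, y_ll = 20)
  expect_error(centroid_track(list(current = m1, bad = m3)), "bad")
})
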