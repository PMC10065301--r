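# Synthetic study systems: smooth correlated environmental fields with a
# known true niche, presence samples drawn from it, and perturbed "future"
# stacks, so the whole pipeline is testable end-to-end without external data.

#' Specify a synthetic truth
#'
#' Describes the generating model for a synthetic study system: linear
#' effects of each variable on the log-density scale (or a unimodal niche
#' around stated optima), target pairwise correlations between layers,
#' spatial autocorrelation length, optional deterministic spatial trends,
#' and the additive per-variable offsets that define future scenarios.
#'
#' @param true_weights named numeric vector of per-variable effects on the
#'   log-density scale (at least one nonzero)
#' @param optimum_style `"linear"` (identity response) or `"unimodal"`
#'   (negated squared deviation from `optimum`)
#' @param optimum named numeric vector of niche optima (unimodal style)
#' @param target_pairwise_r data frame with columns `var1`, `var2`, `r`
#'   giving target cross-layer Pearson correlations (|r| < 1)
#' @param smoothness spatial autocorrelation length, in cells (Gaussian
#'   kernel standard deviation)
#' @param warming_shift named numeric vector of additive offsets applied
#'   to layers when deriving a future stack
#' @param trend optional named list: per-layer `c(dx, dy)` deterministic
#'   gradient (in layer-sd units across the grid extent, west-to-east and
#'   south-to-north)
#' @return an object of class `truth_spec`
#' @export
truth_spec <- function(true_weights,
                       optimum_style = c("linear", "unimodal"),
                       optimum = NULL,
                       target_pairwise_r = NULL,
                       smoothness = 5,
                       warming_shift = numeric(0),
                       trend = NULL) {
  optimum_style <- match.arg(optimum_style)
  stopifnot(length(true_weights) >= 1, !is.null(names(true_weights)))
  if (all(true_weights == 0)) stop("at least one true weight must be nonzero")
  if (!is.null(target_pairwise_r)) {
    stopifnot(all(c("var1", "var2", "r") %in% names(target_pairwise_r)))
    if (any(abs(target_pairwise_r$r) >= 1)) {
      stop("target pairwise correlations must satisfy |r| < 1")
    }
  }
  if (optimum_style == "unimodal" && is.null(optimum)) {
    optimum <- setNames(rep(0, length(true_weights)), names(true_weights))
  }
  structure(
    list(true_weights = true_weights, optimum_style = optimum_style,
         optimum = optimum, target_pairwise_r = target_pairwise_r,
         smoothness = smoothness, warming_shift = warming_shift,
         trend = trend),
    class = "truth_spec"
  )
}

#' Default synthetic study conditions
#'
#' The desk-scale analogue of the real study system: a 100x100 grid,
#' 8 environmental layers with two built-in collinear pairs (r = 0.9,
#' exceeding the 0.85 filter threshold), one strong linear driver (env1)
#' plus two weak ones — env2, which is also env1's collinear partner, and
#' env5 — and a warming shift on the driver for future scenarios. 123
#' presences after thinning is the matching occurrence-sample size.
#'
#' @return a list with elements `n_layers`, `truth` (a [truth_spec]),
#'   `template` (a [raster_grid]), `n_presences`
#' @export
default_truth <- function() {
  w <- setNames(rep(0, 8), paste0("env", 1:8))
  w["env1"] <- 3
  w["env2"] <- 0.8
  w["env5"] <- 0.5
  corr <- data.frame(var1 = c("env1", "env3"), var2 = c("env2", "env4"),
                     r = c(0.9, 0.9))
  tmpl <- raster_grid(matrix(0, 100, 100), x_ll = 100, y_ll = 20,
                      cell_size = 0.05)
  list(
    n_layers = 8,
    truth = truth_spec(w, optimum_style = "linear",
                       target_pairwise_r = corr, smoothness = 5,
                       warming_shift = c(env1 = 1)),
    template = tmpl,
    n_presences = 123
  )
}

# Reflect an out-of-range index back into 1..n (symmetric padding).
reflect_index <- function(idx, n) {
  while (any(idx < 1 | idx > n)) {
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
  }
  idx
}

# 1-D Gaussian smoothing operator with reflection boundary, as a dense
# n x n matrix (desk-scale grids; no FFT needed).
smoothing_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (o in seq_along(k)) {
    off <- o - r - 1L
    src <- reflect_index(seq_len(n) + off, n)
    S[cbind(seq_len(n), src)] <- S[cbind(seq_len(n), src)] + k[o]
  }
  S
}

# Smooth a matrix with an isotropic Gaussian kernel, reflection boundary.
gaussian_smooth <- function(m, sigma) {
  Sr <- smoothing_operator(nrow(m), sigma)
  Sc <- smoothing_operator(ncol(m), sigma)
  Sr %*% m %*% t(Sc)
}

#' Generate a synthetic environmental stack
#'
#' Layers are Gaussian white noise smoothed to the requested spatial
#' autocorrelation length, standardized (mean 0, sd 1 over valid cells),
#' empirically orthogonalized, and then linearly mixed so the sample
#' correlations between layers match `spec$target_pairwise_r` exactly.
#' Deterministic spatial trends (`spec$trend`) are added last, so trended
#' layers deviate from their correlation targets by construction.
#'
#' @param n_layers number of layers (named `env1`, `env2`, ...)
#' @param template a [raster_grid] providing geometry and nodata mask
#' @param spec a [truth_spec]
#' @param seed integer seed; the stack is a pure function of
#'   `(n_layers, template, spec, seed)`
#' @return an [env_stack] labelled `"current"`
#' @export
make_env_stack <- function(n_layers, template, spec, seed) {
  stopifnot(n_layers >= 1)
  nm <- paste0("env", seq_len(n_layers))
  R_target <- diag(n_layers)
  dimnames(R_target) <- list(nm, nm)
  if (!is.null(spec$target_pairwise_r)) {
    for (i in seq_len(nrow(spec$target_pairwise_r))) {
      a <- spec$target_pairwise_r$var1[i]
      b <- spec$target_pairwise_r$var2[i]
      if (a %in% nm && b %in% nm) {
        R_target[a, b] <- R_target[b, a] <- spec$target_pairwise_r$r[i]
      }
    }
  }
  U <- tryCatch(chol(R_target), error = function(e) {
    stop("target correlation matrix is not positive definite")
  })
  nr <- template$n_rows; nc <- template$n_cols
  mask <- is.na(template$values)
  fields <- with_seed(seed, {
    lapply(seq_len(n_layers), function(i) {
      gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), spec$smoothness)
    })
  })
  ok <- which(!mask)
  Z <- vapply(fields, function(f) f[ok], numeric(length(ok)))
  Z <- scale(Z)                       # center + unit sd per column
  if (n_layers > 1 && length(ok) > n_layers) {
    qr_z <- qr(Z)
    Q <- qr.Q(qr_z)
    # fix signs so orientation follows the original fields
    sgn <- sign(diag(qr.R(qr_z)))
    Q <- sweep(Q, 2, ifelse(sgn == 0, 1, sgn), `*`)
    Z <- Q * sqrt(length(ok) - 1)     # exactly uncorrelated, unit sd
  }
  X <- Z %*% U
  layers <- list()
  for (i in seq_len(n_layers)) {
    v <- matrix(NA_real_, nr, nc)
    v[ok] <- X[, i]
    if (!is.null(spec$trend[[nm[i]]])) {
      g <- spec$trend[[nm[i]]]
      u_east <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) / nc - 0.5
      v_north <- ((nr - matrix(rep(seq_len(nr), nc), nr, nc) + 0.5) / nr) - 0.5
      v <- v + g[1] * u_east + g[2] * v_north
      v[mask] <- NA
    }
    layers[[nm[i]]] <- raster_grid(v, template$x_ll, template$y_ll,
                                   template$cell_size, template$nodata_value)
  }
  env_stack(layers, scenario_label = "current")
}

#' True suitability density of a synthetic system
#'
#' Computes the generating niche score `s(x) = sum_v w_v * g(v(x))` with
#' `g` the identity (linear style) or the negated squared deviation from
#' the stated optimum (unimodal style), and returns the normalized density
#' `exp(s) / Z` over non-nodata cells (weights act on the log-density
#' scale). All-zero weights give the uniform density `1/N`.
#'
#' @param stack an [env_stack]
#' @param spec a [truth_spec] whose variables are all in the stack
#' @return a [raster_grid] of cell probabilities summing to 1
#' @export
true_suitability <- function(stack, spec) {
  vars <- names(spec$true_weights)
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss)) stop("truth variables absent from stack: ", paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  s <- matrix(0, ref$n_rows, ref$n_cols)
  for (v in vars) {
    x <- stack$layers[[v]]$values
    g <- if (spec$optimum_style == "linear") x else -(x - spec$optimum[[v]])^2
    s <- s + spec$true_weights[[v]] * g
  }
  ok <- !is.na(ref$values)
  d <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  e <- exp(s[ok] - max(s[ok]))
  d[ok] <- e / sum(e)
  raster_grid(d, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata_value)
}

#' Sample presence records from a true density
#'
#' Draws `n` cells with replacement with probability proportional to the
#' density and places each record at its cell center (so thinning and
#' value extraction are exactly reproducible).
#'
#' @param truth a [raster_grid] density summing to 1 over valid cells
#' @param n number of records
#' @param seed integer seed
#' @return an unthinned [occurrence_set]
#' @export
sample_occurrences <- function(truth, n, seed) {
  stopifnot(n >= 1)
  ok <- valid_cells(truth)
  p <- truth$values[ok]
  cells <- ok[with_seed(seed, sample.int(length(ok), n, replace = TRUE, prob = p))]
  rc <- cbind(row = (cells - 1L) %% truth$n_rows + 1L,
              col = (cells - 1L) %/% truth$n_rows + 1L)
  ctr <- cell_center(truth, rc[, "row"], rc[, "col"])
  occurrence_set(ctr[, "longitude"], ctr[, "latitude"])
}

#' Sample presences to a target size after thinning
#'
#' Repeatedly draws from the density and thins to one record per cell
#' until `n_final` distinct occupied cells are available, then returns the
#' first `n_final` (mirrors compiling an occurrence dataset that is
#' cell-thinned to a fixed record count).
#'
#' @param truth density [raster_grid]
#' @param grid grid defining thinning cells (usually the same geometry)
#' @param n_final thinned record count to return
#' @param seed integer seed
#' @param max_rounds safety cap on draw rounds
#' @return a thinned [occurrence_set] with exactly `n_final` records
#' @export
sample_presences_thinned <- function(truth, grid, n_final, seed,
                                     max_rounds = 50) {
  seeds <- derive_seeds(seed, max_rounds)
  lon <- numeric(0); lat <- numeric(0)
  for (r in seq_len(max_rounds)) {
    draw <- sample_occurrences(truth, max(2L * n_final, 50L), seeds[r])
    lon <- c(lon, draw$records$longitude)
    lat <- c(lat, draw$records$latitude)
    thinned <- thin_per_cell(occurrence_set(lon, lat), grid)
    if (nrow(thinned$records) >= n_final) {
      return(occurrence_set(thinned$records$longitude[seq_len(n_final)],
                            thinned$records$latitude[seq_len(n_final)],
                            thinned = TRUE))
    }
  }
  stop("density too concentrated to yield ", n_final, " distinct occupied cells")
}

#' Derive a future scenario stack
#'
#' Shifts each layer named in `spec$warming_shift` by its additive offset,
#' optionally adding a small smooth seeded noise field; geometry and
#' nodata mask are unchanged.
#'
#' @param stack the current [env_stack]
#' @param spec a [truth_spec]
#' @param scenario_label label for the derived stack
#' @param noise_sd standard deviation of optional additive smooth noise
#' @param seed seed for the noise field (required if `noise_sd > 0`)
#' @return an [env_stack]
#' @export
make_future_stack <- function(stack, spec, scenario_label,
                              noise_sd = 0, seed = NULL) {
  shifts <- spec$warming_shift
  miss <- setdiff(names(shifts), names(stack$layers))
  if (length(miss)) stop("warming_shift names absent from stack: ", paste(miss, collapse = ", "))
  layers <- stack$layers
  noise <- NULL
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    ref <- layers[[1]]
    noise <- with_seed(seed, gaussian_smooth(
      matrix(stats::rnorm(ref$n_rows * ref$n_cols), ref$n_rows, ref$n_cols),
      spec$smoothness))
    noise <- noise / stats::sd(noise) * noise_sd
  }
  for (nm in names(shifts)) {
    g <- layers[[nm]]
    v <- g$values + shifts[[nm]]
    if (!is.null(noise)) v <- v + noise
    v[is.na(g$values)] <- NA
    layers[[nm]] <- raster_grid(v, g$x_ll, g$y_ll, g$cell_size, g$nodata_value)
  }
  env_stack(layers, scenario_label = scenario_label)
}

#' Write the toy fixture to disk
#'
#' Serializes [make_toy_fixture()] through the package's own writers:
#' layer grids and score surfaces as ESRI ASCII, occurrences as CSV.
#' Regeneration is byte-identical, so committed copies act as golden
#' files.
#'
#' @param dir output directory (created if needed)
#' @return the written paths, invisibly
#' @export
write_toy_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_toy_fixture()
  paths <- c(
    env1 = file.path(dir, "toy_env1.asc"),
    env2 = file.path(dir, "toy_env2.asc"),
    scores_current = file.path(dir, "toy_scores_current.asc"),
    scores_future = file.path(dir, "toy_scores_future.asc"),
    occurrences = file.path(dir, "toy_occurrences.csv")
  )
  write_esri_ascii(fx$stack$layers$env1, paths["env1"])
  write_esri_ascii(fx$stack$layers$env2, paths["env2"])
  write_esri_ascii(fx$scores_current, paths["scores_current"])
  write_esri_ascii(fx$scores_future, paths["scores_future"])
  write_occurrences(fx$occ, paths["occurrences"], species = "toy_species")
  invisible(paths)
}

#' A tiny fully enumerated fixture
#'
#' A 6x6, 2-layer study system with deterministic (non-random) layer
#' values, one nodata cell, 8 presence points (two sharing a cell), a
#' continuous suitability surface, and a "future" surface shifted one
#' column east. Every expected value in `$expected` is recomputed here by
#' plain enumeration loops, independent of the package's vectorized
#' operations, for use as a cross-check in tests.
#'
#' @return list with `stack`, `occ`, `scores_current`, `scores_future`,
#'   and `expected` (thinned count, maxSSS threshold, per-class cell
#'   counts and areas, overlay counts, most-class centroid)
#' @export
make_toy_fixture <- function() {
  nr <- 6L; nc <- 6L
  x_ll <- 100; y_ll <- 20; cs <- 0.5
  # layer A increases west->east, layer B increases south->north
  A <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  B <- matrix(rep(seq(1, 0, length.out = nr), nc), nr, nc)
  A[1, 1] <- NA; B[1, 1] <- NA
  stack <- env_stack(list(
    env1 = raster_grid(A, x_ll, y_ll, cs),
    env2 = raster_grid(B, x_ll, y_ll, cs)
  ), "toy-current")
  # suitability rises toward the south-east corner
  p <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (!(i == 1 && j == 1)) p[i, j] <- round((A[i, j] * 0.6 + (1 - B[i, j]) * 0.4), 4)
  }
  scores_current <- raster_grid(p, x_ll, y_ll, cs)
  # future: same surface shifted one column east, west column at 0
  pf <- cbind(rep(0, nr), p[, 1:(nc - 1)])
  pf[1, 2] <- 0   # shifted-in value came from the nodata cell
  pf[1, 1] <- NA  # nodata mask must match the current surface
  scores_future <- raster_grid(pf, x_ll, y_ll, cs)

  occ_lon <- c(101.25, 101.30, 101.25, 100.75, 100.75, 102.25, 101.75, 102.25)
  occ_lat <- c(21.75, 21.80, 22.25, 21.25, 21.75, 20.25, 20.75, 21.25)
  occ <- occurrence_set(occ_lon, occ_lat)

  # ---- expected values by plain enumeration ----
  cell_of <- function(lon, lat) {
    j <- floor((lon - x_ll) / cs) + 1
    i <- nr - floor((lat - y_ll) / cs)
    c(i, j)
  }
  keys <- apply(cbind(occ_lon, occ_lat), 1, function(z) paste(cell_of(z[1], z[2]), collapse = ","))
  thinned_count <- length(unique(keys))

  pres_cells <- unique(t(vapply(seq_along(occ_lon), function(k) cell_of(occ_lon[k], occ_lat[k]), numeric(2))))
  pres_scores <- apply(pres_cells, 1, function(rc) p[rc[1], rc[2]])
  bg_scores <- p[!is.na(p)]
  cand <- sort(unique(c(pres_scores, bg_scores)))
  best_t <- NA; best_s <- -Inf
  for (t in cand) {
    sens <- mean(pres_scores >= t)
    spc <- mean(bg_scores < t)
    if (sens + spc > best_s + 1e-12) { best_s <- sens + spc; best_t <- t }
  }

  R <- 6371.0088
  area_of_row <- function(i) {
    latN <- (y_ll + (nr - i + 1) * cs) * pi / 180
    latS <- (y_ll + (nr - i) * cs) * pi / 180
    R^2 * (cs * pi / 180) * (sin(latN) - sin(latS))
  }
  cls <- function(v, P) {
    if (is.na(v)) return(NA)
    if (v < P) 0 else if (v < 0.33) 1 else if (v < 0.66) 2 else 3
  }
  counts <- c(`0` = 0, `1` = 0, `2` = 0, `3` = 0)
  areas <- c(`0` = 0, `1` = 0, `2` = 0, `3` = 0)
  for (i in 1:nr) for (j in 1:nc) {
    k <- cls(p[i, j], best_t)
    if (!is.na(k)) {
      counts[as.character(k)] <- counts[as.character(k)] + 1
      areas[as.character(k)] <- areas[as.character(k)] + area_of_row(i)
    }
  }
  # overlay of suitable masks (class >= 1) current vs future
  ov <- c(stable = 0, expand = 0, shrink = 0, never = 0)
  for (i in 1:nr) for (j in 1:nc) {
    kc <- cls(p[i, j], best_t); kf <- cls(pf[i, j], best_t)
    if (is.na(kc) || is.na(kf)) next
    cur <- kc >= 1; fut <- kf >= 1
    lab <- if (cur && fut) "stable" else if (fut) "expand" else if (cur) "shrink" else "never"
    ov[lab] <- ov[lab] + 1
  }
  # area-weighted centroid of the most suitable class (current)
  wsum <- 0; lx <- 0; ly <- 0
  for (i in 1:nr) for (j in 1:nc) {
    k <- cls(p[i, j], best_t)
    if (!is.na(k) && k == 3) {
      a <- area_of_row(i)
      wsum <- wsum + a
      lx <- lx + a * (x_ll + (j - 0.5) * cs)
      ly <- ly + a * (y_ll + (nr - i + 0.5) * cs)
    }
  }
  list(
    stack = stack, occ = occ,
    scores_current = scores_current, scores_future = scores_future,
    expected = list(
      thinned_count = thinned_count,
      max_sss = best_t,
      class_counts = counts,
      class_areas_km2 = areas,
      overlay_counts = ov,
      centroid_most = c(longitude = lx / wsum, latitude = ly / wsum)
    )
  )
}
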