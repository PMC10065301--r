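# Shared builders for small deterministic fixtures.

# A small grid with deterministic values and an optional nodata cell.
tiny_grid <- function(nr = 4, nc = 5, x_ll = 100, y_ll = 20, cs = 0.5,
                      nodata_at = NULL) {
  m <- matrix(seq_len(nr * nc) / (nr * nc), nr, nc)
  if (!is.null(nodata_at)) m[nodata_at[1], nodata_at[2]] <- NA
  raster_grid(m, x_ll, y_ll, cs)
}

# A deterministic 2-layer stack on a 1 x n strip (equal-area cells):
# env1 increases east, env2 is an unrelated pattern.
strip_stack <- function(n = 20, x_ll = 100, y_ll = 0, cs = 0.1) {
  a <- matrix(seq(0, 1, length.out = n), 1, n)
  b <- matrix(rep(c(0.2, 0.8), length.out = n), 1, n)
  env_stack(list(env1 = raster_grid(a, x_ll, y_ll, cs),
                 env2 = raster_grid(b, x_ll, y_ll, cs)), "strip")
}

# Occurrences at the centers of the given (row, col) cells of a grid.
occ_at_cells <- function(grid, rows, cols, thinned = FALSE) {
  ctr <- cell_center(grid, rows, cols)
  occurrence_set(ctr[, "longitude"], ctr[, "latitude"], thinned = thinned)
}

# Independent L1 oracle: minimize the same maxent objective by smooth
# reformulation lambda = a - b with a, b >= 0 via L-BFGS-B (penalty
# becomes linear: sum(beta * (a + b))).
oracle_objective <- function(features, rm,
                             beta_class = sdmax:::default_beta_class) {
  Xb <- features$X_bg
  Xp <- features$X_pres
  beta <- rm * beta_class(features$features$kind, features$m) * features$s_bg
  fbar <- colMeans(Xp)
  J <- ncol(Xb)
  fn <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.numeric(Xb %*% lam)
    m <- max(eta)
    -sum(fbar * lam) + m + log(sum(exp(eta - m))) + sum(beta * (ab[1:J] + ab[J + 1:J]))
  }
  gr <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.numeric(Xb %*% lam)
    q <- exp(eta - max(eta)); q <- q / sum(q)
    g <- -fbar + as.numeric(crossprod(Xb, q))
    c(g + beta, -g + beta)
  }
  o <- stats::optim(rep(0, 2 * J), fn, gr, method = "L-BFGS-B",
                    lower = rep(0, 2 * J),
                    control = list(maxit = 2000, factr = 1e4))
  o$value
}

# Brute-force maxSSS: exhaustive scan over every distinct score.
brute_max_sss <- function(sp, sb) {
  cand <- sort(unique(c(sp, sb)))
  best_t <- cand[1]; best <- -Inf
  for (t in cand) {
    s <- mean(sp >= t) + mean(sb < t)
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# Brute-force AUC by pair counting, ties 1/2.
brute_auc <- function(sp, sb) {
  tot <- 0
  for (a in sp) for (b in sb) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sb))
}
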