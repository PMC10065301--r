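# Variable selection (Pearson + contribution) and candidate-model selection.

test_that("Pearson matrix at occurrences matches hand computation", {
  g <- raster_grid(matrix(0, 1, 5), 0, 0, 0.5)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  st <- env_stack(list(
    env1 = raster_grid(matrix(a, 1), 0, 0, 0.5),
    env2 = raster_grid(matrix(b, 1), 0, 0, 0.5),
    dup = raster_grid(matrix(a, 1), 0, 0, 0.5),
    neg = raster_grid(matrix(-a, 1), 0, 0, 0.5)
  ))
  occ <- occ_at_cells(g, rep(1, 5), 1:5)
  r <- pearson_matrix(st, occ)
  expect_equal(r["env1", "dup"], 1)
  expect_equal(r["env1", "neg"], -1)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r["env1", "env2"], hand)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("zero-variance variables at occurrences are flagged as r = 0", {
  g <- raster_grid(matrix(0, 1, 5), 0, 0, 0.5)
  st <- env_stack(list(
    env1 = raster_grid(matrix(1:5, 1), 0, 0, 0.5),
    flat = raster_grid(matrix(c(1, 1, 1, 1, 9), 1), 0, 0, 0.5)
  ))
  occ <- occ_at_cells(g, rep(1, 4), 1:4)  # flat is constant at these cells
  r <- pearson_matrix(st, occ)
  expect_equal(r["env1", "flat"], 0)
  expect_equal(attr(r, "zero_variance"), "flat")
})

test_that("the collinearity filter follows the contribution rule", {
  mk_corr <- function(vars, pairs) {
    r <- diag(length(vars)); dimnames(r) <- list(vars, vars)
    for (p in pairs) r[p[[1]], p[[2]]] <- r[p[[2]], p[[1]]] <- p[[3]]
    r
  }
  # the higher-contribution member of a collinear pair is retained
  r <- mk_corr(c("a", "b"), list(list("a", "b", 0.9)))
  sel <- collinearity_filter(c(a = 30, b = 5), r, 0.85)
  expect_equal(sel$retained, "a")
  expect_equal(sel$dropped$reason, "collinear-with-a")

  # all |r| <= threshold: identity on positive-contribution variables
  r2 <- mk_corr(c("a", "b", "c"), list(list("a", "b", 0.5)))
  sel2 <- collinearity_filter(c(a = 10, b = 10, c = 0), r2, 0.85)
  expect_setequal(sel2$retained, c("a", "b"))
  expect_equal(sel2$dropped$reason, "zero-contribution")

  # chain A-B 0.92, B-C 0.90, A-C 0.2 with A > B > C: B drops at the A-B
  # pair; C survives
  r3 <- mk_corr(c("a", "b", "c"),
                list(list("a", "b", 0.92), list("b", "c", 0.90),
                     list("a", "c", 0.2)))
  sel3 <- collinearity_filter(c(a = 40, b = 30, c = 10), r3, 0.85)
  expect_setequal(sel3$retained, c("a", "c"))
  expect_equal(sel3$dropped$variable, "b")
})

test_that("the filter never retains a pair above threshold and ignores input order", {
  set.seed(99)
  for (i in 1:200) {
    v <- 4 + (i %% 4)
    vars <- letters[1:v]
    A <- matrix(rnorm(20 * v), 20, v)
    r <- cor(A); dimnames(r) <- list(vars, vars)
    # force at least one strong pair
    r[1, 2] <- r[2, 1] <- runif(1, 0.86, 0.99)
    contribs <- setNames(round(runif(v, 0, 50), 1), vars)
    sel <- collinearity_filter(contribs, r, 0.85)
    if (length(sel$retained) >= 2) {
      pr <- t(combn(sel$retained, 2))
      expect_true(all(abs(r[pr]) <= 0.85))
    }
    expect_setequal(c(sel$retained, sel$dropped$variable), vars)
    # permuting the input listing changes nothing
    perm <- sample(vars)
    sel_p <- collinearity_filter(contribs[perm], r[perm, perm], 0.85)
    expect_setequal(sel_p$retained, sel$retained)
  }
})

test_that("the candidate grid is a deduplicated stable cross product", {
  g <- candidate_grid(c(0.5, 1), c("L", "LQ"))
  expect_equal(nrow(g), 4)
  expect_equal(g$fc, c("L", "L", "LQ", "LQ"))  # fc-major, rm-minor
  # the published-style token list with duplicates collapses to unique set
  toks <- c("L", "Q", "P", "T", "H", "LQ", "QPT", "QPT", "QTH", "QTH")
  expect_warning(g2 <- candidate_grid(1, toks), "duplicate")
  expect_equal(nrow(g2), 8)
  # 40 rm values x 29 combinations -> the 1160-candidate design
  expect_equal(nrow(candidate_grid(default_rm_grid(),
                                   all_feature_combinations()[1:29])), 1160)
  expect_length(all_feature_combinations(), 31)
})

test_that("candidate ranking matches independent AICc recomputation", {
  st <- strip_stack(30)
  occ <- occ_at_cells(st$layers[[1]], rep(1, 8),
                      c(16, 18, 20, 22, 24, 26, 28, 30), thinned = TRUE)
  bg <- seq_len(30)
  grid <- candidate_grid(c(1), c("L", "LQ", "LQT"))
  res <- run_candidates(grid, st, occ, bg)
  expect_equal(min(res$delta_aicc[res$valid]), 0)
  # independent recomputation: refit each candidate and apply the formula
  for (i in seq_len(nrow(res))) {
    fit <- maxent_fit(build_features(st, occ, bg, res$fc[i]), rm = res$rm[i])
    pred <- maxent_predict(fit, st, "raw")
    p_hat <- pred$values[1, ] / sum(pred$values[1, ])
    cells <- sdmax:::occ_cell_indices(st$layers[[1]], occ)
    ll <- sum(log(p_hat[cells]))  # 1-row grid: linear index = column
    k <- sum(abs(fit$lambdas) > 1e-8)
    expect_equal(res$loglik[i], ll, tolerance = 1e-8)
    if (res$valid[i]) {
      expect_equal(res$aicc[i], 2 * k - 2 * ll + 2 * k * (k + 1) / (8 - k - 1),
                   tolerance = 1e-8)
    }
  }
  # a single-candidate grid selects that candidate
  one <- run_candidates(candidate_grid(1, "L"), st, occ, bg)
  expect_equal(select_best(one)$fc, "L")
})

test_that("select_best applies the tie-break ladder and ignores row order", {
  res <- data.frame(
    fc = c("LQ", "L", "LQH", "L"), rm = c(1, 0.5, 1, 1),
    k = c(5, 3, 3, 3), loglik = 0,
    aicc = c(100, 100, 100, 100), valid = TRUE)
  res$delta_aicc <- 0
  best <- select_best(res)
  expect_equal(best$k, 3)
  expect_equal(best$rm, 0.5)           # smaller rm wins at equal aicc, k
  res2 <- res[c(3, 1, 4, 2), ]
  expect_equal(select_best(res2)$rm, 0.5)
  # equal aicc, k and rm: lexicographic fc
  res3 <- data.frame(fc = c("LQH", "L"), rm = 1, k = 3, loglik = 0,
                     aicc = 50, valid = TRUE, delta_aicc = 0)
  expect_equal(select_best(res3)$fc, "L")
  expect_error(select_best(data.frame(fc = "L", rm = 1, k = 1, loglik = 0,
                                      aicc = NA, valid = FALSE,
                                      delta_aicc = NA)), "no valid")
})
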