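tmpl_50 <- raster_grid(matrix(0, 50, 50), 100, 20, 0.05)

test_that("generated stacks hit target correlations and are deterministic", {
  spec <- truth_spec(c(env1 = 1), target_pairwise_r = data.frame(
    var1 = "env1", var2 = "env2", r = 0.9), smoothness = 4)
  st <- make_env_stack(2, tmpl_50, spec, seed = 11)
  ok <- sdmax:::valid_cells(st$layers$env1)
  r <- cor(st$layers$env1$values[ok], st$layers$env2$values[ok])
  expect_equal(r, 0.9, tolerance = 0.05)
  st2 <- make_env_stack(2, tmpl_50, spec, seed = 11)
  expect_identical(st, st2)
  st3 <- make_env_stack(2, tmpl_50, spec, seed = 12)
  expect_false(identical(st$layers$env1$values, st3$layers$env1$values))
  # layers standardized over valid cells
  expect_equal(mean(st$layers$env2$values[ok]), 0, tolerance = 1e-10)
  expect_equal(sd(st$layers$env2$values[ok]), 1, tolerance = 1e-10)
})

test_that("impossible correlation targets are rejected", {
  expect_error(truth_spec(c(env1 = 1), target_pairwise_r = data.frame(
    var1 = "env1", var2 = "env2", r = -1.5)), "|r| < 1", fixed = TRUE)
  # a valid-entry but non-PSD matrix
  bad <- data.frame(var1 = c("env1", "env2", "env1"),
                    var2 = c("env2", "env3", "env3"),
                    r = c(0.9, 0.9, -0.9))
  spec <- truth_spec(c(env1 = 1), target_pairwise_r = bad)
  expect_error(make_env_stack(3, tmpl_50, spec, seed = 1), "positive definite")
})

test_that("true suitability follows the stated niche", {
  spec <- truth_spec(c(env1 = 2), smoothness = 3)
  st <- make_env_stack(2, tmpl_50, spec, seed = 5)
  ok <- sdmax:::valid_cells(st$layers$env1)

  # all-zero weights give the uniform density (constructed directly since
  # truth_spec itself requires a nonzero weight for generation)
  null_spec <- list(true_weights = c(env1 = 0), optimum_style = "linear")
  d0 <- true_suitability(st, null_spec)
  expect_equal(d0$values[ok], rep(1 / length(ok), length(ok)))
  expect_equal(sum(d0$values[ok]), 1)

  # single positive linear weight: density strictly increasing in the layer
  d <- true_suitability(st, spec)
  o <- order(st$layers$env1$values[ok])
  expect_true(all(diff(d$values[ok][o]) > 0))

  # unimodal: argmax at the cell nearest the optimum, by exhaustive scan
  spec_u <- truth_spec(c(env1 = 3), "unimodal", optimum = c(env1 = 0.4),
                       smoothness = 3)
  du <- true_suitability(st, spec_u)
  expect_equal(which.max(du$values[ok]),
               which.min((st$layers$env1$values[ok] - 0.4)^2))
})

test_that("presence sampling is measurable against the truth", {
  g <- raster_grid(matrix(0, 10, 10), 0, 0, 1)
  st <- env_stack(list(env1 = raster_grid(matrix(rnorm(100), 10, 10), 0, 0, 1)))
  # zero-density cells are never sampled
  d <- matrix(0, 10, 10); d[, 6:10] <- 1 / 50
  dg <- raster_grid(d, 0, 0, 1)
  occ <- sample_occurrences(dg, 500, seed = 3)
  expect_true(all(occ$records$longitude > 5))
  # uniform density: per-cell counts consistent with uniform multinomial
  du <- raster_grid(matrix(1 / 100, 10, 10), 0, 0, 1)
  occ <- sample_occurrences(du, 5000, seed = 9)
  cells <- paste(floor(occ$records$longitude), floor(occ$records$latitude))
  counts <- table(factor(cells, levels = unique(paste(
    rep(0:9, each = 10), rep(0:9, 10)))))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
  # determinism
  expect_identical(sample_occurrences(du, 100, seed = 4),
                   sample_occurrences(du, 100, seed = 4))
  # thinned sampling hits the requested count exactly
  th <- sample_presences_thinned(du, g, 37, seed = 2)
  expect_equal(nrow(th$records), 37)
  expect_true(th$thinned)
  expect_equal(nrow(thin_per_cell(th, g)$records), 37)
})

test_that("future stacks shift the named layers and the true optimum", {
  spec <- truth_spec(c(env1 = 3), "unimodal", optimum = c(env1 = 0),
                     smoothness = 3, warming_shift = c(env1 = 2))
  st <- make_env_stack(2, tmpl_50, spec, seed = 21)
  ok <- sdmax:::valid_cells(st$layers$env1)

  # zero offsets: identical stack
  spec0 <- truth_spec(c(env1 = 3), "unimodal", optimum = c(env1 = 0),
                      smoothness = 3, warming_shift = c(env1 = 0))
  fut0 <- make_future_stack(st, spec0, "future")
  expect_equal(fut0$layers$env1$values, st$layers$env1$values)

  # +2 offset raises the layer mean by exactly 2, mask unchanged
  fut <- make_future_stack(st, spec, "2050s")
  expect_equal(mean(fut$layers$env1$values[ok]),
               mean(st$layers$env1$values[ok]) + 2)
  expect_identical(is.na(fut$layers$env1$values), is.na(st$layers$env1$values))
  expect_equal(fut$layers$env2$values, st$layers$env2$values)

  # the density argmax moves to previously cooler cells (brute force)
  d_cur <- true_suitability(st, spec)
  d_fut <- true_suitability(fut, spec)
  am_cur <- which.max(d_cur$values[ok])
  am_fut <- which.max(d_fut$values[ok])
  expect_false(am_cur == am_fut)
  expect_equal(am_fut, which.min((st$layers$env1$values[ok] + 2)^2))
  expect_lt(st$layers$env1$values[ok][am_fut], st$layers$env1$values[ok][am_cur])

  # perturbation commutes with layer order
  st_swap <- env_stack(st$layers[c("env2", "env1")], st$scenario_label)
  fut_swap <- make_future_stack(st_swap, spec, "2050s")
  expect_equal(fut_swap$layers$env1$values, fut$layers$env1$values)
})

test_that("the toy fixture is self-consistent and on valid cells", {
  fx <- make_toy_fixture()
  expect_identical(fx, make_toy_fixture())  # regeneration is exact
  ref <- fx$stack$layers[[1]]
  cells <- sdmax:::occ_cell_indices(ref, fx$occ)
  expect_false(anyNA(ref$values[cells]))
  th <- thin_per_cell(fx$occ, ref)
  expect_equal(nrow(th$records), fx$expected$thinned_count)
})

test_that("fixture files regenerate byte-identically against golden copies", {
  golden <- system.file("extdata", package = "sdmax")
  d <- withr::local_tempdir()
  paths <- write_toy_fixture(d)
  for (p in paths) {
    expect_identical(readLines(p), readLines(file.path(golden, basename(p))),
                     info = basename(p))
  }
  # the committed occurrences sit on non-nodata cells of the committed grid
  g <- read_esri_ascii(file.path(golden, "toy_env1.asc"))
  occ <- read_occurrences(file.path(golden, "toy_occurrences.csv"), g)
  expect_equal(nrow(occ$records), 8)
})
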