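# Model interrogation: permutation variable importance, jackknife gains,
# response curves, replicated train/test evaluation.

# Training gain of a fitted lambda vector on (possibly permuted) raw data.
gain_for_raw <- function(model, raw_pres, raw_bg) {
  eta_p <- linear_score(model, raw_pres)
  eta_b <- linear_score(model, raw_bg)
  mean(eta_p) - logsumexp(eta_b) + log(nrow(raw_bg))
}

#' Permutation percent contribution
#'
#' Per-variable importance measured as the drop in training gain when the
#' variable's raw values are randomly permuted jointly across presence and
#' background rows (every feature derived from it is recomputed), averaged
#' over `n_perm` seeded permutations, truncated at zero and normalized to
#' sum to 100.
#'
#' @param model a [maxent_fit] model
#' @param n_perm permutations per variable
#' @param seed integer seed
#' @return named numeric vector of percentages summing to 100
#' @export
percent_contribution <- function(model, n_perm = 5, seed = 1) {
  e <- model$expansion
  full_gain <- training_gain(model)
  vars <- e$var_names
  seeds <- derive_seeds(seed, n_perm * length(vars))
  dim(seeds) <- c(n_perm, length(vars))
  m <- e$m
  drops <- vapply(seq_along(vars), function(vi) {
    v <- vars[vi]
    pooled <- c(e$raw_pres[, v], e$raw_bg[, v])
    mean(vapply(seq_len(n_perm), function(p) {
      perm <- with_seed(seeds[p, vi], sample(pooled))
      rp <- e$raw_pres; rb <- e$raw_bg
      rp[, v] <- perm[seq_len(m)]
      rb[, v] <- perm[-seq_len(m)]
      full_gain - gain_for_raw(model, rp, rb)
    }, numeric(1)))
  }, numeric(1))
  names(drops) <- vars
  drops <- pmax(drops, 0)
  if (sum(drops) < 1e-12) {
    warning("all permutation drops are zero; returning uniform contributions")
    return(setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * drops / sum(drops)
}

#' Jackknife variable importance
#'
#' For each variable, refits the model with only that variable and with
#' all variables except it, reporting the training gains alongside the
#' full-model gain (`2V + 1` gains for `V` variables).
#'
#' @param stack an [env_stack]
#' @param occ a validated [occurrence_set]
#' @param background background cell indices
#' @param fc feature combination
#' @param rm regularization multiplier
#' @param ... further arguments to [maxent_fit]
#' @return data frame (`variable`, `gain_with_only`, `gain_without`) with
#'   attribute `full_gain`
#' @export
jackknife_gain <- function(stack, occ, background, fc, rm = 1, ...) {
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("jackknife requires at least 2 variables")
  fit_on <- function(v) {
    sub <- env_stack(stack$layers[v], stack$scenario_label)
    training_gain(maxent_fit(build_features(sub, occ, background, fc), rm = rm, ...))
  }
  res <- data.frame(
    variable = vars,
    gain_with_only = vapply(vars, function(v) fit_on(v), numeric(1)),
    gain_without = vapply(vars, function(v) fit_on(setdiff(vars, v)), numeric(1)),
    row.names = NULL
  )
  attr(res, "full_gain") <- fit_on(vars)
  res
}

#' Marginal response curve
#'
#' Sweeps one variable over its background `[min, max]` in `n_points`
#' steps with all other variables held at their background means, and
#' reports the cloglog suitability at each point. If a `threshold` is
#' supplied, also reports the suitable sub-range of values whose score
#' reaches it.
#'
#' @param model a [maxent_fit] model
#' @param variable variable name
#' @param n_points sweep resolution
#' @param threshold optional suitability threshold
#' @return list with `curve` (data frame `value`, `cloglog`) and
#'   `suitable_range` (`c(min, max)` or `NULL`)
#' @export
response_curve <- function(model, variable, n_points = 100, threshold = NULL) {
  e <- model$expansion
  if (!variable %in% e$var_names) stop("variable not in model: ", variable)
  vals <- seq(e$var_min[[variable]], e$var_max[[variable]], length.out = n_points)
  raw <- matrix(rep(e$var_mean_bg, each = n_points), n_points,
                dimnames = list(NULL, e$var_names))
  raw[, variable] <- vals
  q <- exp(linear_score(model, raw) - model$log_Z)
  score <- 1 - exp(-exp(model$entropy_H) * q)
  rng <- NULL
  if (!is.null(threshold)) {
    suit <- vals[score >= threshold]
    if (length(suit)) rng <- range(suit)
  }
  list(curve = data.frame(value = vals, cloglog = score), suitable_range = rng)
}

#' Replicated train/test evaluation
#'
#' Repeats a seeded random split `n_replicates` times: withholds
#' `floor(test_fraction * m)` presences, fits on the remainder against the
#' full background, and records training and test AUC (background as the
#' contrast class for both). Summaries are mean and sample standard
#' deviation per split.
#'
#' @param stack an [env_stack]
#' @param occ a validated [occurrence_set] (`m >= 4`)
#' @param background background cell indices
#' @param fc feature combination
#' @param rm regularization multiplier
#' @param n_replicates number of replicates
#' @param test_fraction withheld presence fraction in (0, 1)
#' @param seed master seed; per-replicate seeds are derived and distinct
#' @param ... further arguments to [maxent_fit]
#' @return list with `results` (data frame `replicate`, `seed`, `n_train`,
#'   `n_test`, `auc_train`, `auc_test`) and `summary` (means and sds)
#' @export
replicate_eval <- function(stack, occ, background, fc, rm = 1,
                           n_replicates = 10, test_fraction = 0.25,
                           seed = 1, ...) {
  stopifnot(n_replicates >= 1, test_fraction > 0, test_fraction < 1)
  m <- nrow(occ$records)
  if (m < 4) stop("at least 4 presences are required")
  n_test <- floor(test_fraction * m)
  if (n_test < 1) stop("test split is empty at this test_fraction")
  seeds <- derive_seeds(seed, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    test_idx <- with_seed(seeds[r], sample.int(m, n_test))
    tr <- occurrence_set(occ$records$longitude[-test_idx],
                         occ$records$latitude[-test_idx], thinned = occ$thinned)
    te <- occurrence_set(occ$records$longitude[test_idx],
                         occ$records$latitude[test_idx], thinned = occ$thinned)
    fit <- maxent_fit(build_features(stack, tr, background, fc), rm = rm, ...)
    ref <- stack$layers[[1]]
    sc_bg <- linear_score(fit, extract_values(stack, background))
    sc_tr <- linear_score(fit, extract_values(stack, occ_cell_indices(ref, tr)))
    sc_te <- linear_score(fit, extract_values(stack, occ_cell_indices(ref, te)))
    data.frame(replicate = r, seed = seeds[r],
               n_train = m - n_test, n_test = n_test,
               auc_train = auc(sc_tr, sc_bg), auc_test = auc(sc_te, sc_bg))
  })
  results <- do.call(rbind, rows)
  list(
    results = results,
    summary = list(
      mean_train = mean(results$auc_train), sd_train = stats::sd(results$auc_train),
      mean_test = mean(results$auc_test), sd_test = stats::sd(results$auc_test)
    )
  )
}
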