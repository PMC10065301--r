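# Two selection layers: variable selection (percent contribution +
# pairwise Pearson collinearity rule) and candidate-model selection over a
# regularization-multiplier x feature-combination grid ranked by AICc.

#' Pairwise Pearson correlations at occurrence cells
#'
#' Standard Pearson r between every pair of layers, computed on values
#' extracted at the occurrence cells. A variable with zero variance at the
#' occurrences yields undefined correlations; these are flagged (attribute
#' `zero_variance`) and treated as r = 0.
#'
#' @param stack an [env_stack]
#' @param occ a validated [occurrence_set] with at least 3 records
#' @return symmetric correlation matrix with unit diagonal
#' @export
pearson_matrix <- function(stack, occ) {
  if (nrow(occ$records) < 3) stop("at least 3 occurrences are required")
  vals <- extract_values(stack, occ_cell_indices(stack$layers[[1]], occ))
  zv <- apply(vals, 2, stats::sd) < 1e-12
  r <- suppressWarnings(stats::cor(vals))
  r[is.na(r)] <- 0
  diag(r) <- 1
  if (any(zv)) attr(r, "zero_variance") <- names(which(zv))
  r
}

#' Collinearity-aware variable filter
#'
#' Step 1 drops variables whose percent contribution is not greater than
#' zero. Step 2 scans the remaining pairs in descending |r| (ties broken
#' by lexicographic pair order); for each pair with `|r| > threshold`
#' where both members are still retained, the lower-contribution member is
#' dropped (contribution ties keep the alphabetically first variable). The
#' result never retains a pair above the threshold.
#'
#' @param contribs named numeric vector of percent contributions
#' @param corr symmetric correlation matrix over the same variables
#' @param threshold collinearity cut-off on |r|
#' @return list with `contributions`, `correlation`, `retained`, and
#'   `dropped` (data frame `variable`, `reason`)
#' @export
collinearity_filter <- function(contribs, corr, threshold = 0.85) {
  vars <- sort(names(contribs))
  stopifnot(setequal(vars, rownames(corr)))
  dropped <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  zero <- vars[contribs[vars] <= 0]
  if (length(zero)) {
    dropped <- rbind(dropped, data.frame(variable = zero, reason = "zero-contribution"))
  }
  retained <- setdiff(vars, zero)
  if (length(retained) >= 2) {
    pr <- t(utils::combn(retained, 2))
    r_abs <- abs(corr[pr])
    ord <- order(-r_abs, pr[, 1], pr[, 2])
    for (k in ord) {
      a <- pr[k, 1]; b <- pr[k, 2]
      if (r_abs[k] <= threshold) break
      if (!(a %in% retained) || !(b %in% retained)) next
      drop <- if (contribs[a] > contribs[b]) b
              else if (contribs[b] > contribs[a]) a
              else max(a, b)           # tie: keep alphabetically first
      keep <- setdiff(c(a, b), drop)
      retained <- setdiff(retained, drop)
      dropped <- rbind(dropped, data.frame(
        variable = drop, reason = paste0("collinear-with-", keep)))
    }
  }
  list(contributions = contribs, correlation = corr,
       retained = retained, dropped = dropped)
}

#' Candidate grid
#'
#' Full cross product of regularization multipliers and feature
#' combinations, in stable order (feature-combination major, rm minor).
#' Duplicate entries in either list are removed with a warning.
#'
#' @param rm_values positive regularization multipliers
#' @param fc_combos list/vector of feature combinations (e.g. `"LQH"`)
#' @return data frame with columns `fc`, `rm`
#' @export
candidate_grid <- function(rm_values, fc_combos) {
  stopifnot(length(rm_values) >= 1, length(fc_combos) >= 1, all(rm_values > 0))
  fc_norm <- vapply(fc_combos, fc_label, character(1))
  if (anyDuplicated(fc_norm) || anyDuplicated(rm_values)) {
    warning("duplicate grid entries removed")
  }
  fc_norm <- unique(unname(fc_norm))
  rm_values <- unique(rm_values)
  data.frame(fc = rep(fc_norm, each = length(rm_values)),
             rm = rep(rm_values, length(fc_norm)),
             stringsAsFactors = FALSE)
}

#' Default regularization-multiplier grid
#'
#' 40 log-spaced values spanning 0.1 to 40 (the stated count and range;
#' the exact spacing is a package choice and configurable).
#'
#' @return numeric vector of length 40
#' @export
default_rm_grid <- function() exp(seq(log(0.1), log(40), length.out = 40))

#' All non-empty feature combinations
#'
#' The 31 non-empty subsets of `{L, Q, P, T, H}` in canonical order.
#'
#' @return character vector of combination labels
#' @export
all_feature_combinations <- function() {
  combos <- unlist(lapply(1:5, function(k) {
    apply(utils::combn(FEATURE_CLASSES, k), 2, paste, collapse = "")
  }))
  combos
}

#' Fit and score every candidate
#'
#' One fit plus AICc per `(rm, fc)` candidate; `delta_aicc` is computed
#' against the minimum AICc among valid candidates (those with
#' `n > k + 1`). Candidates are fitted against a shared background.
#'
#' @param grid a [candidate_grid]
#' @param stack an [env_stack]
#' @param occ a thinned, validated [occurrence_set]
#' @param background background cell indices
#' @param ... further arguments to [maxent_fit]
#' @return data frame of candidate results (`fc`, `rm`, `k`, `loglik`,
#'   `aicc`, `delta_aicc`, `valid`), with the fitted models in attribute
#'   `models`
#' @export
run_candidates <- function(grid, stack, occ, background, ...) {
  stopifnot(nrow(grid) >= 1)
  models <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    feats <- build_features(stack, occ, background, grid$fc[i])
    fit <- maxent_fit(feats, rm = grid$rm[i], ...)
    models[[i]] <<- fit
    ic <- aicc(fit, stack, occ)
    data.frame(fc = grid$fc[i], rm = grid$rm[i], k = ic$k,
               loglik = ic$loglik, aicc = ic$aicc, valid = ic$valid,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!any(res$valid)) stop("no valid candidate (all have n <= k + 1)")
  best <- min(res$aicc[res$valid])
  res$delta_aicc <- res$aicc - best
  attr(res, "models") <- models
  res
}

#' Select the best candidate
#'
#' Minimum AICc among valid candidates; ties broken by smaller `k`, then
#' smaller `rm`, then lexicographic feature combination. Invariant to the
#' ordering of the input rows.
#'
#' @param results a [run_candidates] data frame
#' @return the selected row (with its model in attribute `model` when
#'   models were attached)
#' @export
select_best <- function(results) {
  ok <- which(results$valid)
  if (!length(ok)) stop("no valid candidate to select")
  sub <- results[ok, ]
  o <- order(sub$aicc, sub$k, sub$rm, sub$fc)
  pick <- ok[o[1]]
  out <- results[pick, ]
  models <- attr(results, "models")
  if (!is.null(models)) attr(out, "model") <- models[[pick]]
  out
}
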