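# The maximum-entropy presence/background model: a Gibbs density
# exp(lambda . f(x)) / Z over background cells, fitted by minimizing the
# L1-regularized negative mean presence log-likelihood
#   J(lambda) = -(1/m) sum_i lambda.f(x_i) + log Z(lambda)
#               + sum_j beta_j |lambda_j|
# with proximal gradient descent (soft-threshold steps, backtracking line
# search). The objective is convex, so any stationary point is global.

# Per-class base regularization as a function of presence count m:
# linear/quadratic/product interpolate {10: 1.0, 30: 0.6, 100: 0.5} and
# clamp outside; threshold 1.0; hinge 0.5. Configurable via `beta_table`.
default_beta_class <- function(kind, m) {
  lqp <- stats::approx(c(10, 30, 100), c(1.0, 0.6, 0.5), xout = m, rule = 2)$y
  ifelse(kind == "threshold", 1.0,
         ifelse(kind %in% c("forward_hinge", "reverse_hinge"), 0.5, lqp))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the maximum-entropy model
#'
#' Minimizes the L1-regularized Gibbs objective over background cells.
#' Per-feature penalties are `beta_j = rm * beta_class(m) * s_j` with
#' `s_j` the feature's background standard deviation, so the
#' regularization multiplier `rm` scales all penalties globally.
#' Convergence is declared when the relative objective change drops below
#' `tol`; hitting `max_iter` without converging is an error carrying the
#' objective trace.
#'
#' @param features a [build_features] expansion
#' @param rm regularization multiplier (> 0)
#' @param tol relative objective-change tolerance
#' @param max_iter iteration cap
#' @param beta_class function `(kind, m) -> base penalty`; defaults to the
#'   presence-count interpolation described above
#' @return an object of class `maxent_model`: feature weights `lambdas`,
#'   the normalizer `log_Z` and entropy `entropy_H` of the fitted density
#'   over background, penalties `beta`, and the objective trace
#' @export
maxent_fit <- function(features, rm = 1, tol = 1e-6, max_iter = 5000,
                       beta_class = default_beta_class) {
  stopifnot(inherits(features, "feature_expansion"), rm > 0)
  if (features$m < 1) stop("at least one presence is required")
  if (features$N < features$m) stop("background must be at least as large as the presence set")
  Xb <- features$X_bg
  Xp <- features$X_pres
  beta <- rm * beta_class(features$features$kind, features$m) * features$s_bg
  # features constant over background carry no information and are pinned at 0
  fixed <- features$s_bg < 1e-12
  fbar <- colMeans(Xp)
  J <- ncol(Xb)
  lam <- rep(0, J)
  eta_b <- rep(0, nrow(Xb))
  lse <- logsumexp(eta_b)
  f_cur <- -sum(fbar * lam) + lse
  obj_cur <- f_cur + sum(beta * abs(lam))
  trace <- obj_cur
  t_step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- exp(eta_b - lse)
    grad <- -fbar + as.numeric(crossprod(Xb, q))
    repeat {
      lam_new <- soft_threshold(lam - t_step * grad, t_step * beta)
      lam_new[fixed] <- 0
      d <- lam_new - lam
      eta_new <- eta_b + as.numeric(Xb %*% d)
      lse_new <- logsumexp(eta_new)
      f_new <- -sum(fbar * lam_new) + lse_new
      if (f_new <= f_cur + sum(grad * d) + sum(d^2) / (2 * t_step) + 1e-12 ||
          t_step < 1e-12) break
      t_step <- t_step / 2
    }
    obj_new <- f_new + sum(beta * abs(lam_new))
    rel <- abs(obj_cur - obj_new) / max(1, abs(obj_cur))
    lam <- lam_new; eta_b <- eta_new; lse <- lse_new
    f_cur <- f_new; obj_cur <- obj_new
    trace <- c(trace, obj_new)
    if (rel < tol) { converged <- TRUE; break }
    t_step <- t_step * 1.5
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "maxent_fit did not converge in %d iterations (last objective %.8g)",
      max_iter, obj_cur))
    cond$objective_trace <- trace
    stop(cond)
  }
  q <- exp(eta_b - lse)
  names(lam) <- colnames(Xb)
  structure(
    list(lambdas = lam, expansion = features, log_Z = lse,
         entropy_H = -sum(q * log(q)), rm = rm, fc = features$fc,
         beta = beta, objective = obj_cur, objective_trace = trace,
         n_iter = it),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: fc=%s rm=%g, %d/%d nonzero features, gain %.4f, H %.4f\n",
    fc_label(x$fc), x$rm, sum(abs(x$lambdas) > 1e-8), length(x$lambdas),
    training_gain(x), x$entropy_H))
  invisible(x)
}

# lambda . f for a matrix of raw variable values
linear_score <- function(model, raw) {
  as.numeric(feature_values(model$expansion, raw) %*% model$lambdas)
}

#' Predict suitability over a stack
#'
#' `raw` output is the Gibbs density `exp(lambda.f(x) - log Z)`
#' (background-normalized, sums to 1 over the training background);
#' `cloglog` is `1 - exp(-exp(H) * q(x))`, a 0-1 suitability scale that
#' equals `1 - exp(-1)` everywhere under the null (uniform) model.
#' Variables outside the training range are clamped. Nodata propagates.
#'
#' @param model a [maxent_fit] model
#' @param stack an [env_stack] containing all model variables
#' @param output `"cloglog"` (default) or `"raw"`
#' @return a [raster_grid] of predictions
#' @export
maxent_predict <- function(model, stack, output = c("cloglog", "raw")) {
  output <- match.arg(output)
  miss <- setdiff(model$expansion$var_names, names(stack$layers))
  if (length(miss)) stop("stack is missing model variable(s): ", paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  ok <- valid_cells(ref)
  raw_vals <- extract_values(stack, ok)
  q <- exp(linear_score(model, raw_vals) - model$log_Z)
  out <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  out[ok] <- if (output == "raw") q else 1 - exp(-exp(model$entropy_H) * q)
  raster_grid(out, ref$x_ll, ref$y_ll, ref$cell_size, ref$nodata_value)
}

#' Training gain
#'
#' Mean over presences of `log(q(x_i) * N)`: the average log-ratio of the
#' fitted density to the uniform background density. Zero for the null
#' model; grows as the model concentrates on presences.
#'
#' @param model a [maxent_fit] model
#' @return scalar gain
#' @export
training_gain <- function(model) {
  e <- model$expansion
  mean(e$X_pres %*% model$lambdas) - model$log_Z + log(e$N)
}

#' Rank-based AUC
#'
#' Mann-Whitney form: the probability that a random presence score
#' exceeds a random background score, ties counted 1/2.
#'
#' @param scores_presence,scores_background numeric score vectors
#' @return AUC in `[0, 1]`
#' @export
auc <- function(scores_presence, scores_background) {
  stopifnot(length(scores_presence) >= 1, length(scores_background) >= 1)
  m <- length(scores_presence)
  n <- length(scores_background)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Small-sample AIC of a fitted model
#'
#' Raw scores are renormalized to sum to 1 over all valid cells of the
#' stack; the log-likelihood is the sum of log renormalized scores at the
#' presence cells; `k` counts features with `|lambda| > 1e-8`. Undefined
#' (flagged invalid) when `n <= k + 1`.
#'
#' @param model a [maxent_fit] model
#' @param stack the [env_stack] defining the full cell universe
#' @param occ the (thinned) presence set; `n` = its record count
#' @return list with `aicc`, `k`, `loglik`, `n`, `valid`
#' @export
aicc <- function(model, stack, occ) {
  ref <- stack$layers[[1]]
  pred <- maxent_predict(model, stack, output = "raw")
  ok <- valid_cells(pred)
  p_hat <- pred$values[ok] / sum(pred$values[ok])
  cells <- occ_cell_indices(ref, occ)
  p_cell <- pred$values[cells] / sum(pred$values[ok])
  ll <- sum(log(p_cell))
  k <- sum(abs(model$lambdas) > 1e-8)
  n <- nrow(occ$records)
  if (n <= k + 1) {
    return(list(aicc = NA_real_, k = k, loglik = ll, n = n, valid = FALSE))
  }
  list(aicc = 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1),
       k = k, loglik = ll, n = n, valid = TRUE)
}
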