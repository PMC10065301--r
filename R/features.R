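# Feature expansion for the maximum-entropy model: linear, quadratic,
# product, threshold and hinge transforms of [0,1]-scaled variables.

FEATURE_CLASSES <- c("L", "Q", "P", "T", "H")

# Normalize a feature-combination token like "lqh" to c("L","Q","H") in
# canonical class order.
parse_fc <- function(fc) {
  if (length(fc) == 1 && is.character(fc)) fc <- strsplit(toupper(fc), "")[[1]]
  fc <- unique(toupper(fc))
  bad <- setdiff(fc, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (!length(fc)) stop("feature combination must be non-empty")
  FEATURE_CLASSES[FEATURE_CLASSES %in% fc]
}

fc_label <- function(fc) paste(parse_fc(fc), collapse = "")

#' Sample background cells
#'
#' All valid (non-nodata) cells when there are at most `size`, otherwise a
#' seeded uniform sample of `size` cells without replacement.
#'
#' @param grid a [raster_grid] (any layer of the study stack)
#' @param size maximum background size
#' @param seed integer seed used only when sampling is needed
#' @return integer vector of linear cell indices
#' @export
background_sample <- function(grid, size = 10000, seed = 1) {
  ok <- valid_cells(grid)
  if (length(ok) <= size) return(ok)
  sort(ok[with_seed(seed, sample.int(length(ok), size))])
}

# Scale raw variable columns to [0,1] using background min/max, clamping
# values outside the training range (projection behaviour).
scale_clamped <- function(raw, var_min, var_max) {
  out <- sweep(raw, 2, var_min[colnames(raw)], `-`)
  out <- sweep(out, 2, (var_max - var_min)[colnames(raw)], `/`)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Evaluate the design matrix for a table of feature definitions on scaled
# variable values.
design_matrix <- function(feat, scaled) {
  n <- nrow(scaled)
  X <- matrix(0, n, nrow(feat))
  for (k in seq_len(nrow(feat))) {
    v <- scaled[, feat$var1[k]]
    X[, k] <- switch(feat$kind[k],
      linear = v,
      quadratic = v^2,
      product = v * scaled[, feat$var2[k]],
      threshold = as.numeric(v > feat$knot[k]),
      forward_hinge = pmax(0, (v - feat$knot[k]) / (1 - feat$knot[k])),
      reverse_hinge = pmax(0, (feat$knot[k] - v) / feat$knot[k])
    )
  }
  colnames(X) <- feat$name
  X
}

#' Build a feature expansion
#'
#' Expands environmental variables into model features over presence and
#' background cells: `L` one scaled value per variable, `Q` its square,
#' `P` all pairwise products, `T` step indicators at `k_T` equally spaced
#' knots in (0,1), `H` forward and reverse hinges at `k_H` equally spaced
#' knots. Variables constant over the background are excluded with a
#' warning. Scaling (background min/max, clamped) is recorded so the same
#' expansion can be evaluated on projection data.
#'
#' @param stack an [env_stack]
#' @param occ a validated [occurrence_set]
#' @param background integer vector of linear background cell indices
#'   (see [background_sample]); presence cells are conventionally included
#' @param fc feature combination: subset of L, Q, P, T, H (string like
#'   `"LQH"` or character vector)
#' @param k_T,k_H knots per variable for threshold and hinge features
#' @return an object of class `feature_expansion`
#' @export
build_features <- function(stack, occ, background, fc, k_T = 10, k_H = 10) {
  fc <- parse_fc(fc)
  ref <- stack$layers[[1]]
  occ_cells <- occ_cell_indices(ref, occ)
  if (anyNA(occ_cells) || anyNA(ref$values[occ_cells])) {
    stop("all occurrence cells must be valid (inside footprint, non-nodata)")
  }
  raw_bg <- extract_values(stack, background)
  raw_pres <- extract_values(stack, occ_cells)
  var_min <- apply(raw_bg, 2, min)
  var_max <- apply(raw_bg, 2, max)
  const <- var_max - var_min < 1e-12
  if (any(const)) {
    warning("excluding constant variable(s): ", paste(names(which(const)), collapse = ", "))
  }
  keep <- names(which(!const))
  if (!length(keep)) stop("no non-constant variables available")
  raw_bg <- raw_bg[, keep, drop = FALSE]
  raw_pres <- raw_pres[, keep, drop = FALSE]
  var_min <- var_min[keep]; var_max <- var_max[keep]

  feat <- NULL
  add <- function(kind, var1, var2 = NA, knot = NA) {
    data.frame(kind = kind, var1 = var1, var2 = var2, knot = knot,
               stringsAsFactors = FALSE)
  }
  for (cl in fc) {
    feat <- rbind(feat, switch(cl,
      L = add("linear", keep),
      Q = add("quadratic", keep),
      P = if (length(keep) >= 2) {
        pr <- utils::combn(keep, 2)
        add("product", pr[1, ], pr[2, ])
      },
      T = {
        kn <- seq_len(k_T) / (k_T + 1)
        add("threshold", rep(keep, each = k_T), knot = rep(kn, length(keep)))
      },
      H = {
        kn <- seq_len(k_H) / (k_H + 1)
        rbind(
          add("forward_hinge", rep(keep, each = k_H), knot = rep(kn, length(keep))),
          add("reverse_hinge", rep(keep, each = k_H), knot = rep(kn, length(keep)))
        )
      }
    ))
  }
  if (is.null(feat) || !nrow(feat)) stop("feature combination yields no features")
  tag <- c(linear = "L", quadratic = "Q", product = "P", threshold = "T",
           forward_hinge = "H+", reverse_hinge = "H-")[feat$kind]
  feat$name <- ifelse(is.na(feat$knot),
    ifelse(is.na(feat$var2), paste0(tag, ":", feat$var1),
           paste0(tag, ":", feat$var1, ":", feat$var2)),
    paste0(tag, ":", feat$var1, "@", formatC(feat$knot, format = "g")))

  sc_bg <- scale_clamped(raw_bg, var_min, var_max)
  sc_pres <- scale_clamped(raw_pres, var_min, var_max)
  X_bg <- design_matrix(feat, sc_bg)
  X_pres <- design_matrix(feat, sc_pres)
  s_bg <- apply(X_bg, 2, stats::sd)

  structure(
    list(fc = fc, var_names = keep, var_min = var_min, var_max = var_max,
         var_mean_bg = colMeans(raw_bg),
         features = feat, X_pres = X_pres, X_bg = X_bg, s_bg = s_bg,
         raw_pres = raw_pres, raw_bg = raw_bg,
         occ_cells = occ_cells, bg_cells = background,
         m = nrow(X_pres), N = nrow(X_bg), k_T = k_T, k_H = k_H),
    class = "feature_expansion"
  )
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("feature_expansion: fc=%s, %d variables -> %d features, %d presences, %d background\n",
              fc_label(x$fc), length(x$var_names), nrow(x$features), x$m, x$N))
  invisible(x)
}

# Evaluate the expansion's design matrix on new raw variable values
# (columns = kept variables), applying training scaling with clamping.
feature_values <- function(expansion, raw) {
  design_matrix(expansion$features,
                scale_clamped(raw[, expansion$var_names, drop = FALSE],
                              expansion$var_min, expansion$var_max))
}
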