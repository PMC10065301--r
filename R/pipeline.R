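# End-to-end orchestration: fit on the current scenario, project every
# scenario, threshold, classify, area accounting, change overlays and the
# centroid trajectory, all as a pure function of (config, inputs, seed).

#' Run configuration
#'
#' @param fc feature combination for a single-candidate run, or a vector
#'   of combinations to select over
#' @param rm regularization multiplier, or a vector to select over
#' @param n_replicates replicates for train/test AUC evaluation
#' @param test_fraction withheld presence fraction
#' @param background_size background cap (all valid cells if fewer)
#' @param seed master seed for every stochastic step
#' @param class_breaks upper suitability class breaks
#' @param correlation_threshold |r| cut-off for the collinearity filter
#' @param threshold `"auto"` (max sensitivity+specificity on the current
#'   scenario, reused for futures) or a fixed numeric threshold
#' @param evaluate whether to run replicate train/test evaluation
#' @return a `run_config` list
#' @export
run_config <- function(fc = "LQ", rm = 1, n_replicates = 10,
                       test_fraction = 0.25, background_size = 10000,
                       seed = 1, class_breaks = c(0.33, 0.66),
                       correlation_threshold = 0.85,
                       threshold = "auto", evaluate = TRUE) {
  stopifnot(all(rm > 0), test_fraction > 0, test_fraction < 1,
            length(class_breaks) == 2, class_breaks[1] < class_breaks[2],
            class_breaks[1] > 0, class_breaks[2] < 1)
  structure(list(fc = fc, rm = rm, n_replicates = n_replicates,
                 test_fraction = test_fraction,
                 background_size = background_size, seed = seed,
                 class_breaks = class_breaks,
                 correlation_threshold = correlation_threshold,
                 threshold = threshold, evaluate = evaluate),
            class = "run_config")
}

# Check every stack against the current stack's geometry and layer names.
check_alignment <- function(stacks) {
  ref <- stacks[[1]]
  for (s in names(stacks)[-1]) {
    st <- stacks[[s]]
    miss <- setdiff(names(ref$layers), names(st$layers))
    if (length(miss)) {
      stop("scenario '", s, "' is missing layer(s): ", paste(miss, collapse = ", "))
    }
    for (nm in names(ref$layers)) {
      if (!same_geometry(ref$layers[[nm]], st$layers[[nm]])) {
        stop("scenario '", s, "' layer '", nm, "' does not align with the current geometry")
      }
    }
  }
  invisible(TRUE)
}

#' Run the full suitability pipeline
#'
#' Steps: validate scenario alignment, thin the presences, sample the
#' background, fit the model on the first (current) stack — selecting over
#' an (rm, fc) grid by AICc when the config lists more than one candidate
#' — project cloglog suitability for every scenario, estimate the
#' max-sensitivity-plus-specificity threshold on the current scenario
#' (reused for futures), classify, compute per-scenario area reports
#' (changes vs current), change overlays and class transitions of each
#' future vs current, and the centroid trajectory of the most suitable
#' class. A machine-readable manifest records config, seed and versions.
#'
#' @param config a [run_config]
#' @param stacks named list of [env_stack]s; the first is the current
#'   scenario and the baseline for all comparisons
#' @param occ an [occurrence_set] validated against the current stack
#' @param out_dir optional directory: writes classified/suitability grids
#'   (`.asc`), area and change tables (CSV) and `manifest.json`
#' @return a list bundle: `model`, `candidates`, `threshold_P`,
#'   `predictions`, `classified`, `area_reports`, `change_maps`,
#'   `change_proportions`, `transitions`, `centroids`, `evaluation`,
#'   `manifest`
#' @export
run_pipeline <- function(config, stacks, occ, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), length(stacks) >= 1)
  if (is.null(names(stacks)) || any(names(stacks) == "")) {
    stop("stacks must be a named list (first = current scenario)")
  }
  check_alignment(stacks)
  current <- stacks[[1]]
  ref <- current$layers[[1]]
  if (!nrow(occ$records)) stop("occurrence set is empty")
  if (!occ$thinned) occ <- thin_per_cell(occ, ref)
  background <- background_sample(ref, config$background_size, config$seed)

  candidates <- NULL
  if (length(config$fc) > 1 || length(config$rm) > 1) {
    grid <- candidate_grid(config$rm, config$fc)
    candidates <- run_candidates(grid, current, occ, background)
    best <- select_best(candidates)
    model <- attr(best, "model")
  } else {
    model <- maxent_fit(build_features(current, occ, background, config$fc),
                        rm = config$rm)
  }

  predictions <- lapply(stacks, function(s) maxent_predict(model, s, "cloglog"))

  sc_bg <- predictions[[1]]$values[background]
  sc_pres <- predictions[[1]]$values[occ_cell_indices(ref, occ)]
  P <- if (identical(config$threshold, "auto")) {
    max_sss_threshold(sc_pres, sc_bg)
  } else {
    as.numeric(config$threshold)
  }

  classified <- lapply(predictions, classify, P = P, breaks = config$class_breaks)
  reports <- list()
  reports[[names(stacks)[1]]] <- area_report(classified[[1]])
  for (s in names(stacks)[-1]) {
    reports[[s]] <- area_report(classified[[s]], baseline = reports[[1]])
  }

  change_maps <- list(); props <- list(); transitions <- list()
  for (s in names(stacks)[-1]) {
    change_maps[[s]] <- overlay_change(classified[[1]], classified[[s]])
    props[[s]] <- change_proportions(change_maps[[s]])
    transitions[[s]] <- class_transition(classified[[1]], classified[[s]])
  }
  centroids <- centroid_track(classified)

  evaluation <- NULL
  if (isTRUE(config$evaluate)) {
    evaluation <- replicate_eval(current, occ, background, fc_label(model$fc),
                                 rm = model$rm,
                                 n_replicates = config$n_replicates,
                                 test_fraction = config$test_fraction,
                                 seed = config$seed)
  }

  manifest <- list(
    config = unclass(config), seed = config$seed,
    scenarios = names(stacks), n_presences = nrow(occ$records),
    n_background = length(background), threshold_P = P,
    selected = list(fc = fc_label(model$fc), rm = model$rm),
    versions = list(
      package = as.character(utils::packageVersion("sdmax")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(stacks)) {
      write_esri_ascii(predictions[[s]], file.path(out_dir, paste0("suitability_", s, ".asc")))
      write_esri_ascii(classified[[s]]$classes, file.path(out_dir, paste0("classified_", s, ".asc")))
    }
    area_tab <- do.call(rbind, lapply(names(reports), function(s) {
      r <- reports[[s]]
      data.frame(scenario = s, t(r$areas), t(r$shares),
                 check.names = FALSE)
    }))
    utils::write.csv(area_tab, file.path(out_dir, "area_reports.csv"), row.names = FALSE)
    utils::write.csv(centroids$points, file.path(out_dir, "centroids.csv"), row.names = FALSE)
    if (!is.null(centroids$segments)) {
      utils::write.csv(centroids$segments, file.path(out_dir, "centroid_segments.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(model = model, candidates = candidates, threshold_P = P,
       predictions = predictions, classified = classified,
       area_reports = reports, change_maps = change_maps,
       change_proportions = props, transitions = transitions,
       centroids = centroids, evaluation = evaluation, manifest = manifest)
}
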