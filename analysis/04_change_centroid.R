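#!/usr/bin/env Rscript
# Step 4: range-change analytics.
#
# Reads the classified maps written by 03_project_classify.R and, for
# each future scenario against current: the stable/expand/shrink/never
# overlay with area proportions (stable and shrink relative to the
# current suitable area, expand relative to the future suitable area),
# the 4x4 class-transition area matrix, and the centroid trajectory of
# the most suitable class (per-segment haversine distance, initial
# bearing, 8-sector compass direction).
#
# Run after 03_project_classify.R; writes results/.

suppressPackageStartupMessages(library(sdmax))

run_dir <- file.path("scratch", "run")
scen <- c("current", "2050s-ssp126", "2050s-ssp245", "2050s-ssp585")
manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
P <- manifest$threshold_P

classified <- lapply(scen, function(s) {
  g <- read_esri_ascii(file.path(run_dir, paste0("suitability_", s, ".asc")))
  suppressMessages(classify(g, P))
})
names(classified) <- scen

prop_rows <- list(); trans_rows <- list()
for (s in scen[-1]) {
  ov <- overlay_change(classified$current, classified[[s]])
  pr <- change_proportions(ov)
  prop_rows[[s]] <- data.frame(scenario = s, t(round_half_away(pr, 2)))
  M <- class_transition(classified$current, classified[[s]])
  trans_rows[[s]] <- data.frame(scenario = s, from = rownames(M),
                                round(M / 1e4, 4), check.names = FALSE)
}
props <- do.call(rbind, prop_rows)
write.csv(props, "results/change_proportions.csv", row.names = FALSE)
write.csv(do.call(rbind, trans_rows), "results/transitions_1e4km2.csv",
          row.names = FALSE)
print(props, row.names = FALSE)

track <- centroid_track(classified)
write.csv(track$points, "results/centroid_points.csv", row.names = FALSE)
if (!is.null(track$segments)) {
  write.csv(track$segments, "results/centroid_segments.csv", row.names = FALSE)
}
print(track)
if (!is.null(track$overall)) {
  message(sprintf("overall first-to-last move: %.1f km, bearing %.1f deg (%s)",
                  track$overall$distance_km, track$overall$bearing_deg,
                  track$overall$compass))
}
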