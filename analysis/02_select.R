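#!/usr/bin/env Rscript
# Step 2: the two selection layers.
#
# (a) Variable selection: percent contribution of each layer from an
#     initial fit, then the pairwise-Pearson collinearity rule (drop the
#     lower-contribution member of any pair with |r| > 0.85 at the
#     occurrences).
# (b) Model selection: a regularization-multiplier x feature-combination
#     candidate grid ranked by small-sample AICc (delta AICc = 0 marks
#     the chosen candidate).
#
# Run after 01_simulate.R; reads scratch/sim, writes results/.

suppressPackageStartupMessages({library(sdmax); library(jsonlite)})

sim_dir <- file.path("scratch", "sim")
dir.create("results", showWarnings = FALSE)
seed <- 1

read_stack <- function(dir, label) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  layers <- lapply(files, read_esri_ascii)
  names(layers) <- sub("\\.asc$", "", basename(files))
  env_stack(layers, label)
}
current <- read_stack(file.path(sim_dir, "current"), "current")
occ <- thin_per_cell(
  read_occurrences(file.path(sim_dir, "occurrences.csv"),
                   current$layers[[1]]),
  current$layers[[1]])
bg <- background_sample(current$layers[[1]], 10000, seed)

message("initial lightly-regularized fit for percent contribution ...")
fit0 <- maxent_fit(build_features(current, occ, bg, "LQ"), rm = 0.05)
contribs <- percent_contribution(fit0, seed = seed)
corr <- pearson_matrix(current, occ)
sel <- collinearity_filter(contribs, corr, threshold = 0.85)
message("retained: ", paste(sel$retained, collapse = ", "))
if (nrow(sel$dropped)) {
  message("dropped: ", paste(sel$dropped$variable, "(", sel$dropped$reason, ")",
                             collapse = "; "))
}
write.csv(data.frame(variable = names(contribs),
                     contribution_pct = round(unname(contribs), 3),
                     retained = names(contribs) %in% sel$retained),
          "results/variable_selection.csv", row.names = FALSE)

retained_stack <- env_stack(current$layers[sel$retained], "current")

message("candidate grid (rm x feature combination) ...")
grid <- candidate_grid(c(0.25, 0.5, 1, 2), c("L", "LQ", "LQH"))
res <- run_candidates(grid, retained_stack, occ, bg)
res_ranked <- res[order(res$delta_aicc), ]
write.csv(res_ranked[, c("fc", "rm", "k", "loglik", "aicc", "delta_aicc")],
          "results/candidates.csv", row.names = FALSE)
best <- select_best(res)
message(sprintf("selected: fc=%s rm=%g (k=%d, AICc=%.2f)",
                best$fc, best$rm, best$k, best$aicc))
write_json(list(fc = best$fc, rm = best$rm, retained = sel$retained,
                seed = seed),
           "results/selected_model.json", auto_unbox = TRUE, digits = NA)
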