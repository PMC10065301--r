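#!/usr/bin/env Rscript
# Step 1: build the synthetic study system.
#
# Conditions mirror the real study at desk scale: a 100x100 grid of
# environmental layers (8 layers, two collinear pairs at r = 0.9, one
# strong linear driver), 123 cell-thinned presence records sampled from
# the known true niche, and three future scenarios derived by additive
# warming shifts of increasing strength on the driver (low / moderate /
# high emission analogues). Everything is written through the package's
# own ESRI ASCII / CSV writers so later steps exercise the I/O path.

suppressPackageStartupMessages(library(sdmax))

seed <- 1
sim_dir <- file.path("scratch", "sim")
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

d <- default_truth()
message("generating the current stack (", d$n_layers, " layers, 100x100) ...")
current <- make_env_stack(d$n_layers, d$template, d$truth, seed = seed)

shifts <- c(`2050s-ssp126` = 0.5, `2050s-ssp245` = 1.0, `2050s-ssp585` = 1.5)
stacks <- list(current = current)
for (nm in names(shifts)) {
  spec_s <- d$truth
  spec_s$warming_shift <- c(env1 = unname(shifts[[nm]]))
  stacks[[nm]] <- make_future_stack(current, spec_s, nm)
}

truth <- true_suitability(current, d$truth)
occ <- sample_presences_thinned(truth, d$template, d$n_presences,
                                seed = seed + 1)

for (nm in names(stacks)) {
  dir.create(file.path(sim_dir, nm), showWarnings = FALSE)
  for (ly in names(stacks[[nm]]$layers)) {
    write_esri_ascii(stacks[[nm]]$layers[[ly]],
                     file.path(sim_dir, nm, paste0(ly, ".asc")))
  }
}
write_esri_ascii(truth, file.path(sim_dir, "true_density.asc"))
write_occurrences(occ, file.path(sim_dir, "occurrences.csv"),
                  species = "synthetic_species")

ok <- !is.na(current$layers$env1$values)
r12 <- cor(current$layers$env1$values[ok], current$layers$env2$values[ok])
message(sprintf("wrote %d scenarios to %s", length(stacks), sim_dir))
message(sprintf("presences after thinning: %d", nrow(occ$records)))
message(sprintf("built-in collinearity: cor(env1, env2) = %.3f", r12))
message(sprintf("warming shifts on env1 (sd units): %s",
                paste(names(shifts), shifts, sep = "=", collapse = ", ")))
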