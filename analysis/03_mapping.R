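#!/usr/bin/env Rscript
# Stage 3 — mapping: crack-score regions over grouped material toughness
# (G = G_mat = G_ost = G_cl, 50-400 J/m^2) and grouped critical interface
# strain (1e-5 to 0.0045) for all three orientations, plus the cement-line
# stiffness variants (9.6 / 15 / 18 GPa) for the longitudinal model on the
# 0.0005-0.003 interface grid. Desk-scale 4 x 4 grids on the coarse mesh;
# aborted sweeps resume from the CSV cell cache.

suppressMessages(library(osteocrack))

cfg <- study_config(out_dir = "results/mapping",
                    orientations = c("longitudinal", "radial", "transversal"),
                    mode = "fem", mesh_level = "coarse", seed = 1)

cat("Sweeping 3 x 16 map cells + 3 x 16 stiffness cells (coarse mesh)...\n")
t0 <- Sys.time()
res <- run_mapping(cfg)
cat(sprintf("done in %.1f min\n", as.numeric(Sys.time() - t0, units = "mins")))

show_map <- function(map, label) {
  cat("\n--", label, "--\n")
  wide <- stats::xtabs(score ~ G + eps_cl, data = map)
  print(wide)
}
for (ori in names(res$maps)) show_map(res$maps[[ori]], ori)
for (E in unique(res$stiffness$E_cl))
  show_map(res$stiffness[res$stiffness$E_cl == E, ],
           sprintf("longitudinal, E_cl = %.1f GPa", E / 1e9))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  maps <- do.call(rbind, res$maps)
  ggplot2::ggsave("results/mapping/region_maps.pdf", plot_region_map(maps),
                  width = 9, height = 7)
  ggplot2::ggsave("results/mapping/stiffness_maps.pdf",
                  plot_region_map(res$stiffness), width = 9, height = 4)
  cat("\nRegion plots written to results/mapping/*.pdf\n")
}
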