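#!/usr/bin/env Rscript
# Bifurcation structure of the GAL circuit under glucose + galactose.
#
# Scans the default glucose-repressor model along glucose at three galactose
# doses, maps the bistable region of the wild-type and GAL80 open-loop
# variants over the (glucose, galactose) plane, and contrasts the wild type
# with a reduced-repressor-affinity parameterization.

suppressPackageStartupMessages(library(galswitch))
dir.create("results", showWarnings = FALSE)

p_wt <- default_params("repressor")

message("-- saddle-node thresholds along glucose --")
scans <- do.call(rbind, lapply(c(75, 150, 300), function(gal) {
  bs <- bifurcation_scan(p_wt, gal, 10^seq(1, 3.2, length.out = 14))
  message(sprintf("gal = %3d nM: %s; glu* = [%.1f, %.1f] nM", gal,
                  paste(rle(bs$regime)$values, collapse = " -> "),
                  bs$glu_low_star, bs$glu_high_star))
  data.frame(gal_nM = gal, glu_nM = bs$glu_grid, regime = bs$regime,
             glu_low_star = bs$glu_low_star, glu_high_star = bs$glu_high_star)
}))
write.csv(scans, "results/bifurcation_scans.csv", row.names = FALSE)

message("-- bistable area: wild type vs GAL80 open loop --")
glu_grid <- 10^seq(0.8, 3.1, length.out = 13)
gal_grid <- 10^seq(1.2, 2.8, length.out = 9)
maps <- lapply(c(repressor = "repressor", gal80_open_loop = "gal80_open_loop"),
               function(v) regime_map(default_params(v), glu_grid, gal_grid))
for (v in names(maps))
  message(sprintf("%-18s bistable cells: %d / %d", v,
                  maps[[v]]$bistable_area, length(glu_grid) * length(gal_grid)))
long <- do.call(rbind, lapply(names(maps), function(v) {
  m <- maps[[v]]
  data.frame(variant = v,
             glu_nM = rep(m$glu_grid, times = length(m$gal_grid)),
             gal_nM = rep(m$gal_grid, each = length(m$glu_grid)),
             regime = as.vector(m$labels))
}))
write.csv(long, "results/regime_maps.csv", row.names = FALSE)

message("-- reduced repressor affinity (K_R1, K_R4 x 1.25) --")
p_ra <- validate_params(within(unclass(p_wt),
                               { K_R1 <- K_R1 * 1.25; K_R4 <- K_R4 * 1.25 }))
bs_wt <- bifurcation_scan(p_wt, 150, 10^seq(1, 3.3, length.out = 14))
bs_ra <- bifurcation_scan(p_ra, 150, 10^seq(1, 3.3, length.out = 14))
message(sprintf("wild type        window [%.1f, %.1f] nM", bs_wt$glu_low_star,
                bs_wt$glu_high_star))
message(sprintf("reduced affinity window [%.1f, %.1f] nM (shifted upward)",
                bs_ra$glu_low_star, bs_ra$glu_high_star))
message("=> with the same decaying glucose input, the reduced-affinity model")
message("   reaches its bifurcation threshold earlier: shorter bimodal epoch")
write.csv(data.frame(model = c("wild_type", "reduced_affinity"),
                     glu_low_star = c(bs_wt$glu_low_star, bs_ra$glu_low_star),
                     glu_high_star = c(bs_wt$glu_high_star, bs_ra$glu_high_star)),
          "results/affinity_windows.csv", row.names = FALSE)
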