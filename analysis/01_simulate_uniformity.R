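#!/usr/bin/env Rscript
# Stage 1 - simulate uniformity-trial data for a Smarthouse zone.
#
# A zone is 3 lanes x 24 positions (72 carts). The default calibration puts
# the day-51 total area at a centre-of-lane mean of 71.62 thousand pixels
# with plant-to-plant sd 20.2 (CV ~ 28%) and a gentle west-east linear
# trend. A second, strongly trended dataset mimics a zone where separating
# the position trend pays around 35% in precision; a third adds six shaded
# northern lanes on the full 24-lane grid to show the south-north decline.

library(smartdesign)

out_dir <- "results/01_uniformity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

lay <- grid_layout(3, 24)

message("Default zone (calibrated day-51 total area) ...")
uni <- simulate_uniformity(make_field(lay, field_params()), seed = seed)
write_uniformity_csv(uni, file.path(out_dir, "zone_default.csv"))
s <- uniformity_summary(uni, "grid")
print(s)
message(sprintf("  whole-grid CV = %.1f%% (plant-to-plant band is 20-30%%)",
                s$cv))

message("Strongly trended zone (pooled/separated sd ratio near 137%) ...")
trendy <- simulate_uniformity(make_field(lay, field_params(pos_slope = 1.67)),
                              seed = seed + 1L)
write_uniformity_csv(trendy, file.path(out_dir, "zone_trend.csv"))
pv <- pool_vs_separate_positions(trendy)
message(sprintf("  sd separated %.1f, sd pooled %.1f, relative precision %.1f%%",
                pv$sd_separated, pv$sd_pooled, pv$relative_precision))
write.csv(data.frame(sd_separated = pv$sd_separated,
                     sd_pooled = pv$sd_pooled,
                     relative_precision = pv$relative_precision),
          file.path(out_dir, "pool_vs_separate.csv"), row.names = FALSE)

message("Full 24-lane house with 6 shaded northern lanes ...")
house <- grid_layout(24, 24, zone_bounds = split(1:24, rep(1:4, each = 6)))
hp <- field_params(zone_mean = 70, zone_sd = 14, pos_slope = 0.5,
                   lane_effects = seq(0, -4, length.out = 24),
                   shaded_lanes = 19:24, shade_penalty = 0.7)
huni <- simulate_uniformity(make_field(house, hp), seed = seed + 2L)
write_uniformity_csv(huni, file.path(out_dir, "house_shaded.csv"))
zs <- uniformity_summary(huni, "zone")
print(zs)
message("  northern zones show depressed means (shading), as in multiline houses")
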