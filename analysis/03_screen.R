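#!/usr/bin/env Rscript
# Stage 4a -- data analysis: outlier removal and screening tables.
#
# Filters the long trait table by per-cell linear quantile regressions
# (value ~ day at tau 0.05/0.95), then builds Kruskal-Wallis screening
# tables by drought treatment and by variety (alpha 0.005 for image
# traits), and validates image area against the hand measurements.

library(shootpheno)

traits <- read.csv("results/traits.csv", stringsAsFactors = FALSE)
long <- traits_to_long(traits)

filt <- suppressWarnings(quantile_outlier_filter(long, taus = c(0.05, 0.95)))
cat(sprintf("outlier filter: removed %d of %d rows (%.1f%%)\n",
            sum(filt$report$flags$removed), nrow(long),
            100 * mean(filt$report$flags$removed)))
write.csv(filt$table, "results/traits_filtered.csv", row.names = FALSE)
write.csv(filt$report$flags, "results/outlier_flags.csv", row.names = FALSE)

scr <- suppressWarnings(
  build_screening_tables(filt$table, grouping = c("treatment", "variety"),
                         alpha = 0.005))
write.csv(scr, "results/screening_image.csv", row.names = FALSE)

day14 <- scr[scr$day == 14 & scr$grouping == "treatment" & !is.na(scr$p_value), ]
cat(sprintf("day +14, treatment grouping: %d/%d trait x view cells significant at 0.005\n",
            sum(day14$significant), nrow(day14)))
day28 <- scr[scr$day == 28 & scr$grouping == "treatment" & !is.na(scr$p_value), ]
cat(sprintf("day +28 (end of recovery): %d/%d cells still significant\n",
            sum(day28$significant), nrow(day28)))

# validation against hand measurements (height vs vertical area)
hand <- read.csv("results/trial/hand_measurements.csv", stringsAsFactors = FALSE)
vert <- traits[traits$view == "vertical", ]
key <- paste(hand$plant_id, hand$day)
m <- match(paste(vert$plant_id, vert$day), key)
r <- pearson_correlation(vert$area, hand$height_mm[m])
cat(sprintf("Pearson r, vertical image area vs hand-measured height: %.2f\n", r))
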