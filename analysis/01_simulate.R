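#!/usr/bin/env Rscript
# Stage 1 -- data acquisition (simulation).
#
# Generates the demonstration drought trial: 6 varieties x 7 randomized
# plots (2 unstressed, 5 drought-treated), imaged at days -7, 0, +14 and
# +28 around a 14-day water-deficit treatment followed by a 14-day
# recovery, from vertical and horizontal camera angles. Writes the
# images, ground-truth masks and tables under results/trial/.

library(shootpheno)

cfg <- trial_config(n_varieties = 6, exclude_from_second_plot = 0,
                    days = c(-7L, 0L, 14L, 28L),
                    views = c("vertical", "horizontal"), seed = 42)
trial <- generate_trial(cfg)

dir.create("results", showWarnings = FALSE)
write_trial(trial, "results/trial")

st <- trial$truth$states
cat(sprintf("simulated %d plants (%d unstressed, %d drought-treated)\n",
            nrow(trial$plants),
            sum(trial$plants$treatment == "unstressed"),
            sum(trial$plants$treatment == "drought")))
cat(sprintf("wrote %d images and %d truth masks to results/trial/\n",
            length(trial$images), length(trial$truth$masks)))

# headline of the simulated biology: treated area falls behind during
# treatment and mostly catches up during recovery
for (d in cfg$days) {
  s <- st[st$day == d, ]
  ratio <- mean(s$true_area_mm2[s$treatment == "drought"]) /
    mean(s$true_area_mm2[s$treatment == "unstressed"])
  cat(sprintf("day %+3d: treated/unstressed mean area = %.2f\n", d, ratio))
}
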