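#!/usr/bin/env Rscript
# Stage 4b -- data analysis: embeddings.
#
# Per-timepoint PCA (by trait category) and all-13-trait t-SNE
# (perplexity 10 at this demo scale; 30 requires > 90 plants per
# timepoint), with the silhouette of the treatment partition as the
# separation score. Writes coordinates and scatter plots.

library(shootpheno)

traits <- read.csv("results/traits.csv", stringsAsFactors = FALSE)
days <- sort(unique(traits$day))
coords <- list()

for (d in days) {
  fm <- suppressMessages(feature_matrix(traits, "all13", day = d,
                                        view = "vertical"))
  if (nrow(fm) < 10) next
  ts <- tsne_embed(fm, perplexity = 10, seed = 42, max_iter = 500)
  pc <- pca_embed(fm)
  cat(sprintf("day %+3d: silhouette(treatment) tsne = %5.2f, pca = %5.2f\n",
              d, cluster_separation(ts), cluster_separation(pc)))
  meta <- attr(fm, "meta")
  coords[[as.character(d)]] <- data.frame(
    day = d, plant_id = meta$plant_id, treatment = meta$treatment,
    tsne1 = ts$coordinates[, 1], tsne2 = ts$coordinates[, 2],
    pc1 = pc$coordinates[, 1], pc2 = pc$coordinates[, 2])
}

emb <- do.call(rbind, coords)
write.csv(emb, "results/embeddings.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(emb, aes(tsne1, tsne2, colour = treatment)) +
    geom_point(size = 1.5, alpha = 0.8) +
    facet_wrap(~day, scales = "free", labeller = label_both) +
    scale_colour_manual(values = c(unstressed = "red", drought = "blue")) +
    theme_minimal() +
    labs(title = "t-SNE of 13 image-based traits, vertical view",
         colour = "treatment")
  ggsave("results/tsne_by_day.png", p, width = 8, height = 6, dpi = 120)
  cat("wrote results/tsne_by_day.png\n")
}
cat("embedding coordinates -> results/embeddings.csv\n")
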