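#!/usr/bin/env Rscript

# Step 4 — figures.
#
# Distribution plots of the gradient markers by group and structure
# (box-plus-jitter, one panel per structure) and a tile grid of
# early- versus late-stage AUC per (structure, feature).

suppressMessages({
  library(pdtexture)
  library(ggplot2)
})

fig_dir <- "results/figures"
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

clinical <- read_stable_csv("scratch/runs/cohort/clinical.csv")
features <- read_stable_csv("results/features.csv")
data <- merge(features, clinical, by = "subject_id")
data$group <- factor(data$group, levels = c("CTRL", "earlyPD", "latePD"))

markers <- c("entropy", "sumV", "sumSQR")
for (m in markers) {
  p <- ggplot(data, aes(x = group, y = .data[[m]], fill = group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, size = 0.7, alpha = 0.6) +
    facet_wrap(~structure, scales = "free_y", nrow = 1) +
    labs(title = paste(m, "by group and structure"),
         x = NULL, y = m) +
    theme_bw() + theme(legend.position = "none")
  ggsave(file.path(fig_dir, paste0(m, "_by_group.png")), p,
         width = 10, height = 3, dpi = 150)
}

# AUC grid (early vs late) over every structure and feature
pd <- data[data$group %in% c("earlyPD", "latePD"), ]
grid <- expand.grid(structure = unique(pd$structure),
                    feature = c("mean", "sd", "kurtosis", "skewness",
                                "homogeneity", "contrast", "entropy",
                                "correlation", "sumSQR", "sumA", "sumV",
                                "idm"),
                    stringsAsFactors = FALSE)
grid$auc <- mapply(function(st, f) {
  d <- pd[pd$structure == st, ]
  if (anyNA(d[[f]]) || sd(d[[f]]) == 0) return(NA_real_)
  roc_evaluate(d[[f]], d$group)$auc
}, grid$structure, grid$feature)
write_stable_csv(grid, file.path(fig_dir, "auc_grid.csv"))

p <- ggplot(grid, aes(x = feature, y = structure, fill = auc)) +
  geom_tile() +
  geom_text(aes(label = sprintf("%.2f", auc)), size = 2.7) +
  scale_fill_gradient2(midpoint = 0.5, low = "steelblue", mid = "white",
                       high = "firebrick", limits = c(0, 1)) +
  labs(title = "Early- vs late-stage discrimination (AUC)", x = NULL,
       y = NULL) +
  theme_bw() + theme(axis.text.x = element_text(angle = 45, hjust = 1))
ggsave(file.path(fig_dir, "auc_grid.png"), p, width = 8, height = 3.2,
       dpi = 150)

cat("Figures written to", fig_dir, "\n")
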