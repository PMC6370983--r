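#!/usr/bin/env Rscript
# Step 4 — report.
#
# Aggregates the search results into overall zone means, sets them beside
# the reference per-task AUCs of the original clinical cohort, and draws
# the comparison figure. The synthetic cohort is not the clinical one, so
# agreement is qualitative (similar range and zone ordering), not numeric.

suppressMessages({
  library(zonegrade)
  library(ggplot2)
})

summary <- read.csv("results/search/summary.csv", stringsAsFactors = FALSE)
ref <- reference_task_aucs()

cat("Overall mean best AUC per zone (synthetic cohort):\n")
for (z in unique(summary$zone)) {
  cat(sprintf("  %-6s %.3f (reference clinical mean: %.2f)\n", z,
              mean(summary$mean_auc[summary$zone == z]),
              mean(ref$auc[ref$zone == z])))
}

both <- rbind(
  data.frame(zone = summary$zone, task = summary$task,
             auc = summary$mean_auc, source = "synthetic (this run)"),
  data.frame(zone = ref$zone, task = ref$task, auc = ref$auc,
             source = "clinical (reference)")
)
both$task <- factor(both$task, levels = names(binary_tasks()))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
p <- ggplot(both, aes(task, auc, fill = source)) +
  geom_col(position = "dodge") +
  facet_wrap(~zone) +
  coord_cartesian(ylim = c(0.5, 1)) +
  labs(y = "mean 3-fold CV ROC AUC", x = NULL,
       title = "Best-subset KNN performance per one-vs-rest task") +
  theme_minimal(base_size = 10) +
  theme(axis.text.x = element_text(angle = 30, hjust = 1))
ggsave("results/figures/mean_auc_by_task.pdf", p, width = 8, height = 4)

cat("Figure written to results/figures/mean_auc_by_task.pdf\n")
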