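#!/usr/bin/env Rscript
# Step 2 — extract the 38-feature panel.
#
# Reads the cohort written by step 1 back from disk (PNG + records, via the
# package's image-ingestion path) and computes, per lesion, the 11 Galloway
# run-length, 14 Haralick and 13 histogram features at 128 gray levels with
# four-direction averaging. Writes results/features.csv at full precision.

suppressMessages(library(zonegrade))

cohort <- read_cohort_png("results/cohort")
cat(sprintf("Loaded %d lesions from results/cohort/\n", nrow(cohort$records)))

t0 <- proc.time()["elapsed"]
features <- cohort_features(cohort, G = 128L)
cat(sprintf("Extracted %d x %d feature table in %.1f s\n",
            nrow(features), length(feature_names()),
            proc.time()["elapsed"] - t0))

out <- features
for (nm in feature_names()) out[[nm]] <- sprintf("%.17g", out[[nm]])
write.csv(out, "results/features.csv", row.names = FALSE, quote = FALSE)

# quick look: a first-order and a texture feature by zone group
agg <- aggregate(cbind(hist_mean, haralick_contrast) ~ ifelse(zone == "PZ", "PZ", "TZ+AFS") + gg,
                 data = features, FUN = function(x) round(mean(x), 2))
names(agg)[1] <- "zone_group"
print(agg[order(agg$zone_group, agg$gg), ], row.names = FALSE)
cat("Feature table written to results/features.csv\n")
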