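#!/usr/bin/env Rscript
# Stage 2: missingness filtering, collinearity pruning, and the ten gut
# mediator indices (alpha diversity, Bray-Curtis PCoA axes, phylum and
# Gram ratios, functional-guild abundances).

library(micromediate)

cohort <- read_tsv_table("results/stages/cohort.tsv")
abund_df <- read_tsv_table("results/stages/abundance.tsv")
abund <- as.matrix(abund_df[, -1])
rownames(abund) <- abund_df$sample_id

filtered <- filter_missing(cohort)
cat(sprintf("missingness filter: %d -> %d participants, dropped vars: %s\n",
            nrow(cohort), nrow(filtered),
            paste(attr(filtered, "dropped_variables"), collapse = ", ")))

exp_cols <- grep("^exposure", names(filtered), value = TRUE)
prune <- spearman_prune(filtered[exp_cols])
cat(sprintf("collinearity pruning (|rho| > 0.85): dropped %d of %d exposures\n",
            length(prune$dropped), length(exp_cols)))
write_tsv_table(prune$log, "results/stages/spearman_prune_log.tsv")

idx <- suppressWarnings(suppressMessages(
  compute_indices(abund[filtered$participant_id, ])
))
write_tsv_table(idx, "results/stages/indices.tsv")
write_tsv_table(filtered, "results/stages/cohort_filtered.tsv")

cat(sprintf("indices for %d samples; Shannon %.2f-%.2f bits, F/B %.2f-%.2f\n",
            nrow(idx), min(idx$shannon), max(idx$shannon),
            min(idx$fb_ratio, na.rm = TRUE),
            max(idx$fb_ratio, na.rm = TRUE)))
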