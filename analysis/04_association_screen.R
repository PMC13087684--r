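#!/usr/bin/env Rscript
# Stage 4: bivariate screening of every exposure against every gut index
# and every health outcome with HC1 robust standard errors, BH-FDR within
# each dependent variable, and the dual significance criterion
# (FDR < 0.05 and adjusted R^2 > 0.005). Also: taxa correlated with the
# first ordination axis, and the prevalence-shift contrast between high-
# and low-exposure quartiles.

library(micromediate)

filtered <- read_tsv_table("results/stages/cohort_filtered.tsv")
idx <- read_tsv_table("results/stages/indices.tsv")
abund_df <- read_tsv_table("results/stages/abundance.tsv")
abund <- as.matrix(abund_df[, -1])
rownames(abund) <- abund_df$sample_id
abund <- abund[filtered$participant_id, ]

exp_cols <- grep("^exposure", names(filtered), value = TRUE)
out_cols <- grep("^outcome", names(filtered), value = TRUE)

m_screen <- screen_associations(filtered[exp_cols], idx[index_names()])
y_screen <- screen_associations(filtered[exp_cols], filtered[out_cols])
write_tsv_table(m_screen$results, "results/stages/screen_mediators.tsv")
write_tsv_table(y_screen$results, "results/stages/screen_outcomes.tsv")
write_tsv_table(as.data.frame(m_screen$signed_r2),
                "results/stages/signed_r2_matrix.tsv")

cat(sprintf("exposure-index screen: %d of %d pairs pass the dual criterion\n",
            sum(m_screen$results$significant), nrow(m_screen$results)))
cat(sprintf("exposure-outcome screen: %d of %d pairs significant\n",
            sum(y_screen$results$significant), nrow(y_screen$results)))

rel <- sweep(abund, 1, rowSums(abund), "/")
axis_cor <- axis_taxa_correlation(idx$pcoa1, rel)
write_tsv_table(axis_cor, "results/stages/pcoa1_taxa_correlations.tsv")
cat(sprintf("PCoA1-correlated taxa (FDR < 0.05, |r| > 0.2): %d\n",
            sum(axis_cor$retained)))

shift <- prevalence_shift(abund, filtered$exposure_main)
shift <- shift[order(-abs(shift$difference_pp)), ]
write_tsv_table(shift, "results/stages/prevalence_shift.tsv")
cat("largest quartile prevalence shifts (percentage points):\n")
print(utils::head(shift[, c("taxon", "difference_pp", "fdr")], 5),
      row.names = FALSE)
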