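#!/usr/bin/env Rscript
# Stage 5: formal mediation for every exposure that passed both screens.
# Continuous outcomes use the bootstrap percentile CI for ab; binary
# outcomes use the distribution-of-product CI on the mixed
# linear/logistic paths. Every pathway is classified as full, partial,
# inconsistent, or none, with the proportion mediated ab/c.

library(micromediate)

filtered <- read_tsv_table("results/stages/cohort_filtered.tsv")
idx <- read_tsv_table("results/stages/indices.tsv")
m_screen <- list(results = read_tsv_table("results/stages/screen_mediators.tsv"))
y_screen <- list(results = read_tsv_table("results/stages/screen_outcomes.tsv"))
m_screen$results$significant <- as.logical(m_screen$results$significant)
y_screen$results$significant <- as.logical(y_screen$results$significant)

triplets <- select_triplets(m_screen, y_screen)
cat(sprintf("eligible triplets (X significant for both an index and an outcome): %d\n",
            nrow(triplets)))

rows <- lapply(seq_len(nrow(triplets)), function(i) {
  tr <- triplets[i, ]
  y <- filtered[[tr$y]]
  binary <- all(stats::na.omit(y) %in% c(0, 1))
  covs <- filtered[c("age", "sex")]
  m <- if (binary) {
    mediate_binary(filtered[[tr$x]], idx[[tr$m]], y, covs, seed = 200 + i)
  } else {
    mediate_continuous(filtered[[tr$x]], idx[[tr$m]], y, covs,
                       n_boot = 2000, seed = 200 + i)
  }
  cbind(tr, as.data.frame(m))
})
res <- do.call(rbind, rows)
write_tsv_table(res, "results/stages/mediation.tsv")

cat("pathways by classification:\n")
print(table(res$classification))
sig <- res[res$classification != "none", ]
if (nrow(sig)) {
  cat("\nsignificant pathways:\n")
  print(sig[, c("x", "m", "y", "ab", "ab_ci_lo", "ab_ci_hi",
                "proportion_mediated", "classification")],
        row.names = FALSE)
}
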