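#!/usr/bin/env Rscript
# Stage 3: standardize the unevenly sampled per-city environmental
# collections. Cities with more than 14 samples are retained; cities above
# the target size are iteratively subsampled until the subset's
# alpha-diversity distribution is KS-indistinguishable from the full
# city's (p > 0.05); pathogen loads are summed per sample.

library(micromediate)

long <- read_tsv_table("results/stages/city_samples.tsv")
sets <- lapply(split(long, long$city), function(d) {
  m <- as.matrix(d[, setdiff(names(d), c("city", "sample_id"))])
  rownames(m) <- d$sample_id
  list(city = d$city[1], abundance = m)
})
names(sets) <- NULL

kept <- eligible_cities(sets)
cat(sprintf("eligibility (>14 samples): %d of %d cities retained\n",
            length(kept), length(sets)))
target <- target_size(kept)
cat(sprintf("standardization target (median retained size): %d\n", target))

std <- lapply(seq_along(kept), function(i) {
  subsample_city(kept[[i]], target, seed = 100 + i)
})
summary_tab <- do.call(rbind, lapply(std, function(s) {
  ad <- env_alpha_diversity(s)
  path_ob <- mean(apply(s$abundance, 1, pathogen_load, which = "obligate"))
  path_fa <- mean(apply(s$abundance, 1, pathogen_load,
                        which = "facultative"))
  data.frame(city = s$city, n = nrow(s$abundance),
             iterations = s$iterations, ks_p = s$ks_p,
             mean_fisher_alpha = mean(ad$fisher_alpha, na.rm = TRUE),
             mean_shannon = mean(ad$shannon),
             mean_obligate_load = path_ob,
             mean_facultative_load = path_fa)
}))
write_tsv_table(summary_tab, "results/stages/city_standardized.tsv")
print(summary_tab, row.names = FALSE)
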