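#!/usr/bin/env Rscript
# Stage 1: synthesize the study inputs.
#
# Generates (i) a participant cohort with continuous/binary exposures,
# age/sex covariates, and one continuous plus one binary health outcome
# wired to the gut community through planted coefficients; (ii) the
# genus-level count table whose composition shifts with the main exposure;
# (iii) per-city environmental sample sets of uneven size for the
# standardization stage. Ground truth goes to a JSON sidecar.

library(micromediate)

seed <- 1
n <- 600
dir.create("results/stages", showWarnings = FALSE, recursive = TRUE)

sim <- generate_cohort(n = n, seed = seed,
                       missingness = c(exposure_main = 0.05))
write_tsv_table(sim$cohort, "results/stages/cohort.tsv")
abund <- data.frame(sample_id = rownames(sim$abundance), sim$abundance,
                    check.names = FALSE)
write_tsv_table(abund, "results/stages/abundance.tsv")
jsonlite::write_json(lapply(sim$truths, unclass),
                     "results/stages/truth.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

city_sizes <- c(10, 14, 15, 30, 40, 55, 80, 120)
cities <- generate_city_samples(city_sizes, seed = seed + 1)
city_long <- do.call(rbind, lapply(cities, function(s) {
  data.frame(city = s$city, sample_id = rownames(s$abundance),
             s$abundance, check.names = FALSE)
}))
write_tsv_table(city_long, "results/stages/city_samples.tsv")

cat(sprintf("cohort: %d participants, %d taxa, %.1f%% missing on main exposure\n",
            nrow(sim$cohort), ncol(sim$abundance),
            100 * mean(is.na(sim$cohort$exposure_main))))
cat(sprintf("cities: %d sets with sizes %s\n", length(cities),
            paste(city_sizes, collapse = ", ")))
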