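test_that("truth validation names the offending field", {
  expect_error(synthetic_truth(n = 5), "n")
  expect_error(synthetic_truth(noise_sd_m = 0), "noise_sd_m")
  expect_error(synthetic_truth(a = Inf), "a")
  expect_error(synthetic_truth(outcome_type = "ordinal"))
})

test_that("triplet generation is deterministic and matches its moments", {
  tr <- synthetic_truth(n = 4000, seed = 8)
  d1 <- generate_mediation_triplet(tr)
  d2 <- generate_mediation_triplet(tr)
  expect_identical(d1, d2)                       # bit-identical per seed
  expect_lt(abs(mean(d1$X)), 3 / sqrt(nrow(d1)))
  resid_m <- d1$M - tr$a * d1$X
  expect_lt(abs(mean(resid_m)), 3 * tr$noise_sd_m / sqrt(nrow(d1)))
  expect_equal(sd(resid_m), tr$noise_sd_m, tolerance = 0.05)
  expect_true(all(d1$age >= 18 & d1$age <= 90))
  expect_true(all(d1$sex %in% 0:1))
})

test_that("fitted paths recover planted values over replicates", {
  fits <- t(vapply(1:100, function(s) {
    tr <- synthetic_truth(a = 0.5, b = 0.4, c_prime = 0.3, n = 5000,
                          seed = s)
    d <- generate_mediation_triplet(tr)
    fa <- coef(lm(M ~ X, data = d))["X"]
    fyb <- coef(lm(Y ~ X + M, data = d))
    c(a = unname(fa), b = unname(fyb["M"]), c_prime = unname(fyb["X"]))
  }, numeric(3)))
  means <- colMeans(fits)
  expect_lt(abs(means["a"] - 0.5) / 0.5, 0.05)
  expect_lt(abs(means["b"] - 0.4) / 0.4, 0.05)
  expect_lt(abs(means["c_prime"] - 0.3) / 0.3, 0.05)
})

test_that("null triplets give ab intervals covering zero ~95% of the time", {
  covered <- vapply(1:100, function(s) {
    tr <- synthetic_truth(a = 0, b = 0, c_prime = 0, n = 1000, seed = s)
    d <- generate_mediation_triplet(tr)
    m <- mediate_continuous(d$X, d$M, d$Y, n_boot = 300, seed = s)
    m$ab_ci_lo <= 0 && m$ab_ci_hi >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.89)
})

test_that("cohort generation plants taxa effects and injects missingness", {
  cfg <- community_config()
  expect_error(community_config(depth = 10), "depth")
  expect_error(community_config(effect_taxa = c(NotATaxon = 1)),
               "effect_taxa")
  expect_error(generate_cohort(n = 50, missingness = c(exposure_main = 1)),
               "missingness")

  coh <- generate_cohort(n = 200, seed = 31,
                         missingness = c(exposure_main = 0.1))
  expect_true(all(unlist(default_guilds()) %in% colnames(coh$abundance)))
  expect_gt(sum(is.na(coh$cohort$exposure_main)), 0)
  expect_identical(coh$cohort,
                   generate_cohort(n = 200, seed = 31,
                                   missingness = c(exposure_main = 0.1))$cohort)

  # a variable with 60% missingness is removed by the downstream filter
  coh2 <- generate_cohort(n = 200, seed = 32,
                          missingness = c(exposure_null1 = 0.6))
  filt <- filter_missing(coh2$cohort)
  expect_true("exposure_null1" %in% attr(filt, "dropped_variables"))
})

test_that("planted composition shifts move richness between X quartiles", {
  # positive shift on 5 taxa with X: high-X quartile richer on average
  cfg <- community_config(
    depth = 1000, concentration = 0.2,
    effect_taxa = c(Faecalibacterium = 1, Roseburia = 1, Coprococcus = 1,
                    Blautia = 1, Dorea = 1)
  )
  diffs <- vapply(1:60, function(s) {
    set.seed(s)
    X <- rnorm(120)
    counts <- micromediate:::draw_counts(cfg, X)
    rich <- rowSums(counts > 0)
    q <- quantile(X, c(0.25, 0.75))
    mean(rich[X > q[2]]) - mean(rich[X < q[1]])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.5)
  expect_gt(mean(diffs), 0)

  # no planted effect: exposure uncorrelated with Shannon across replicates
  rhos <- vapply(1:40, function(s) {
    cfg0 <- community_config(effect_taxa = numeric(0))
    set.seed(s)
    X <- rnorm(80)
    counts <- micromediate:::draw_counts(cfg0, X)
    sh <- apply(counts, 1, shannon_index)
    cor(X, sh, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)) + 0.05)
})

test_that("city sample generation validates sizes and is reproducible", {
  expect_error(generate_city_samples(c(10, 0)), "sizes")
  s1 <- generate_city_samples(c(20, 30), seed = 5)
  s2 <- generate_city_samples(c(20, 30), seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1[[2]]$abundance), 30)
})
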