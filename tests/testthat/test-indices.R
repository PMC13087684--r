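test_that("Shannon index in bits matches hand values and its bound", {
  expect_equal(shannon_index(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_index(c(7, 0, 0)), 0)
  expect_equal(shannon_index(c(2, 2)), 1)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  set.seed(2)
  for (i in 1:20) {
    row <- rpois(15, 5)
    if (sum(row) == 0) next
    h <- shannon_index(row)
    expect_gte(h, 0)
    expect_lte(h, log2(observed_features(row)) + 1e-12)
  }
})

test_that("observed features counts positive taxa", {
  expect_equal(observed_features(c(5, 0, 1)), 2)
  expect_equal(observed_features(rep(3, 40)), 40)
  expect_equal(observed_features(c(1, 0, 0, 0)), 1)
})

test_that("Fisher's alpha solves S = alpha log(1 + N/alpha)", {
  # self-consistency at the specified residual tolerance
  a <- fisher_alpha(c(rep(1, 5), 100, 200, 300, 50, 345))
  S <- 10; N <- 1000
  expect_lt(abs(a * log1p(N / a) - S), 1e-9)
  # independent bisection oracle
  expect_equal(a, fisher_alpha_bisection(10, 1000), tolerance = 1e-7)
  # monotone in S at fixed N
  alphas <- vapply(2:20, function(S) {
    counts <- c(rep(1, S - 1), 1000 - (S - 1))
    fisher_alpha(counts)
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
  # all singletons: no finite root, flagged missing
  res <- fisher_alpha(rep(1, 7))
  expect_true(is.na(res))
  expect_true(isTRUE(attr(res, "no_finite_root")))
  # matches vegan's solver
  row <- c(rep(1, 9), 991)
  expect_equal(fisher_alpha(row),
               as.numeric(vegan::fisher.alpha(matrix(row, 1))),
               tolerance = 1e-4)
})

test_that("Bray-Curtis has hand values, symmetry, and identity", {
  x <- rbind(u = c(1, 1, 0), v = c(0, 1, 1), w = c(1, 1, 0))
  d <- bray_curtis(x)
  expect_equal(d["u", "v"], 0.5)
  expect_equal(d["u", "w"], 0)          # identical rows
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 3)))[1, 2], 1)  # disjoint
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "zero-sum")
})

test_that("PCoA reproduces geometry and the Gower eigenvalue identity", {
  # three collinear points, pairwise distances (1, 1, 2)
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(d, k = 2)
  ax1 <- res$coordinates[, 1]
  expect_equal(unname(abs(ax1["a"] - ax1["b"])), 1, tolerance = 1e-8)
  expect_equal(unname(abs(ax1["a"] - ax1["c"])), 2, tolerance = 1e-8)
  expect_lt(abs(res$eigenvalues[2]), 1e-8)

  # Euclidean-embeddable distances are reproduced on the positive axes
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  de <- as.matrix(dist(pts))
  res2 <- pcoa(de, k = 5)
  rec <- as.matrix(dist(res2$coordinates))
  expect_equal(rec, de, tolerance = 1e-8, ignore_attr = TRUE)
  # sum of positive eigenvalues equals the trace of the centered matrix
  G <- -0.5 * de^2
  n <- nrow(de)
  J <- diag(n) - matrix(1 / n, n, n)
  expect_equal(sum(res2$eigenvalues[res2$eigenvalues > 1e-10]),
               sum(diag(J %*% G %*% J)), tolerance = 1e-8)
  # duplicated sample gets identical coordinates
  x <- rbind(a = c(3, 1, 0), b = c(3, 1, 0), c = c(0, 2, 5), d = c(1, 1, 1))
  r3 <- pcoa(bray_curtis(x))
  expect_equal(r3$coordinates["a", ], r3$coordinates["b", ],
               tolerance = 1e-10)
  # sign convention: lexicographically first sample loads non-negatively
  expect_true(all(r3$coordinates["a", ] >= 0))
})

test_that("group ratios and guild abundances follow the count sums", {
  counts <- toy_counts()
  fir <- c("Faecalibacterium", "Roseburia")
  bac <- c("Bacteroides", "Prevotella")
  expect_equal(group_ratio(counts, fir, bac), 30 / 40)
  expect_equal(group_ratio(counts * 10, fir, bac), 30 / 40)  # scale-free
  miss <- group_ratio(counts, fir, "AbsentPhylumTaxon")
  expect_true(is.na(miss))
  expect_true(isTRUE(attr(miss, "zero_denominator")))

  g <- default_guilds()
  expect_equal(guild_abundance(counts, g$risk), 10 / 100)
  expect_equal(guild_abundance(counts, g$butyrate), 30 / 100)
  expect_equal(guild_abundance(counts, "NotPresent"), 0)
  only_f <- c(Faecalibacterium = 20, Bacteroides = 80)
  expect_equal(guild_abundance(only_f, g$butyrate), 0.2)
})

test_that("compute_indices returns the ten indices with valid ranges", {
  cohort <- generate_cohort(n = 40, seed = 11)
  idx <- suppressWarnings(suppressMessages(compute_indices(cohort$abundance)))
  expect_setequal(setdiff(names(idx), "sample_id"), index_names())
  expect_equal(nrow(idx), 40)
  expect_true(all(idx$observed_features <= ncol(cohort$abundance)))
  for (g in c("risk_abund", "butyrate_abund", "lactate_abund")) {
    expect_true(all(idx[[g]] >= 0 & idx[[g]] <= 1))
  }
  expect_true(all(idx$shannon >= 0))
  expect_true(all(idx$fb_ratio > 0, na.rm = TRUE))
})
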