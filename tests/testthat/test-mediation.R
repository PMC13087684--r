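test_that("triplet selection crosses significant mediators and outcomes", {
  fake_screen <- function(rows) {
    list(results = data.frame(
      x = rows$x, dv = rows$dv, significant = rows$sig,
      stringsAsFactors = FALSE
    ))
  }
  ms <- fake_screen(data.frame(
    x = c("e1", "e1", "e2"), dv = c("m1", "m2", "m1"),
    sig = c(TRUE, TRUE, FALSE)
  ))
  ys <- fake_screen(data.frame(
    x = c("e1", "e1", "e1", "e2"), dv = c("y1", "y2", "y3", "y1"),
    sig = c(TRUE, TRUE, TRUE, TRUE)
  ))
  tri <- select_triplets(ms, ys)
  expect_equal(nrow(tri), 6)                   # 2 mediators x 3 outcomes
  expect_false("e2" %in% tri$x)                # no significant mediator
  empty <- select_triplets(fake_screen(data.frame(
    x = "e", dv = "m", sig = FALSE
  )), ys)
  expect_equal(nrow(empty), 0)
})

test_that("OLS mediation satisfies c = c' + ab to machine precision", {
  for (s in 1:5) {
    tr <- synthetic_truth(n = 300, seed = s, a = runif(1, -1, 1),
                          b = runif(1, -1, 1), c_prime = runif(1, -1, 1))
    d <- generate_mediation_triplet(tr)
    m <- mediate_continuous(d$X, d$M, d$Y, d[c("age", "sex")],
                            n_boot = 100, seed = 1)
    expect_lt(abs(m$c - (m$c_prime + m$ab)), 1e-10)
  }
})

test_that("continuous engine recovers planted paths and proportion mediated", {
  tr <- synthetic_truth(a = 0.5, b = 0.4, c_prime = 0.3, n = 5000, seed = 10)
  d <- generate_mediation_triplet(tr)
  m <- mediate_continuous(d$X, d$M, d$Y, d[c("age", "sex")],
                          n_boot = 1000, seed = 2)
  expect_lt(m$ab_ci_lo, 0.20); expect_gt(m$ab_ci_hi, 0.20)
  # planted proportion mediated = ab / (ab + c') = 0.2 / 0.5 = 0.4
  expect_equal(m$proportion_mediated, 0.4, tolerance = 0.1)
  expect_identical(m$classification, "partial")
})

test_that("null indirect effect is covered ~95% of the time (continuous)", {
  covered <- vapply(1:150, function(s) {
    tr <- synthetic_truth(a = 0.5, b = 0, c_prime = 0.3, n = 400, seed = s)
    d <- generate_mediation_triplet(tr)
    m <- mediate_continuous(d$X, d$M, d$Y, d[c("age", "sex")],
                            n_boot = 300, seed = s)
    m$ab_ci_lo <= 0 && m$ab_ci_hi >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("binary engine estimates log-odds paths with a product CI", {
  tr <- synthetic_truth(a = 0.5, b = 0.4, c_prime = 0.3, n = 10000,
                        outcome_type = "binary", baseline = -1, seed = 12)
  d <- generate_mediation_triplet(tr)
  m <- mediate_binary(d$X, d$M, d$Y, d[c("age", "sex")])
  expect_equal(m$a, 0.5, tolerance = 0.1)
  expect_equal(m$b, 0.4, tolerance = 0.15)
  expect_lt(m$ab_ci_lo, m$ab); expect_gt(m$ab_ci_hi, m$ab)
  expect_identical(m$method, "dist_of_product")
  expect_true(m$noncollapsibility_caveat)
  # reported p agrees with the CI gate (both derive from the product CDF)
  expect_lt(m$ab_p, 0.05)
  # single-class outcome errors
  expect_error(
    mediate_binary(d$X, d$M, rep(1, nrow(d)), d[c("age", "sex")]),
    "single-class"
  )
  # perfect separation errors, naming the model
  ysep <- as.integer(d$X[1:200] > 0)
  suppressWarnings(expect_error(
    mediate_binary(d$X[1:200], d$M[1:200], ysep),
    "separation"
  ))
})

test_that("Y independent of M given X never asserts mediation through M", {
  classes <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 1500
    X <- rnorm(n); M <- 0.5 * X + rnorm(n)
    Y <- rbinom(n, 1, plogis(-0.5 + 0.4 * X))  # no M path
    mediate_binary(X, M, Y)$classification
  }, character(1))
  expect_gt(mean(classes == "none"), 0.9)
  expect_false(any(classes %in% c("partial", "inconsistent")) &&
                 mean(classes != "none") > 0.2)
})

test_that("distribution-of-product CI is symmetric at zero and matches MC", {
  ci0 <- dist_of_product_ci(0, 1, 0, 1)
  expect_lt(abs(ci0[1] + ci0[2]), 1e-6)
  for (case in list(c(0.5, 1, 1, 1), c(2, 1, 0.5, 1), c(1, 0.3, -0.8, 0.2))) {
    ci <- dist_of_product_ci(case[1], case[2], case[3], case[4])
    mc <- dop_mc_quantiles(case[1], case[2], case[3], case[4],
                           c(0.025, 0.975), n = 5e5)
    expect_lt(max(abs(ci - mc)), 0.012)
  }
  # far from zero the interval converges to the Sobel normal approximation
  a <- 50; b <- 50
  ci <- dist_of_product_ci(a, 1, b, 1)
  sobel <- a * b + c(-1, 1) * qnorm(0.975) * sqrt(a^2 + b^2)
  expect_lt(max(abs(ci - sobel) / diff(sobel)), 0.01)
  expect_error(dist_of_product_ci(NA, 1, 0, 1), "non-finite")
  expect_error(dist_of_product_ci(0, 0, 0, 1), "non-finite")
})

test_that("classification follows the sign/significance rules", {
  expect_identical(classify_mediation(0.02, c(0.01, 0.03), 0.2, 0.001),
                   "partial")
  expect_identical(classify_mediation(-0.02, c(-0.03, -0.01), 0.2, 0.001),
                   "inconsistent")
  expect_identical(classify_mediation(0.02, c(0.01, 0.03), 0.2, 0.4),
                   "full")
  expect_identical(classify_mediation(0.0, c(-0.01, 0.03), 0.2, 0.001),
                   "none")
  # invariant to rescaling X: signs and significances are scale-free
  tr <- synthetic_truth(n = 800, seed = 19)
  d <- generate_mediation_triplet(tr)
  m1 <- mediate_continuous(d$X, d$M, d$Y, n_boot = 200, seed = 3)
  m2 <- mediate_continuous(100 * d$X, d$M, d$Y, n_boot = 200, seed = 3)
  expect_identical(m1$classification, m2$classification)
  expect_equal(m1$ab, m2$ab, tolerance = 1e-10)  # X is Z-scored internally
})

test_that("proportion mediated is signed, flagged out of range or undefined", {
  expect_equal(proportion_mediated(0.02, 0.2), 0.1)
  pm <- proportion_mediated(-0.01, 0.2)
  expect_equal(as.numeric(pm), -0.05)
  expect_true(isTRUE(attr(pm, "out_of_range")))
  und <- proportion_mediated(0.01, 0)
  expect_true(is.na(und))
  expect_true(isTRUE(attr(und, "undefined_total_effect")))
})
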