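test_that("questionnaire coding reproduces the daily-occurrence scale", {
  expect_identical(code_response("frequency", "never"), 0)
  expect_equal(code_response("frequency", "rarely"), 2 / 30.4)
  expect_equal(round(code_response("frequency", "rarely"), 3), 0.066)
  expect_equal(code_response("frequency", "occasionally"), 1.5 / 7)
  expect_equal(round(code_response("frequency", "occasionally"), 3), 0.214)
  expect_equal(code_response("frequency", "often"), 4 / 7)
  expect_equal(round(code_response("frequency", "often"), 3), 0.571)
  expect_identical(code_response("frequency", "every day"), 1)
  expect_identical(code_response("binary", "yes"), 1)
  expect_identical(code_response("binary", "no"), 0)
  expect_identical(
    code_response("ordinal", "c", options = c("a", "b", "c", "d")), 2
  )
  # idempotent on already-numeric input
  expect_identical(code_response("frequency", 0.5), 0.5)
  expect_error(code_response("frequency", "sometimes"), "allowed")
})

test_that("missingness filter drops variables first, then participants", {
  set.seed(1)
  tab <- data.frame(
    participant_id = sprintf("p%02d", 1:20),
    v_bad = c(rep(NA, 12), rnorm(8)),        # 60% missing -> dropped
    v1 = rnorm(20), v2 = rnorm(20), v3 = rnorm(20)
  )
  # participant missing 2 of 3 retained variables (67% > 50%) -> dropped
  tab$v1[1] <- NA; tab$v2[1] <- NA
  out <- filter_missing(tab)
  expect_identical(attr(out, "dropped_variables"), "v_bad")
  expect_false("v_bad" %in% names(out))
  expect_false("p01" %in% out$participant_id)
  expect_equal(nrow(out), 19)
  # exactly 50% missing is retained (strict > threshold)
  tab2 <- data.frame(participant_id = c("a", "b"),
                     v1 = c(NA, 1), v2 = c(1, 2))
  out2 <- filter_missing(tab2)
  expect_equal(nrow(out2), 2)
  expect_true("v1" %in% names(out2))
  # no missingness -> identity
  clean <- tab[2:20, c("participant_id", "v1", "v2", "v3")]
  expect_equal(filter_missing(clean), clean, ignore_attr = TRUE)
})

test_that("all-missing table flags empty result instead of erroring", {
  tab <- data.frame(participant_id = c("a", "b"),
                    v1 = c(NA_real_, NA_real_))
  out <- filter_missing(tab)
  expect_true(isTRUE(attr(out, "empty_result")))
})

test_that("Spearman pruning drops one member per collinear pair", {
  set.seed(7)
  x <- data.frame(a = rnorm(100))
  x$b <- x$a                      # duplicate
  x$c <- rnorm(100)
  res <- spearman_prune(x)
  expect_identical(res$dropped, "b")  # equal missingness -> later name
  expect_setequal(res$kept, c("a", "c"))
  expect_equal(nrow(res$log), 1)

  # three mutually duplicated columns: two dropped, one kept
  y <- data.frame(a = x$a, b = x$a, c = x$a)
  res3 <- spearman_prune(y)
  expect_length(res3$dropped, 2)
  expect_length(res3$kept, 1)
  expect_identical(res3$kept, "a")

  # member with more missing values loses
  z <- data.frame(a = x$a, b = x$a)
  z$a[1:5] <- NA
  resz <- spearman_prune(z)
  expect_identical(resz$dropped, "a")
})

test_that("independent columns survive pruning; constants only warn", {
  dropped_any <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.data.frame(matrix(rnorm(500 * 4), 500))
    length(spearman_prune(x)$dropped) > 0
  }, logical(1))
  expect_lte(mean(dropped_any), 0.05)
  xc <- data.frame(a = rnorm(50), b = rep(1, 50))
  expect_warning(res <- spearman_prune(xc), "constant")
  expect_length(res$dropped, 0)
})

test_that("three-year window averages the preceding years with fallback", {
  s <- c("2012" = 1, "2013" = 2, "2014" = 3)
  expect_equal(as.numeric(average_three_year_window(s, 2015)), 2)
  # all three target years absent -> three most recent preceding years
  s2 <- c("2009" = 3, "2010" = 3, "2011" = 3)
  v2 <- average_three_year_window(s2, 2015)
  expect_equal(as.numeric(v2), 3)
  expect_true(isTRUE(attr(v2, "fallback")))
  # partial window flagged short
  s3 <- c("2013" = 4)
  v3 <- average_three_year_window(s3, 2015)
  expect_equal(as.numeric(v3), 4)
  expect_true(isTRUE(attr(v3, "short_window")))
  # no preceding data at all
  v4 <- average_three_year_window(c("2020" = 1), 2015)
  expect_true(is.na(v4))
  expect_true(isTRUE(attr(v4, "no_data")))
})

test_that("mycotoxin dose chain follows C = D*M and E = C * sum(F*W)", {
  expect_equal(regional_concentration(0.5, 10), 5)
  expect_equal(regional_concentration(0, 7), 0)
  expect_equal(regional_concentration(1, 7.3), 7.3)
  expect_error(regional_concentration(1.2, 1), "detection_rate")

  expect_equal(individual_mycotoxin_exposure(2, c(1, 1, 1)), 2)
  expect_equal(individual_mycotoxin_exposure(5, c(0, 0, 0)), 0)
  # hand evaluation with coded frequencies often (grains) and rarely (dairy)
  expect_equal(
    individual_mycotoxin_exposure(5, c(0.5714, 0.0658, 0)),
    5 * (0.5714 * 0.5 + 0.0658 * 0.3)
  )
  expect_error(individual_mycotoxin_exposure(1, c(-1, 0, 0)), "frequencies")
  # linear in C and in each frequency component
  f <- c(0.3, 0.2, 0.1)
  expect_equal(individual_mycotoxin_exposure(4, f),
               2 * individual_mycotoxin_exposure(2, f))
  expect_equal(individual_mycotoxin_exposure(2, 2 * f),
               2 * individual_mycotoxin_exposure(2, f))
})

test_that("city assignment uses a 5-km haversine radius with tie-break", {
  centers <- data.frame(city = c("alpha", "beta"),
                        lat = c(40, 41), lon = c(-74, -74))
  expect_identical(assign_city(40, -74, centers), "alpha")
  # 0.1 degrees latitude is ~11.1 km: outside the radius
  expect_identical(assign_city(40.1, -74, centers[1, ]), NA_character_)
  # equidistant between two centers 0.06 degrees apart each: lexicographic
  mid <- data.frame(city = c("zeta", "eta"),
                    lat = c(40.02, 39.98), lon = c(-74, -74))
  expect_identical(assign_city(40, -74, mid), "eta")
  expect_error(assign_city(95, 0, centers), "lat")
  expect_error(assign_city(0, 200, centers), "lon")
})
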