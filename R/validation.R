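# Simulation studies validating the estimation machinery against planted
# ground truth: parameter recovery with CI coverage, false-positive control
# of the dual-criterion screen, type-I error of the group-comparison tests,
# Monte-Carlo verification of the product-of-normals CI, and the
# subsampler's acceptance behaviour. Used by the test suite and the
# reproduction script; sized so a single CPU completes them in minutes.

#' Parameter-recovery study for a mediation engine
#'
#' Repeatedly generates triplets with planted paths, runs the requested
#' engine, and summarizes recovery of the planted indirect effect
#' `ab = a * b`: the mean estimate, the fraction of 95% CIs covering the
#' planted value, and the mean proportion mediated.
#'
#' @param engine `"continuous"` (bootstrap CI) or `"binary"`
#'   (distribution-of-product CI).
#' @param n_rep Number of replicates.
#' @param n Cohort size per replicate.
#' @param a,b,c_prime Planted paths.
#' @param baseline Baseline (log-odds for the binary engine).
#' @param n_boot Bootstrap resamples per replicate (continuous engine).
#' @param seed Master seed.
#' @return List with `mean_ab`, `coverage`, `mean_proportion_mediated`,
#'   `n_rep`, `planted_ab`.
#' @export
recovery_study <- function(engine = c("continuous", "binary"), n_rep = 500,
                           n = 5000, a = 0.5, b = 0.4, c_prime = 0.3,
                           baseline = if (engine == "binary") -1 else 0,
                           n_boot = 800, seed = 1) {
  engine <- match.arg(engine)
  planted_ab <- a * b
  res <- vapply(seq_len(n_rep), function(r) {
    tr <- synthetic_truth(a = a, b = b, c_prime = c_prime, n = n,
                          outcome_type = engine,
                          baseline = baseline, seed = sub_seed(seed, r))
    d <- generate_mediation_triplet(tr)
    m <- if (engine == "continuous") {
      mediate_continuous(d$X, d$M, d$Y, d[c("age", "sex")],
                         n_boot = n_boot, seed = sub_seed(seed, r) + 1L)
    } else {
      mediate_binary(d$X, d$M, d$Y, d[c("age", "sex")],
                     seed = sub_seed(seed, r) + 1L)
    }
    c(ab = m$ab,
      covered = as.numeric(m$ab_ci_lo <= planted_ab &
                             m$ab_ci_hi >= planted_ab),
      pm = m$proportion_mediated)
  }, numeric(3))
  list(mean_ab = mean(res["ab", ]), coverage = mean(res["covered", ]),
       mean_proportion_mediated = mean(res["pm", ]), n_rep = n_rep,
       planted_ab = planted_ab)
}

#' False-positive rate of the dual-criterion screen on null data
#'
#' Generates exposures and dependent variables with no associations at all
#' and reports the mean fraction of pairs the dual criterion flags.
#'
#' @param n_rep Replicates.
#' @param n Samples per replicate.
#' @param n_x,n_dv Numbers of exposure and dependent-variable columns.
#' @param seed Master seed.
#' @export
null_screen_fpr <- function(n_rep = 10, n = 1000, n_x = 50, n_dv = 10,
                            seed = 1) {
  rates <- vapply(seq_len(n_rep), function(r) {
    set.seed(sub_seed(seed, r))
    X <- as.data.frame(matrix(stats::rnorm(n * n_x), n))
    DV <- as.data.frame(matrix(stats::rnorm(n * n_dv), n))
    sc <- screen_associations(X, DV)
    mean(sc$results$significant)
  }, numeric(1))
  mean(rates)
}

#' Type-I error of the Mann-Whitney test under identical distributions
#' @param n_rep Replicates.
#' @param n Per-group sample size.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @export
mw_type1 <- function(n_rep = 500, n = 50, alpha = 0.05, seed = 1) {
  mean(vapply(seq_len(n_rep), function(r) {
    set.seed(sub_seed(seed, r))
    mann_whitney(stats::rnorm(n), stats::rnorm(n))$p < alpha
  }, logical(1)))
}

#' Type-I error of PERMANOVA under random labels
#'
#' Random two-group labels on exchangeable count data; rejection rate at
#' `alpha` with the discrete permutation p-value (`p <= alpha`, attainable
#' exactly with the add-one convention).
#' @param n_rep Replicates.
#' @param n Samples per replicate.
#' @param n_perm Permutations per test.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @export
permanova_type1 <- function(n_rep = 500, n = 30, n_perm = 199,
                            alpha = 0.05, seed = 1) {
  mean(vapply(seq_len(n_rep), function(r) {
    set.seed(sub_seed(seed, r))
    x <- matrix(stats::rpois(n * 12, 8), n)
    labels <- sample(rep(c("a", "b"), length.out = n))
    d <- bray_curtis(x)
    permanova(d, labels, n_perm = n_perm,
              seed = sub_seed(seed, r) + 1L)$p <= alpha
  }, logical(1)))
}

#' Monte-Carlo verification of the distribution-of-product CI
#'
#' Across a grid of standardized effect ratios `a/se` and `b/se`, compares
#' both endpoints of the analytic interval with empirical quantiles of
#' `n_draws` simulated products and returns the maximum absolute
#' discrepancy. The grid is evaluated at the standard-error magnitude
#' typical of fitted mediation paths (`se = 0.1` by default), where a
#' 2e6-draw empirical quantile is itself precise to a few 1e-4; at unit
#' standard errors the Monte-Carlo quantiles alone wander by more than 0.01
#' at the outer grid points, which would measure the oracle's noise, not
#' the interval's accuracy.
#'
#' @param ratios Grid of standardized ratios (used for both paths).
#' @param se Standard error at which the grid is realized (`a = ratio * se`).
#' @param n_draws Monte-Carlo draws per grid point.
#' @param level Confidence level.
#' @param seed Master seed.
#' @export
dop_ci_mc_discrepancy <- function(ratios = c(0, 0.5, 1, 2, 5), se = 0.1,
                                  n_draws = 2e6, level = 0.95, seed = 1) {
  alpha <- (1 - level) / 2
  worst <- 0
  k <- 0L
  for (ra in ratios) {
    for (rb in ratios) {
      k <- k + 1L
      ci <- dist_of_product_ci(ra * se, se, rb * se, se, level = level)
      set.seed(sub_seed(seed, k))
      prod <- stats::rnorm(n_draws, ra * se, se) *
        stats::rnorm(n_draws, rb * se, se)
      mc <- stats::quantile(prod, c(alpha, 1 - alpha), names = FALSE)
      worst <- max(worst, abs(ci - mc))
    }
  }
  worst
}

#' First-draw acceptance rate of the KS-gated subsampler on iid cities
#'
#' Under iid sampling the subset's alpha distribution matches the full
#' city's, so the first draw should be accepted nearly always.
#'
#' @param n_seeds Number of independent subsampling runs.
#' @param n City size.
#' @param target Subsample target size.
#' @param seed Master seed.
#' @export
subsampler_first_draw_rate <- function(n_seeds = 100, n = 100, target = 55,
                                       seed = 1) {
  set <- generate_city_samples(n, seed = sub_seed(seed, 0L))[[1]]
  mean(vapply(seq_len(n_seeds), function(s) {
    subsample_city(set, target, seed = sub_seed(seed, s))$iterations == 1L
  }, logical(1)))
}
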