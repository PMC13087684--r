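# Mediation analysis: direct (c') and microbiome-mediated indirect (ab)
# effects for exposure -> index -> outcome triplets, with a nonparametric
# bootstrap CI (continuous outcomes) or a distribution-of-product CI (binary
# outcomes, mixed linear/logistic paths), proportion mediated ab/c, and the
# full/partial/inconsistent classification.

#' Select mediation triplets from two screens
#'
#' An exposure qualifies for mediation when it is significantly associated
#' with both a mediator index and a health outcome in the bivariate screens.
#' Each exposure's significant mediators are crossed with its significant
#' outcomes.
#'
#' @param m_screen Screen result for exposure -> mediator (from
#'   [screen_associations()]).
#' @param y_screen Screen result for exposure -> outcome.
#' @return Data frame with columns `x`, `m`, `y` (possibly 0 rows).
#' @export
select_triplets <- function(m_screen, y_screen) {
  ms <- m_screen$results[m_screen$results$significant, c("x", "dv")]
  ys <- y_screen$results[y_screen$results$significant, c("x", "dv")]
  out <- merge(ms, ys, by = "x", suffixes = c("_m", "_y"))
  if (!nrow(out)) {
    return(data.frame(x = character(), m = character(), y = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(x = out$x, m = out$dv_m, y = out$dv_y,
             stringsAsFactors = FALSE)
}

#' Proportion mediated
#'
#' `ab / c`, the share of the total effect transmitted through the
#' mediator. Signed: values outside \[0, 1\] occur under inconsistent
#' mediation and are flagged; |c| below `eps` yields a flagged undefined
#' value.
#'
#' @param ab Indirect effect.
#' @param c_total Total effect.
#' @param eps Threshold below which `c` is treated as zero.
#' @export
proportion_mediated <- function(ab, c_total, eps = 1e-8) {
  if (!is.finite(c_total) || abs(c_total) < eps) {
    return(set_flag(NA_real_, "undefined_total_effect"))
  }
  pm <- ab / c_total
  if (pm < 0 || pm > 1) pm <- set_flag(pm, "out_of_range")
  pm
}

#' Classify a mediation pathway
#'
#' `none` if the indirect-effect CI includes 0; `full` if ab is significant
#' but the direct effect is not; `partial` if both are significant with the
#' same sign; `inconsistent` if both are significant with opposite signs.
#'
#' @param ab Indirect effect estimate.
#' @param ab_ci Length-2 CI for ab.
#' @param c_prime Direct effect estimate.
#' @param c_prime_p p-value of the direct effect.
#' @param alpha Significance level for the direct effect (default 0.05).
#' @export
classify_mediation <- function(ab, ab_ci, c_prime, c_prime_p, alpha = 0.05) {
  ab_sig <- ab_ci[1L] > 0 || ab_ci[2L] < 0
  cp_sig <- is.finite(c_prime_p) && c_prime_p < alpha
  if (!ab_sig) return("none")
  if (!cp_sig) return("full")
  if (sign(ab) == sign(c_prime)) "partial" else "inconsistent"
}

# CDF of the product of two independent normals A ~ N(a, se_a^2),
# B ~ N(b, se_b^2): F(t) = E_A[ P(B <= t/A | A > 0) + P(B >= t/A | A < 0) ].
# A is integrated in standardized units over +/- 10 SD (truncation error
# < 1e-20, far below the 1e-6 CDF tolerance); the finite range keeps the
# adaptive quadrature fast when t/x crosses a near-step of the inner CDF.
dop_cdf <- function(t, a, se_a, b, se_b) {
  z0 <- -a / se_a  # standardized point where A crosses 0
  L <- 10
  h_pos <- function(z) {
    x <- a + se_a * z
    stats::dnorm(z) * stats::pnorm((t / x - b) / se_b)
  }
  h_neg <- function(z) {
    x <- a + se_a * z
    stats::dnorm(z) * stats::pnorm((t / x - b) / se_b, lower.tail = FALSE)
  }
  quad <- function(f, lo, hi) {
    if (lo >= hi) return(0)
    stats::integrate(f, lo, hi, rel.tol = 1e-8, abs.tol = 1e-10,
                     subdivisions = 2000L)$value
  }
  quad(h_pos, max(z0, -L), L) + quad(h_neg, -L, min(z0, L))
}

#' Distribution-of-product confidence interval for an indirect effect
#'
#' Asymmetric confidence interval for `ab` from the exact distribution of
#' the product of two independent normal estimates `N(a, se_a^2) *
#' N(b, se_b^2)`. The product CDF is evaluated by numerical integration of
#' the conditional normal CDF and the interval endpoints are found by
#' root-finding to a CDF tolerance of 1e-6.
#'
#' @param a,b Path estimates.
#' @param se_a,se_b Their standard errors (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
dist_of_product_ci <- function(a, se_a, b, se_b, level = 0.95) {
  if (!all(is.finite(c(a, se_a, b, se_b))) || se_a <= 0 || se_b <= 0) {
    stop("non-finite inputs or non-positive standard errors", call. = FALSE)
  }
  mu <- a * b
  sigma <- sqrt(a^2 * se_b^2 + b^2 * se_a^2 + se_a^2 * se_b^2)
  alpha <- (1 - level) / 2
  quantile_at <- function(prob) {
    f <- function(t) dop_cdf(t, a, se_a, b, se_b) - prob
    lo <- mu - 10 * sigma; hi <- mu + 10 * sigma
    while (f(lo) > 0) lo <- lo - 10 * sigma
    while (f(hi) < 0) hi <- hi + 10 * sigma
    stats::uniroot(f, c(lo, hi), tol = sigma * 1e-6)$root
  }
  c(quantile_at(alpha), quantile_at(1 - alpha))
}

# Z-score using the analysis sample's own mean/SD.
zscore <- function(x) (x - mean(x)) / stats::sd(x)

# Guard against (quasi-)complete separation in a logistic fit.
check_separation <- function(fit, label) {
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop(sprintf("perfect separation detected in logistic model for '%s'",
                 label), call. = FALSE)
  }
}

#' Mediation analysis for a continuous outcome
#'
#' Causal-steps estimation with OLS: the total effect c from `Y ~ X + C`,
#' the exposure-mediator path a from `M ~ X + C`, and the direct and
#' mediator paths (c', b) from `Y ~ X + M + C`, where `C` are the adjustment
#' covariates (age and sex by default). X is Z-score standardized on the
#' listwise-complete analysis sample. The indirect effect is `ab = a * b`
#' with a percentile 95% CI from nonparametric row resampling; with shared
#' covariates the decomposition `c = c' + a * b` holds to machine precision.
#'
#' @param X Exposure vector (standardized internally).
#' @param M Mediator vector (a gut-microbiome index).
#' @param Y Continuous outcome vector.
#' @param covariates Data frame of adjustment covariates (may be NULL).
#' @param n_boot Bootstrap resamples (default 5000; < 100 warns).
#' @param seed RNG seed for the resampling stream.
#' @param level Confidence level (default 0.95).
#' @return A `mediation_result` list: paths a, b, c, c_prime with SEs, ab,
#'   its CI and two-sided p (significance is gated on the CI; the p-value
#'   is reported alongside), proportion mediated, classification, method,
#'   n, seed.
#' @export
mediate_continuous <- function(X, M, Y, covariates = NULL, n_boot = 5000,
                               seed = 1, level = 0.95) {
  if (n_boot < 100) warning("n_boot < 100: CI will be unstable")
  dat <- assemble_triplet(X, M, Y, covariates)
  n <- length(dat$y)

  Zx <- cbind(1, dat$x, dat$covs)
  Zm <- cbind(1, dat$x, dat$m, dat$covs)
  fc <- stats::lm.fit(Zx, dat$y)
  fa <- stats::lm.fit(Zx, dat$m)
  fb <- stats::lm.fit(Zm, dat$y)
  if (fc$rank < ncol(Zx) || fb$rank < ncol(Zm)) {
    stop("rank-deficient design", call. = FALSE)
  }
  est <- list(c = fc$coefficients[2L], a = fa$coefficients[2L],
              c_prime = fb$coefficients[2L], b = fb$coefficients[3L])
  se <- function(fit, Z, j) {
    rss <- sum(fit$residuals^2)
    df <- length(fit$residuals) - fit$rank
    XtXinv <- chol2inv(chol(crossprod(Z)))
    sqrt(rss / df * XtXinv[j, j])
  }
  se_a <- se(fa, Zx, 2L)
  se_b <- se(fb, Zm, 3L)
  cp_t <- est$c_prime / se(fb, Zm, 2L)
  cp_p <- 2 * stats::pt(-abs(cp_t), df = n - fb$rank)

  set.seed(seed)
  ab_boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Zx <- cbind(1, dat$x[idx], dat$covs[idx, , drop = FALSE])
    Zm <- cbind(Zx[, 1:2, drop = FALSE], dat$m[idx],
                dat$covs[idx, , drop = FALSE])
    a_i <- stats::lm.fit(Zx, dat$m[idx])$coefficients[2L]
    b_i <- stats::lm.fit(Zm, dat$y[idx])$coefficients[3L]
    ab_boot[i] <- a_i * b_i
  }
  alpha <- (1 - level) / 2
  ab_ci <- unname(stats::quantile(ab_boot, c(alpha, 1 - alpha), type = 7))
  # bootstrap two-sided p for ab, reported alongside the gating CI
  ab_p <- min(1, 2 * min(mean(ab_boot <= 0), mean(ab_boot >= 0)))

  build_mediation_result(
    a = est$a, se_a = se_a, b = est$b, se_b = se_b, c_total = est$c,
    c_prime = est$c_prime, c_prime_p = cp_p, ab_ci = ab_ci, ab_p = ab_p,
    method = "bootstrap", outcome_type = "continuous", n = n, seed = seed,
    n_boot = n_boot
  )
}

#' Mediation analysis for a binary outcome
#'
#' Mixed linear/logistic estimation: path a (X -> M) by linear regression;
#' the total effect c and the (c', b) pair by logistic regression of Y on X
#' and on (X, M), coefficients on the log-odds scale. The indirect effect
#' `ab = a * b` gets an asymmetric 95% CI from the distribution of the
#' product of the two normal estimates ([dist_of_product_ci()]). The
#' proportion mediated ab/c is reported with a scale-heterogeneity
#' (non-collapsibility) caveat flag.
#'
#' @inheritParams mediate_continuous
#' @param Y Binary outcome vector (0/1, both classes present).
#' @export
mediate_binary <- function(X, M, Y, covariates = NULL, seed = 1,
                           level = 0.95) {
  dat <- assemble_triplet(X, M, Y, covariates)
  if (length(unique(dat$y)) < 2L) {
    stop("single-class outcome: both classes of Y must be present",
         call. = FALSE)
  }
  if (!all(dat$y %in% c(0, 1))) stop("binary Y must be 0/1", call. = FALSE)
  n <- length(dat$y)

  covs <- dat$covs
  dfr <- data.frame(y = dat$y, x = dat$x, m = dat$m)
  if (!is.null(covs) && ncol(covs)) dfr <- cbind(dfr, as.data.frame(covs))
  cov_terms <- setdiff(names(dfr), c("y", "x", "m"))
  form <- function(rhs) {
    stats::as.formula(paste("y ~", paste(c(rhs, cov_terms), collapse = " + ")))
  }
  fa <- stats::lm(stats::as.formula(
    paste("m ~", paste(c("x", cov_terms), collapse = " + "))), data = dfr)
  fc <- stats::glm(form("x"), family = stats::binomial(), data = dfr)
  fb <- stats::glm(form(c("x", "m")), family = stats::binomial(), data = dfr)
  check_separation(fc, "Y ~ X")
  check_separation(fb, "Y ~ X + M")

  sa <- summary(fa)$coefficients
  sc <- summary(fc)$coefficients
  sb <- summary(fb)$coefficients
  a <- sa["x", 1L]; se_a <- sa["x", 2L]
  b <- sb["m", 1L]; se_b <- sb["m", 2L]
  c_total <- sc["x", 1L]
  c_prime <- sb["x", 1L]; c_prime_p <- sb["x", 4L]
  ab_ci <- dist_of_product_ci(a, se_a, b, se_b, level = level)
  # two-sided p from the product CDF at zero, reported alongside the CI
  F0 <- dop_cdf(0, a, se_a, b, se_b)
  ab_p <- min(1, 2 * min(F0, 1 - F0))

  res <- build_mediation_result(
    a = a, se_a = se_a, b = b, se_b = se_b, c_total = c_total,
    c_prime = c_prime, c_prime_p = c_prime_p, ab_ci = ab_ci, ab_p = ab_p,
    method = "dist_of_product", outcome_type = "binary", n = n, seed = seed,
    n_boot = NA_integer_
  )
  res$noncollapsibility_caveat <- TRUE
  res
}

# Shared listwise deletion + X standardization for both engines.
assemble_triplet <- function(X, M, Y, covariates) {
  covs <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  idx <- if (is.null(covs)) {
    complete_rows(X, M, Y)
  } else {
    do.call(complete_rows, c(list(X, M, Y), unname(as.list(covs))))
  }
  if (length(idx) < 10L) stop("fewer than 10 complete cases", call. = FALSE)
  if (stats::sd(X[idx]) == 0) stop("constant exposure X", call. = FALSE)
  cm <- if (is.null(covs)) NULL else
    as.matrix(covs[idx, , drop = FALSE])
  list(x = zscore(X[idx]), m = M[idx], y = Y[idx], covs = cm)
}

build_mediation_result <- function(a, se_a, b, se_b, c_total, c_prime,
                                   c_prime_p, ab_ci, ab_p = NA_real_,
                                   method, outcome_type, n, seed, n_boot) {
  ab <- a * b
  pm <- proportion_mediated(ab, c_total)
  structure(list(
    a = unname(a), se_a = unname(se_a), b = unname(b), se_b = unname(se_b),
    c = unname(c_total), c_prime = unname(c_prime),
    c_prime_p = unname(c_prime_p),
    ab = unname(ab), ab_ci_lo = ab_ci[1L], ab_ci_hi = ab_ci[2L],
    ab_p = unname(ab_p),
    proportion_mediated = as.numeric(pm),
    proportion_mediated_flag = if (has_flag(pm, "undefined_total_effect")) {
      "undefined"
    } else if (has_flag(pm, "out_of_range")) "out_of_range" else "ok",
    classification = classify_mediation(ab, ab_ci, c_prime, c_prime_p),
    method = method, outcome_type = outcome_type, n = n, seed = seed,
    n_boot = n_boot
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    paste0("Mediation (%s outcome, %s CI, n = %d)\n",
           "  a = %.4f (SE %.4f), b = %.4f (SE %.4f)\n",
           "  c = %.4f, c' = %.4f (p = %.3g)\n",
           "  ab = %.4f [%.4f, %.4f], proportion mediated = %.3f (%s)\n",
           "  classification: %s\n"),
    x$outcome_type, x$method, x$n, x$a, x$se_a, x$b, x$se_b, x$c, x$c_prime,
    x$c_prime_p, x$ab, x$ab_ci_lo, x$ab_ci_hi, x$proportion_mediated,
    x$proportion_mediated_flag, x$classification
  ))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    a = x$a, se_a = x$se_a, b = x$b, se_b = x$se_b, c = x$c,
    c_prime = x$c_prime, c_prime_p = x$c_prime_p, ab = x$ab,
    ab_ci_lo = x$ab_ci_lo, ab_ci_hi = x$ab_ci_hi, ab_p = x$ab_p,
    proportion_mediated = x$proportion_mediated,
    proportion_mediated_flag = x$proportion_mediated_flag,
    classification = x$classification, method = x$method,
    outcome_type = x$outcome_type, n = x$n, seed = x$seed,
    n_boot = x$n_boot, stringsAsFactors = FALSE
  )
}
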