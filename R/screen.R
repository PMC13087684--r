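# Bivariate exposure -> mediator / exposure -> outcome screening with
# heteroskedasticity-consistent standard errors, BH-FDR, and the dual
# significance criterion (FDR < 0.05 and adjusted R^2 > 0.005).

#' Bivariate OLS with heteroskedasticity-consistent standard errors
#'
#' Regresses `y` on `x` after listwise deletion, with an HC1 sandwich
#' standard error for the slope, a 95% Wald confidence interval (t
#' reference, n - 2 df), and the adjusted R^2
#' `1 - (1 - R^2) * (n - 1) / (n - 2)`.
#'
#' @param x,y Numeric vectors.
#' @param hc_type Sandwich variant (default `"HC1"`).
#' @param level Confidence level (default 0.95).
#' @return List with `beta`, `se`, `ci_lo`, `ci_hi`, `adj_r2`, `p`, `n`.
#' @export
bivariate_ols_robust <- function(x, y, hc_type = "HC1", level = 0.95) {
  idx <- complete_rows(x, y)
  x <- x[idx]; y <- y[idx]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("constant x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  se <- sqrt(sandwich::vcovHC(fit, type = hc_type)[2L, 2L])
  beta <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  tval <- beta / se
  list(
    beta = beta, se = se,
    ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
    adj_r2 = adj_r2,
    p = 2 * stats::pt(-abs(tval), df = n - 2),
    n = n
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    fail_field("p", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Dual-criterion association screen
#'
#' Runs [bivariate_ols_robust()] for every (exposure, dependent-variable)
#' pair, adjusts p-values with BH-FDR within the chosen family, and flags a
#' pair significant only if FDR < `fdr_cut`, the 95% CI for the slope
#' excludes zero, and adjusted R^2 > `r2_cut`. The signed effect-size matrix
#' holds `sign(beta) * adj_r2` for significant pairs and 0 elsewhere (the
#' heatmap encoding).
#'
#' @param X Data frame / matrix of exposures (columns = X variables).
#' @param DV Data frame / matrix of dependent variables (mediator indices or
#'   outcomes), same rows as `X`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param r2_cut Minimum adjusted R^2 (default 0.005).
#' @param fdr_family `"per_dv"` (one BH family per dependent variable,
#'   default) or `"global"` (one family over all pairs).
#' @return List with `results` (one row per pair: beta, robust SE, CI,
#'   adjusted R^2, raw and FDR p, significance, n) and `signed_r2` (X x DV
#'   matrix). The family choice is recorded in `attr(, "fdr_family")`.
#' @export
screen_associations <- function(X, DV, fdr_cut = 0.05, r2_cut = 0.005,
                                fdr_family = c("per_dv", "global")) {
  fdr_family <- match.arg(fdr_family)
  X <- as.data.frame(X); DV <- as.data.frame(DV)
  grid <- expand.grid(x = names(X), dv = names(DV),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- bivariate_ols_robust(X[[grid$x[i]]], DV[[grid$dv[i]]])
    data.frame(x = grid$x[i], dv = grid$dv[i], beta = r$beta, se = r$se,
               ci_lo = r$ci_lo, ci_hi = r$ci_hi, adj_r2 = r$adj_r2,
               p = r$p, n = r$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  if (fdr_family == "per_dv") {
    for (dv in unique(res$dv)) {
      sel <- res$dv == dv
      res$fdr[sel] <- bh_fdr(res$p[sel])
    }
  } else {
    res$fdr <- bh_fdr(res$p)
  }
  res$significant <- res$fdr < fdr_cut &
    (res$ci_lo > 0 | res$ci_hi < 0) & res$adj_r2 > r2_cut

  signed <- matrix(0, nrow = ncol(X), ncol = ncol(DV),
                   dimnames = list(names(X), names(DV)))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    signed[cbind(sig$x, sig$dv)] <- sign(sig$beta) * sig$adj_r2
  }
  out <- list(results = res, signed_r2 = signed)
  attr(out, "fdr_family") <- fdr_family
  out
}

#' Taxa correlated with an ordination axis
#'
#' Pearson correlation between each taxon's relative abundance and an
#' ordination axis score, BH-adjusted across taxa; a taxon is retained if
#' FDR < `fdr_cut` and `|r| > r_cut`. Zero-variance taxa are skipped.
#'
#' @param axis Numeric vector of per-sample axis scores.
#' @param rel_abund Samples x taxa matrix of relative abundances.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param r_cut Minimum absolute correlation (default 0.2).
#' @return Data frame (taxon, r, p, fdr, retained), one row per testable
#'   taxon.
#' @export
axis_taxa_correlation <- function(axis, rel_abund, fdr_cut = 0.05,
                                  r_cut = 0.2) {
  rel_abund <- as.matrix(rel_abund)
  stopifnot(length(axis) == nrow(rel_abund))
  sds <- apply(rel_abund, 2L, stats::sd)
  skipped <- colnames(rel_abund)[sds == 0]
  if (length(skipped)) {
    message("zero-variance taxa skipped: ", paste(skipped, collapse = ", "))
  }
  use <- which(sds > 0)
  res <- do.call(rbind, lapply(use, function(j) {
    ct <- stats::cor.test(axis, rel_abund[, j])
    data.frame(taxon = colnames(rel_abund)[j],
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  res$retained <- res$fdr < fdr_cut & abs(res$r) > r_cut
  res
}
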