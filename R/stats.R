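# Group-comparison statistics: Mann-Whitney U, PERMANOVA on a distance
# matrix, and the high/low exposure-quartile prevalence-shift analysis.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U with midrank tie handling. The exact null
#' distribution is used when `n1 * n2 <= 400` and there are no ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used.
#'
#' @param a,b Numeric samples for the two groups.
#' @return List with `U` (for group `a`), `p`, and `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  # ranks-based U (midranks), equal to wilcox.test's W
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  list(U = U, p = wt$p.value,
       method = if (use_exact) "exact" else "normal_tie_corrected")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance. Among- and within-group
#' sums of squares are computed directly from the squared distances (Gower
#' identity): `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`. The pseudo-F is
#' `(SS_among / (k - 1)) / (SS_within / (n - k))`; the p-value counts
#' permuted statistics at least as large under the add-one convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d Distance matrix (square symmetric, zero diagonal).
#' @param labels Group label per sample (>= 2 groups, all sizes >= 1).
#' @param n_perm Number of label permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return List with `F`, `R2`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  labels <- as.factor(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n, nlevels(labels) >= 2)
  if (any(table(labels) < 1)) stop("empty group", call. = FALSE)
  k <- nlevels(labels)
  D2 <- d^2
  ss_total <- sum(D2[upper.tri(D2)]) / n

  within_ss <- function(Z) {
    # Z: n x m 0/1 membership matrix for one group across m permutations;
    # z' D2 z / (2 n_g) sums within-group squared distances
    colSums(Z * (D2 %*% Z)) / (2 * colSums(Z))
  }
  memb <- stats::model.matrix(~ labels - 1)
  ss_within <- sum(vapply(seq_len(k), function(g) {
    within_ss(memb[, g, drop = FALSE])
  }, numeric(1)))
  F_obs <- ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))

  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  ss_w_perm <- rep(0, n_perm)
  for (g in seq_len(k)) {
    Zg <- matrix(memb[perms, g], nrow = n)
    ss_w_perm <- ss_w_perm + within_ss(Zg)
  }
  F_perm <- ((ss_total - ss_w_perm) / (k - 1)) / (ss_w_perm / (n - k))
  list(
    F = F_obs,
    R2 = (ss_total - ss_within) / ss_total,
    p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
    n_perm = n_perm, seed = seed
  )
}

#' Prevalence shift between high- and low-exposure quartiles
#'
#' Splits samples into a high group (exposure strictly above the 75th
#' percentile) and a low group (strictly below the 25th; boundary ties
#' excluded), computes each taxon's prevalence (fraction of samples with
#' count > 0) in both groups, the difference in percentage points, a
#' two-sided Fisher's exact test per taxon, and BH-FDR across taxa.
#'
#' @param abund Samples x taxa count matrix.
#' @param exposure Numeric exposure per sample.
#' @param taxa Taxon names to test (default: all columns).
#' @return Data frame (taxon, prevalence_high, prevalence_low,
#'   difference_pp, p, fdr) with attribute `quartile_n = c(high, low)`.
#' @export
prevalence_shift <- function(abund, exposure, taxa = colnames(abund)) {
  abund <- as.matrix(abund)
  ok <- which(!is.na(exposure))
  if (length(ok) < 8L) stop("need >= 8 non-missing exposure values",
                            call. = FALSE)
  e <- exposure[ok]
  q <- stats::quantile(e, c(0.25, 0.75))
  if (q[1L] == q[2L]) stop("degenerate quartiles: exposure has no spread",
                           call. = FALSE)
  hi <- ok[e > q[2L]]
  lo <- ok[e < q[1L]]
  res <- do.call(rbind, lapply(taxa, function(tx) {
    ph <- mean(abund[hi, tx] > 0)
    pl <- mean(abund[lo, tx] > 0)
    tab <- matrix(c(sum(abund[hi, tx] > 0), sum(abund[hi, tx] == 0),
                    sum(abund[lo, tx] > 0), sum(abund[lo, tx] == 0)),
                  nrow = 2L)
    data.frame(taxon = tx, prevalence_high = ph, prevalence_low = pl,
               difference_pp = 100 * (ph - pl),
               p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  attr(res, "quartile_n") <- c(high = length(hi), low = length(lo))
  res
}
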