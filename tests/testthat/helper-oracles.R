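# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, bisection, brute-force definition, Monte
# Carlo) kept separate from the code paths it checks.

# Benjamini-Hochberg from the step-up definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(1, adj)[order(o)]
}

# Exact two-sided Mann-Whitney p by enumerating all label assignments.
mw_enumeration <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, u_of)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# Fisher's alpha by plain bisection on [1e-6, 1e6].
fisher_alpha_bisection <- function(S, N, iter = 200) {
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-6; hi <- 1e6
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo quantiles of the product of two independent normals.
dop_mc_quantiles <- function(a, se_a, b, se_b, probs, n = 2e6, seed = 99) {
  set.seed(seed)
  prod <- stats::rnorm(n, a, se_a) * stats::rnorm(n, b, se_b)
  unname(stats::quantile(prod, probs))
}

# Small named count row covering several guilds.
toy_counts <- function() {
  c(Faecalibacterium = 20, Roseburia = 10, Bacteroides = 30,
    Prevotella = 10, Eggerthella = 5, Klebsiella = 5,
    Bifidobacterium = 10, Akkermansia = 10)
}
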