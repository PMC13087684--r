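# The ten gut-microbiome mediator indices: alpha diversity (Shannon,
# observed features, Fisher's alpha), Bray-Curtis PCoA axes, phylum and
# Gram-stain ratios, and functional-guild relative abundances.

#' Default functional-guild taxon lists
#'
#' Shipped defaults for the risk-associated, butyrate-producing, and
#' lactate-producing guilds. Risk-associated taxa are an ecological marker
#' of dysbiosis (expansion of opportunists), not evidence of infection.
#' The butyrate list mixes genera and named species; matching is exact on
#' the full name.
#'
#' @return Named list of character vectors: `risk`, `butyrate`, `lactate`.
#' @export
default_guilds <- function() {
  list(
    risk = c("Eggerthella", "Anaerotruncus", "Klebsiella"),
    butyrate = c(
      "Butyricimonas", "Odoribacter", "Anaerostipes", "Anaerobutyricum",
      "Agathobacter", "Butyrivibrio", "Coprococcus", "Roseburia",
      "Shuttleworthia", "Butyricicoccus", "Oscillibacter",
      "Faecalibacterium", "Flavonifractor", "Pseudoflavonifractor",
      "Subdoligranulum", "Subdoligranulum variabile", "Eubacterium ventriosum"
    ),
    lactate = c(
      "Bifidobacterium", "Lactobacillus", "Streptococcus", "Enterococcus",
      "Leuconostoc", "Lactococcus", "Pediococcus"
    )
  )
}

#' Default genus-to-phylum lookup for the taxa the synthetic cohort emits
#'
#' The Firmicutes/Bacteroidetes ratio needs a phylum assignment for each
#' genus; real data should supply a lookup covering its own taxa.
#' @return Named character vector: taxon -> phylum.
#' @export
default_phylum_map <- function() {
  fir <- c(
    "Anaerostipes", "Anaerobutyricum", "Agathobacter", "Butyrivibrio",
    "Coprococcus", "Roseburia", "Shuttleworthia", "Butyricicoccus",
    "Oscillibacter", "Faecalibacterium", "Flavonifractor",
    "Pseudoflavonifractor", "Subdoligranulum", "Subdoligranulum variabile",
    "Eubacterium ventriosum", "Anaerotruncus", "Lactobacillus",
    "Streptococcus", "Enterococcus", "Leuconostoc", "Lactococcus",
    "Pediococcus", "Blautia", "Ruminococcus", "Dorea", "Veillonella",
    "Dialister"
  )
  bac <- c("Bacteroides", "Prevotella", "Alistipes", "Parabacteroides",
           "Odoribacter", "Butyricimonas")
  act <- c("Bifidobacterium", "Eggerthella", "Collinsella")
  pro <- c("Klebsiella", "Escherichia", "Sutterella", "Bilophila")
  other <- c(Akkermansia = "Verrucomicrobia", Fusobacterium = "Fusobacteria")
  c(stats::setNames(rep("Firmicutes", length(fir)), fir),
    stats::setNames(rep("Bacteroidetes", length(bac)), bac),
    stats::setNames(rep("Actinobacteria", length(act)), act),
    stats::setNames(rep("Proteobacteria", length(pro)), pro),
    other)
}

#' Default Gram-stain lookup
#'
#' Gram status by known phylogeny: Firmicutes and Actinobacteria are
#' Gram-positive except the diderm Negativicutes (Veillonella, Dialister);
#' Bacteroidetes, Proteobacteria, Verrucomicrobia, and Fusobacteria are
#' Gram-negative.
#' @return Named character vector: taxon -> "positive" or "negative".
#' @export
default_gram_map <- function() {
  phy <- default_phylum_map()
  gram <- ifelse(phy %in% c("Firmicutes", "Actinobacteria"),
                 "positive", "negative")
  names(gram) <- names(phy)
  gram[c("Veillonella", "Dialister")] <- "negative"
  gram
}

#' Shannon diversity (bits)
#'
#' `-sum(p_i log2 p_i)` over taxa with positive counts, `p_i` the relative
#' abundance. Computed in base 2 by default; natural log available.
#'
#' @param counts Non-negative count vector for one sample.
#' @param base Logarithm base (2 for bits, `exp(1)` for nats).
#' @export
shannon_index <- function(counts, base = 2) {
  if (sum(counts) <= 0) stop("all-zero count row", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Observed features (richness)
#' @param counts Non-negative count vector for one sample.
#' @export
observed_features <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero count row", call. = FALSE)
  sum(counts > 0)
}

#' Fisher's alpha diversity
#'
#' The unique positive root of `S = alpha * log(1 + N / alpha)` where S is
#' the number of observed taxa and N the total count, found by bracketed
#' root-finding to |S_model - S| < 1e-9. All-singleton samples (S = N) have
#' no finite root and return a flagged missing value.
#'
#' @param counts Non-negative count vector for one sample.
#' @return Fisher's alpha, or flagged `NA` when S = N.
#' @export
fisher_alpha <- function(counts) {
  S <- sum(counts > 0)
  N <- sum(counts)
  if (S < 1 || N < S) stop("need S >= 1 and N >= S", call. = FALSE)
  if (S == N) return(set_flag(NA_real_, "no_finite_root"))
  f <- function(a) a * log1p(N / a) - S
  # f is increasing in alpha; bracket grows until the sign changes
  lo <- 1e-12; hi <- 1
  while (f(hi) < 0) hi <- hi * 10
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # polish to the specified residual tolerance
  stopifnot(abs(f(root)) < 1e-9)
  root
}

#' Bray-Curtis dissimilarity matrix
#'
#' `D(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))` on counts.
#'
#' @param x Samples x taxa matrix of non-negative counts.
#' @return Symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(rowSums(x) <= 0)) stop("zero-sum sample row", call. = FALSE)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2 / 2`, eigendecomposition, and coordinates
#' scaled by the square root of the k largest positive eigenvalues. Negative
#' eigenvalues are dropped with a warning (no Cailliez correction). Each
#' axis's sign is fixed so that the lexicographically first sample has a
#' non-negative coordinate.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param k Number of axes requested (default 2).
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending), and `axes_returned`; flagged `fewer_axes` if fewer than k
#'   positive eigenvalues exist.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), isTRUE(all.equal(d, t(d))),
            all(abs(diag(d)) < 1e-12))
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, nrow(d) - 1L),
                                          eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("negative eigenvalues dropped (non-Euclidean distances)",
            call. = FALSE)
  }
  n_pos <- sum(eig > max(eig) * 1e-10)
  coords <- fit$points[, seq_len(min(k, n_pos)), drop = FALSE]
  # sign convention: lexicographically first sample loads non-negatively
  first <- if (!is.null(rownames(d))) which.min(rank(rownames(d))) else 1L
  for (j in seq_len(ncol(coords))) {
    if (coords[first, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("pcoa", seq_len(ncol(coords)))
  out <- list(coordinates = coords, eigenvalues = sort(eig, decreasing = TRUE),
              axes_returned = ncol(coords))
  if (ncol(coords) < k) out <- set_flag(out, "fewer_axes")
  out
}

#' Ratio of two taxon-group count sums
#'
#' Sum of counts mapped to the numerator group divided by the sum mapped to
#' the denominator group (e.g. Firmicutes/Bacteroidetes). A zero denominator
#' yields a flagged missing value, never infinity. Scale-invariant, so
#' counts and relative abundances are equivalent.
#'
#' @param counts Named count vector for one sample.
#' @param numerator,denominator Character vectors of member taxon names.
#' @export
group_ratio <- function(counts, numerator, denominator) {
  num <- sum(counts[intersect(names(counts), numerator)])
  den <- sum(counts[intersect(names(counts), denominator)])
  if (den == 0) {
    return(set_flag(NA_real_, if (num == 0) "both_zero" else "zero_denominator"))
  }
  num / den
}

#' Relative abundance of a functional guild
#'
#' Summed relative abundance of the guild's member taxa; members absent
#' from the table contribute 0.
#'
#' @param counts Named non-negative count vector for one sample.
#' @param members Character vector of member taxon names.
#' @export
guild_abundance <- function(counts, members) {
  total <- sum(counts)
  if (total <= 0) stop("all-zero count row", call. = FALSE)
  sum(counts[intersect(names(counts), members)]) / total
}

#' Compute the ten mediator indices for every sample
#'
#' Per-sample Shannon index (bits), observed features, Fisher's alpha, the
#' first two Bray-Curtis principal coordinates, Firmicutes/Bacteroidetes and
#' Gram-positive/Gram-negative ratios, and risk-associated / butyrate- /
#' lactate-producer relative abundances. Indices are computed on raw counts
#' (no rarefaction).
#'
#' @param abund Samples x taxa count matrix with taxon column names and
#'   sample row names.
#' @param guilds Guild definition list (default [default_guilds()]).
#' @param phylum_map Taxon -> phylum lookup (default [default_phylum_map()]).
#' @param gram_map Taxon -> Gram-status lookup (default [default_gram_map()]).
#' @return Data frame of samples x 10 indices.
#' @export
compute_indices <- function(abund, guilds = default_guilds(),
                            phylum_map = default_phylum_map(),
                            gram_map = default_gram_map()) {
  abund <- as.matrix(abund)
  taxa <- colnames(abund)
  unmatched <- setdiff(
    unique(c(unlist(guilds), names(phylum_map), names(gram_map))), taxa
  )
  if (length(unmatched)) {
    message("taxa in configuration absent from table (contribute 0): ",
            length(unmatched), " names")
  }
  ord <- pcoa(bray_curtis(abund), k = 2)
  coords <- ord$coordinates
  if (ncol(coords) < 2L) {
    coords <- cbind(coords, matrix(0, nrow(coords), 2L - ncol(coords)))
  }
  fir <- names(phylum_map)[phylum_map == "Firmicutes"]
  bac <- names(phylum_map)[phylum_map == "Bacteroidetes"]
  gpos <- names(gram_map)[gram_map == "positive"]
  gneg <- names(gram_map)[gram_map == "negative"]
  one <- function(row) {
    c(shannon = shannon_index(row),
      observed_features = observed_features(row),
      fisher_alpha = as.numeric(fisher_alpha(row)),
      fb_ratio = as.numeric(group_ratio(row, fir, bac)),
      gp_gn_ratio = as.numeric(group_ratio(row, gpos, gneg)),
      risk_abund = guild_abundance(row, guilds$risk),
      butyrate_abund = guild_abundance(row, guilds$butyrate),
      lactate_abund = guild_abundance(row, guilds$lactate))
  }
  per <- t(apply(abund, 1L, one))
  out <- data.frame(
    sample_id = rownames(abund) %||% as.character(seq_len(nrow(abund))),
    shannon = per[, "shannon"],
    observed_features = per[, "observed_features"],
    fisher_alpha = per[, "fisher_alpha"],
    pcoa1 = coords[, 1L], pcoa2 = coords[, 2L],
    fb_ratio = per[, "fb_ratio"], gp_gn_ratio = per[, "gp_gn_ratio"],
    risk_abund = per[, "risk_abund"],
    butyrate_abund = per[, "butyrate_abund"],
    lactate_abund = per[, "lactate_abund"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Names of the ten mediator indices
#' @export
index_names <- function() {
  c("shannon", "observed_features", "fisher_alpha", "pcoa1", "pcoa2",
    "fb_ratio", "gp_gn_ratio", "risk_abund", "butyrate_abund",
    "lactate_abund")
}
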