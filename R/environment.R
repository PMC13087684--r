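# Standardization of unevenly sampled per-city environmental microbiome
# collections: eligibility, target size, KS-gated iterative subsampling,
# alpha-diversity summaries, and pathogen load sums.

#' Default obligate and facultative pathogen species lists
#'
#' Environmental pathogen load is the summed abundance of these species.
#' @return List with `obligate` (10 species) and `facultative` (11 species).
#' @export
default_pathogens <- function() {
  list(
    obligate = c(
      "Brucella ovis", "Brucella pinnipedialis", "Salmonella enterica",
      "Campylobacter jejuni", "Listeria monocytogenes",
      "Helicobacter pylori", "Neisseria gonorrhoeae",
      "Neisseria meningitidis", "Streptococcus pyogenes",
      "Haemophilus influenzae"
    ),
    facultative = c(
      "Acinetobacter baumannii", "Klebsiella pneumoniae",
      "Pseudomonas aeruginosa", "Staphylococcus aureus",
      "Clostridium perfringens", "Enterococcus faecalis",
      "Enterococcus faecium", "Escherichia coli", "Mycobacterium avium",
      "Mycobacterium abscessus", "Streptococcus pneumoniae"
    )
  )
}

#' Retain cities with sufficient sampling depth
#'
#' Cities with strictly more than `min_n - 1` samples (default: > 14) are
#' retained.
#'
#' @param sets List of city sample sets, each a list with `city` and
#'   `abundance` (samples x taxa matrix).
#' @param min_n Minimum retained sample count (retention rule is
#'   `n >= min_n`, i.e. `n > min_n - 1`).
#' @export
eligible_cities <- function(sets, min_n = 15) {
  keep <- vapply(sets, function(s) nrow(s$abundance) >= min_n, logical(1))
  sets[keep]
}

#' Standardization target size
#'
#' The median sample count of the retained cities (lower median for an even
#' count, so the target is an achievable city size), or a fixed override.
#'
#' @param sets Retained city sample sets.
#' @param override Optional fixed target (e.g. 55).
#' @export
target_size <- function(sets, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  sizes <- sort(vapply(sets, function(s) nrow(s$abundance), integer(1)))
  if (!length(sizes)) stop("no retained cities", call. = FALSE)
  as.integer(sizes[ceiling(length(sizes) / 2)])  # lower median
}

#' KS-gated iterative subsampling of one city
#'
#' Repeatedly draws a uniform random subset of `target` samples and accepts
#' the first whose per-sample alpha-diversity distribution is not
#' significantly different from the full city's (two-sample
#' Kolmogorov-Smirnov test, p > `p_threshold`). Cities at or below the
#' target pass through unchanged. The asymptotic KS p-value is used: ties
#' between subset and full-set values are guaranteed because the subset is
#' drawn from the full set.
#'
#' @param set City sample set (list with `city`, `abundance`).
#' @param target Target sample count.
#' @param alpha_metric Which per-sample alpha metric gates acceptance:
#'   `"fisher_alpha"` (default), `"shannon"`, or `"observed_features"`.
#' @param p_threshold KS acceptance threshold (default 0.05).
#' @param max_iter Maximum draws before giving up (default 1000).
#' @param seed RNG seed for the draw stream.
#' @return List with `city`, `abundance` (the subset), `iterations`,
#'   `ks_p`, and `seed`. If `max_iter` is exhausted an error is thrown
#'   whose condition carries the best (highest-p) subset seen.
#' @export
subsample_city <- function(set, target,
                           alpha_metric = c("fisher_alpha", "shannon",
                                            "observed_features"),
                           p_threshold = 0.05, max_iter = 1000, seed = 1) {
  alpha_metric <- match.arg(alpha_metric)
  x <- set$abundance
  n <- nrow(x)
  if (n <= target) {
    return(list(city = set$city, abundance = x, iterations = 0L,
                ks_p = NA_real_, seed = seed))
  }
  alpha_full <- env_alpha_diversity(set)[[alpha_metric]]
  best_p <- -Inf; best_idx <- NULL
  set.seed(seed)
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, target)
    p <- suppressWarnings(
      stats::ks.test(alpha_full[idx], alpha_full, exact = FALSE)$p.value
    )
    if (p > best_p) { best_p <- p; best_idx <- idx }
    if (p > p_threshold) {
      return(list(city = set$city, abundance = x[idx, , drop = FALSE],
                  iterations = it, ks_p = p, seed = seed))
    }
  }
  cond <- simpleError(sprintf(
    "subsample_city: max_iter = %d exhausted for city '%s' (best KS p = %.4g)",
    max_iter, set$city, best_p
  ))
  cond$best_subset <- list(city = set$city,
                           abundance = x[best_idx, , drop = FALSE],
                           ks_p = best_p, iterations = max_iter, seed = seed)
  stop(cond)
}

#' Per-sample alpha diversity of an environmental sample set
#'
#' Delegates to the gut-index implementations on the environmental matrix.
#'
#' @param set City sample set (list with `city`, `abundance`).
#' @return Data frame with `fisher_alpha`, `shannon`, `observed_features`
#'   per sample.
#' @export
env_alpha_diversity <- function(set) {
  x <- as.matrix(set$abundance)
  data.frame(
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    fisher_alpha = apply(x, 1L, function(r) as.numeric(fisher_alpha(r))),
    shannon = apply(x, 1L, shannon_index),
    observed_features = apply(x, 1L, observed_features),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summed pathogen abundance of one environmental sample
#'
#' @param counts Named abundance vector for one sample.
#' @param lists Pathogen lists (default [default_pathogens()]).
#' @param which `"obligate"` or `"facultative"`.
#' @export
pathogen_load <- function(counts, lists = default_pathogens(),
                          which = c("obligate", "facultative")) {
  which <- match.arg(which)
  sum(counts[intersect(names(counts), lists[[which]])])
}
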