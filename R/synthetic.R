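# Synthetic cohort generator with planted ground truth. Two modes:
# abstract triplets (X, M, Y drawn directly from the structural model, the
# default for statistical validation) and end-to-end cohorts (X shifts
# Dirichlet-multinomial genus counts, the mediator is an index computed
# from those counts).

#' Planted truth for a synthetic mediation triplet
#'
#' Houses the structural coefficients of the mediation model: the
#' exposure-mediator path `a`, the mediator-outcome path `b` (linear units
#' for continuous Y, log-odds per mediator unit for binary Y), and the
#' direct path `c_prime`.
#'
#' @param id Label for the triplet.
#' @param a,b,c_prime Planted path coefficients.
#' @param noise_sd_m Residual SD of the mediator (> 0).
#' @param noise_sd_y Residual SD of a continuous outcome (> 0).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param baseline Intercept (continuous) or baseline log-odds (binary).
#' @param n Cohort size (>= 10).
#' @param seed Integer RNG seed.
#' @param age_coef,sex_coef Small covariate effects on Y so adjustment is
#'   testable (default 0).
#' @return A validated `synthetic_truth` list.
#' @export
synthetic_truth <- function(id = "triplet", a = 0.5, b = 0.4, c_prime = 0.3,
                            noise_sd_m = 1, noise_sd_y = 1,
                            outcome_type = c("continuous", "binary"),
                            baseline = 0, n = 5000, seed = 1,
                            age_coef = 0, sex_coef = 0) {
  outcome_type <- match.arg(outcome_type)
  if (!is.numeric(n) || n < 10) fail_field("n", "must be >= 10")
  if (!is.numeric(noise_sd_m) || noise_sd_m <= 0) {
    fail_field("noise_sd_m", "must be > 0")
  }
  if (!is.numeric(noise_sd_y) || noise_sd_y <= 0) {
    fail_field("noise_sd_y", "must be > 0")
  }
  for (f in c("a", "b", "c_prime", "baseline")) {
    v <- get(f)
    if (!is.numeric(v) || !is.finite(v)) fail_field(f, "must be finite numeric")
  }
  structure(list(
    id = id, a = a, b = b, c_prime = c_prime, noise_sd_m = noise_sd_m,
    noise_sd_y = noise_sd_y, outcome_type = outcome_type,
    baseline = baseline, n = as.integer(n), seed = as.integer(seed),
    age_coef = age_coef, sex_coef = sex_coef
  ), class = "synthetic_truth")
}

# Age ~ Normal(45, 15) truncated to [18, 90], by rejection; sex ~ Bern(0.5).
draw_covariates <- function(n) {
  age <- stats::rnorm(n, 45, 15)
  bad <- which(age < 18 | age > 90)
  while (length(bad)) {
    age[bad] <- stats::rnorm(length(bad), 45, 15)
    bad <- bad[age[bad] < 18 | age[bad] > 90]
  }
  data.frame(age = age, sex = stats::rbinom(n, 1, 0.5))
}

#' Generate one abstract mediation triplet
#'
#' Draws `X ~ N(0, 1)`, `M = a X + e_m`, and either a continuous outcome
#' `Y = baseline + c' X + b M + (covariate terms) + e_y` or a binary outcome
#' `Y ~ Bernoulli(logistic(baseline + c' X + b M + covariate terms))`.
#' Age and sex are drawn independently. Reproducible for a fixed seed.
#'
#' @param truth A [synthetic_truth()] object.
#' @return Data frame with columns `X`, `M`, `Y`, `age`, `sex` of length
#'   `truth$n`.
#' @export
generate_mediation_triplet <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  n <- truth$n
  X <- stats::rnorm(n)
  covs <- draw_covariates(n)
  M <- truth$a * X + stats::rnorm(n, 0, truth$noise_sd_m)
  age_z <- (covs$age - 45) / 15
  lin <- truth$baseline + truth$c_prime * X + truth$b * M +
    truth$age_coef * age_z + truth$sex_coef * covs$sex
  Y <- if (truth$outcome_type == "continuous") {
    lin + stats::rnorm(n, 0, truth$noise_sd_y)
  } else {
    stats::rbinom(n, 1, stats::plogis(lin))
  }
  data.frame(X = X, M = M, Y = Y, age = covs$age, sex = covs$sex)
}

#' Community configuration for the count generator
#'
#' @param taxa Taxon names (defaults to the taxa covered by the shipped
#'   guild/phylum/Gram lookups).
#' @param concentration Dirichlet concentration vector (positive), recycled
#'   to the number of taxa.
#' @param depth Sequencing depth per sample (>= 100).
#' @param effect_taxa Named numeric vector: per-unit-X log-abundance shift
#'   for a subset of taxa.
#' @export
community_config <- function(taxa = names(default_phylum_map()),
                             concentration = 1, depth = 10000,
                             effect_taxa = c(
                               Faecalibacterium = 0.4, Roseburia = 0.4,
                               Coprococcus = 0.3, Eggerthella = -0.3,
                               Klebsiella = -0.3
                             )) {
  concentration <- rep_len(concentration, length(taxa))
  if (any(concentration <= 0)) {
    fail_field("concentration", "must be positive")
  }
  if (depth < 100) fail_field("depth", "must be >= 100")
  if (!all(names(effect_taxa) %in% taxa)) {
    fail_field("effect_taxa", "keys must be a subset of the taxon set")
  }
  list(taxa = taxa, concentration = stats::setNames(concentration, taxa),
       depth = as.integer(depth), effect_taxa = effect_taxa)
}

# Dirichlet-multinomial counts: per-sample Dirichlet weights with the
# effect-taxa concentrations scaled by exp(shift * X_i).
draw_counts <- function(config, X) {
  n <- length(X)
  K <- length(config$taxa)
  shifts <- matrix(0, n, K, dimnames = list(NULL, config$taxa))
  if (length(config$effect_taxa)) {
    shifts[, names(config$effect_taxa)] <-
      outer(X, unname(config$effect_taxa))
  }
  alpha <- sweep(exp(shifts), 2L, config$concentration, `*`)
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  p <- g / rowSums(g)
  counts <- t(apply(p, 1L, function(pr) {
    stats::rmultinom(1L, config$depth, pr)[, 1L]
  }))
  colnames(counts) <- config$taxa
  counts
}

#' Generate a full synthetic cohort (end-to-end mode)
#'
#' Draws continuous and binary exposures, Dirichlet-multinomial genus counts
#' whose composition shifts with the first continuous exposure via
#' `effect_taxa`, computes the butyrate-producer relative abundance from
#' those counts as the realized mediator (the default effect taxa are
#' butyrate producers, so the planted exposure-mediator path is mechanical
#' rather than assumed), and generates continuous and binary outcomes with
#' planted direct (`c_prime`) and mediator (`b`) coefficients plus age/sex
#' covariates. The mediator enters the outcome model centered, so
#' `baseline` is the outcome level at the average community state.
#' Missingness is injected completely at random at the stated per-variable
#' rates.
#'
#' @param n Cohort size.
#' @param config A [community_config()].
#' @param truths List of [synthetic_truth()] objects, one per outcome; the
#'   `a` path of each truth is realized through the count shifts, so only
#'   `b`, `c_prime`, `baseline`, and `outcome_type` are used here.
#' @param n_null_exposures Extra exposure columns with no planted effect.
#' @param missingness Named vector of per-variable missing rates in \[0, 1).
#' @param seed Integer RNG seed.
#' @return List with `cohort` (data frame: participant_id, lat/lon,
#'   sample_year, exposures, age, sex, outcomes), `abundance` (samples x
#'   taxa counts), and `truths`.
#' @export
generate_cohort <- function(n = 1000, config = community_config(),
                            truths = list(
                              synthetic_truth(id = "outcome_cont", b = 5,
                                              c_prime = 0.3,
                                              outcome_type = "continuous"),
                              synthetic_truth(id = "outcome_bin", b = 5,
                                              c_prime = 0.3, baseline = -1,
                                              outcome_type = "binary")
                            ),
                            n_null_exposures = 5,
                            missingness = c(exposure_main = 0.05),
                            seed = 1) {
  if (any(missingness >= 1)) {
    fail_field("missingness", "rates must be < 1")
  }
  set.seed(seed)
  X <- stats::rnorm(n)
  nulls <- matrix(stats::rnorm(n * n_null_exposures), n,
                  dimnames = list(NULL, paste0("exposure_null",
                                               seq_len(n_null_exposures))))
  binary_exp <- stats::rbinom(n, 1, 0.4)
  covs <- draw_covariates(n)
  counts <- draw_counts(config, X)
  rownames(counts) <- sprintf("S%04d", seq_len(n))
  mediator <- apply(counts, 1L, guild_abundance,
                    members = default_guilds()$butyrate)

  age_z <- (covs$age - 45) / 15
  med_c <- mediator - mean(mediator)  # baseline is the value at average M
  outcomes <- lapply(truths, function(tr) {
    lin <- tr$baseline + tr$c_prime * X + tr$b * med_c +
      tr$age_coef * age_z + tr$sex_coef * covs$sex
    if (tr$outcome_type == "continuous") {
      lin + stats::rnorm(n, 0, tr$noise_sd_y)
    } else {
      stats::rbinom(n, 1, stats::plogis(lin))
    }
  })
  names(outcomes) <- vapply(truths, `[[`, character(1), "id")

  cohort <- data.frame(
    participant_id = rownames(counts),
    latitude = stats::runif(n, 25, 49),
    longitude = stats::runif(n, -124, -67),
    sample_year = sample(2013:2017, n, replace = TRUE),
    exposure_main = X, exposure_binary = binary_exp,
    nulls, covs, outcomes,
    stringsAsFactors = FALSE
  )
  for (v in names(missingness)) {
    hit <- stats::runif(n) < missingness[[v]]
    cohort[[v]][hit] <- NA
  }
  list(cohort = cohort, abundance = counts, truths = truths)
}

#' Default species set for synthetic environmental (urban) samples
#'
#' Common built-environment taxa plus several of the obligate and
#' facultative pathogen species whose summed loads the standardization
#' stage reports.
#' @return Character vector of species names.
#' @export
env_taxa <- function() {
  c("Sphingomonas paucimobilis", "Cutibacterium acnes",
    "Micrococcus luteus", "Moraxella osloensis", "Bacillus subtilis",
    "Corynebacterium glutamicum", "Deinococcus radiodurans",
    "Paracoccus denitrificans", "Rhodococcus erythropolis",
    "Stenotrophomonas maltophilia", "Acinetobacter johnsonii",
    "Janthinobacterium lividum",
    # facultative pathogens
    "Escherichia coli", "Staphylococcus aureus", "Pseudomonas aeruginosa",
    "Klebsiella pneumoniae", "Enterococcus faecalis",
    "Streptococcus pneumoniae",
    # obligate pathogens (rare on surfaces but screened for)
    "Salmonella enterica", "Campylobacter jejuni",
    "Listeria monocytogenes", "Streptococcus pyogenes")
}

#' Generate per-city environmental sample sets
#'
#' Fixture generator for the standardization stage: each city's samples x
#' taxa count matrix is drawn from a shared Dirichlet-multinomial unless a
#' per-city concentration is supplied. The default taxon set ([env_taxa()])
#' mixes built-environment species with listed pathogens so the pathogen
#' load summaries are exercised; the obligate pathogens get a much smaller
#' concentration than the rest of the community.
#'
#' @param sizes Integer vector of per-city sample counts (positive).
#' @param config A [community_config()] (effect taxa ignored).
#' @param city_concentration Optional list (per city) of concentration
#'   vectors to make cities distributionally distinct.
#' @param seed Integer RNG seed.
#' @return List of city sample sets: `city`, `abundance`.
#' @export
generate_city_samples <- function(sizes,
                                  config = community_config(
                                    taxa = env_taxa(),
                                    concentration = c(rep(1, 18),
                                                      rep(0.05, 4)),
                                    effect_taxa = numeric(0)
                                  ),
                                  city_concentration = NULL, seed = 1) {
  if (any(sizes < 1)) fail_field("sizes", "must be positive integers")
  set.seed(seed)
  lapply(seq_along(sizes), function(i) {
    cfg <- config
    if (!is.null(city_concentration)) {
      cfg$concentration <- rep_len(city_concentration[[i]],
                                   length(cfg$taxa))
      names(cfg$concentration) <- cfg$taxa
    }
    cfg$effect_taxa <- numeric(0)
    counts <- draw_counts(cfg, rep(0, sizes[i]))
    rownames(counts) <- sprintf("city%02d_s%03d", i, seq_len(sizes[i]))
    list(city = sprintf("city%02d", i), abundance = counts)
  })
}
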