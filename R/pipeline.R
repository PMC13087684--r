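# End-to-end orchestration: synthesize (or read) inputs, filter, compute
# indices, screen, mediate, and write stage outputs with a JSON manifest
# carrying seeds, counts, and a config hash.

#' Read / write tab-delimited tables
#'
#' Plain UTF-8 TSV with a header row; the interchange format for every
#' pipeline stage.
#' @param path File path.
#' @param x Data frame to write.
#' @name tsv_io
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname tsv_io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the defaults used
#' throughout: 50% missingness filters, |rho| > 0.85 Spearman pruning,
#' FDR < 0.05 with adjusted R^2 > 0.005 for the dual screen criterion,
#' KS p > 0.05 for the environmental subsampler, and age/sex adjustment in
#' mediation.
#'
#' @param n Synthetic cohort size.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param var_missing,sample_missing Missingness thresholds.
#' @param spearman_cutoff Collinearity pruning cutoff.
#' @param fdr_cut,r2_cut Dual-criterion thresholds.
#' @param fdr_family `"per_dv"` or `"global"`.
#' @param n_boot Bootstrap resamples for continuous mediation.
#' @param covariates Covariate column names adjusted for in mediation.
#' @param alpha Significance level for the direct path.
#' @export
run_config <- function(n = 600, seed = 1, out_dir = tempfile("mmrun"),
                       var_missing = 0.5, sample_missing = 0.5,
                       spearman_cutoff = 0.85, fdr_cut = 0.05,
                       r2_cut = 0.005, fdr_family = "per_dv",
                       n_boot = 1000, covariates = c("age", "sex"),
                       alpha = 0.05) {
  cfg <- list(
    n = n, seed = as.integer(seed), out_dir = out_dir,
    var_missing = var_missing, sample_missing = sample_missing,
    spearman_cutoff = spearman_cutoff, fdr_cut = fdr_cut, r2_cut = r2_cut,
    fdr_family = fdr_family, n_boot = n_boot, covariates = covariates,
    alpha = alpha
  )
  stopifnot(var_missing > 0, var_missing <= 1, fdr_cut > 0, fdr_cut < 1,
            r2_cut >= 0, spearman_cutoff > 0, spearman_cutoff <= 1)
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[sort(names(config))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic cohort with planted effects, applies the
#' missingness filters and collinearity pruning, computes the ten mediator
#' indices, screens exposure-mediator and exposure-outcome associations
#' under the dual criterion, selects and runs all eligible mediation
#' triplets, and writes every stage table plus a JSON manifest (counts per
#' stage, seeds, config hash) to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest`, `indices`, `screens`,
#'   `triplets`, `mediation`, and the generated `data`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  data <- generate_cohort(n = config$n, seed = sub_seed(config$seed, 1L))
  cohort <- data$cohort
  n_in <- nrow(cohort)

  filtered <- filter_missing(cohort, config$var_missing,
                             config$sample_missing)
  exp_cols <- grep("^exposure", names(filtered), value = TRUE)
  prune <- spearman_prune(filtered[exp_cols], config$spearman_cutoff)
  exp_cols <- prune$kept

  abund <- data$abundance[filtered$participant_id, , drop = FALSE]
  idx <- compute_indices(abund)

  out_cols <- grep("^outcome", names(filtered), value = TRUE)
  m_screen <- screen_associations(filtered[exp_cols],
                                  idx[index_names()],
                                  fdr_cut = config$fdr_cut,
                                  r2_cut = config$r2_cut,
                                  fdr_family = config$fdr_family)
  y_screen <- screen_associations(filtered[exp_cols], filtered[out_cols],
                                  fdr_cut = config$fdr_cut,
                                  r2_cut = config$r2_cut,
                                  fdr_family = config$fdr_family)
  triplets <- select_triplets(m_screen, y_screen)

  outcome_type <- function(y) {
    if (all(stats::na.omit(filtered[[y]]) %in% c(0, 1))) "binary"
    else "continuous"
  }
  med_rows <- lapply(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    covs <- filtered[config$covariates]
    res <- if (outcome_type(tr$y) == "binary") {
      mediate_binary(filtered[[tr$x]], idx[[tr$m]], filtered[[tr$y]],
                     covariates = covs, seed = sub_seed(config$seed, 100L + i))
    } else {
      mediate_continuous(filtered[[tr$x]], idx[[tr$m]], filtered[[tr$y]],
                         covariates = covs, n_boot = config$n_boot,
                         seed = sub_seed(config$seed, 100L + i))
    }
    cbind(tr, as.data.frame(res))
  })
  mediation <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame()

  class_counts <- if (nrow(mediation)) {
    as.list(table(mediation$classification))
  } else {
    list()
  }
  manifest <- list(
    config_hash = hash, seed = config$seed,
    n_samples_in = n_in, n_samples_kept = nrow(filtered),
    n_samples_dropped = n_in - nrow(filtered),
    variables_dropped_missingness =
      as.character(attr(filtered, "dropped_variables")),
    exposures_dropped_collinearity = prune$dropped,
    n_exposures = length(exp_cols),
    n_mediators = length(index_names()),
    n_outcomes = length(out_cols),
    fdr_family = config$fdr_family,
    associations_mediator = sum(m_screen$results$significant),
    associations_outcome = sum(y_screen$results$significant),
    triplets_tested = nrow(triplets),
    mediations_by_class = class_counts
  )

  write_tsv_table(filtered, file.path(config$out_dir, "cohort_filtered.tsv"))
  write_tsv_table(idx, file.path(config$out_dir, "indices.tsv"))
  write_tsv_table(m_screen$results,
                  file.path(config$out_dir, "screen_mediators.tsv"))
  write_tsv_table(y_screen$results,
                  file.path(config$out_dir, "screen_outcomes.tsv"))
  if (nrow(mediation)) {
    write_tsv_table(mediation, file.path(config$out_dir, "mediation.tsv"))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, indices = idx,
                 screens = list(mediator = m_screen, outcome = y_screen),
                 triplets = triplets, mediation = mediation, data = data))
}
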