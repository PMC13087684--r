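# Exposure derivation: questionnaire coding, missingness filters,
# collinearity pruning, exposure windows, mycotoxin dose estimation,
# and city assignment.

#' Numeric coding of questionnaire responses
#'
#' Converts a raw questionnaire response to its numeric code. Binary
#' yes/true and no/false responses map to 1 and 0. Food/activity frequency
#' categories map to average daily occurrences: "never" = 0, "rarely" =
#' 2/30.4 (about 0.066, two occurrences per month), "occasionally" = 1.5/7
#' (about 0.214), "often" = 4/7 (about 0.571), "every day" = 1. Ordinal
#' questions map to 0..N-1 in the supplied option order. Exact quotients are
#' stored, not their 3-decimal printed values, so downstream regressions do
#' not compound rounding.
#'
#' @param question_kind One of `"binary"`, `"frequency"`, or `"ordinal"`.
#' @param raw_response Character response (or numeric, returned unchanged).
#' @param options For `ordinal` questions, the character vector giving the
#'   option order; codes are `0:(length(options) - 1)`.
#' @return A numeric code.
#' @examples
#' code_response("frequency", "rarely")   # 2/30.4 ~= 0.066
#' code_response("frequency", "often")    # 4/7   ~= 0.571
#' code_response("binary", "yes")         # 1
#' code_response("ordinal", "moderate", options = c("low", "moderate", "high"))
#' @export
code_response <- function(question_kind, raw_response, options = NULL) {
  if (is.numeric(raw_response)) return(as.numeric(raw_response)) # idempotent
  kind <- match.arg(question_kind, c("binary", "frequency", "ordinal"))
  resp <- tolower(trimws(as.character(raw_response)))
  vocab <- switch(kind,
    binary = c(yes = 1, "true" = 1, no = 0, "false" = 0),
    frequency = c(
      never = 0, rarely = 2 / 30.4, occasionally = 1.5 / 7,
      often = 4 / 7, "every day" = 1, daily = 1
    ),
    ordinal = {
      if (is.null(options)) {
        stop("ordinal questions require `options` giving the option order",
             call. = FALSE)
      }
      stats::setNames(seq_along(options) - 1, tolower(trimws(options)))
    }
  )
  if (!resp %in% names(vocab)) {
    stop(sprintf(
      "unknown %s response '%s'; allowed: %s",
      kind, raw_response, paste(sQuote(names(vocab)), collapse = ", ")
    ), call. = FALSE)
  }
  unname(vocab[[resp]])
}

#' Two-step missingness filter for a cohort table
#'
#' Variable-first filtering: variables missing in strictly more than
#' `var_threshold` of participants are dropped, then participants missing
#' strictly more than `sample_threshold` of the remaining variables are
#' dropped. `id_cols` are never counted or dropped.
#'
#' @param table Data frame of participants x variables.
#' @param var_threshold,sample_threshold Missing-fraction cutoffs in (0, 1].
#' @param id_cols Column names excluded from the missingness accounting.
#' @return The filtered data frame with attributes `dropped_variables`,
#'   `dropped_participants`, and (if nothing survives) an `empty_result`
#'   flag instead of an error.
#' @export
filter_missing <- function(table, var_threshold = 0.5, sample_threshold = 0.5,
                           id_cols = intersect("participant_id", names(table))) {
  stopifnot(var_threshold > 0, var_threshold <= 1,
            sample_threshold > 0, sample_threshold <= 1)
  vars <- setdiff(names(table), id_cols)
  var_miss <- vapply(table[vars], function(v) mean(is.na(v)), numeric(1))
  drop_vars <- vars[var_miss > var_threshold]
  keep_vars <- setdiff(vars, drop_vars)
  out <- table[, c(id_cols, keep_vars), drop = FALSE]

  if (length(keep_vars)) {
    samp_miss <- rowMeans(is.na(out[, keep_vars, drop = FALSE]))
  } else {
    samp_miss <- rep(1, nrow(out))
  }
  drop_rows <- which(samp_miss > sample_threshold)
  dropped_ids <- if (length(id_cols)) {
    out[[id_cols[1L]]][drop_rows]
  } else {
    drop_rows
  }
  if (length(drop_rows)) out <- out[-drop_rows, , drop = FALSE]

  attr(out, "dropped_variables") <- drop_vars
  attr(out, "dropped_participants") <- dropped_ids
  if (nrow(out) == 0L || length(keep_vars) == 0L) {
    out <- set_flag(out, "empty_result")
  }
  out
}

#' Prune collinear variables by Spearman rank correlation
#'
#' Scans all variable pairs with `|rho| > cutoff` in descending `|rho|` and
#' drops one member of each still-active pair: the member with more missing
#' values, ties broken toward the lexicographically later name. Constant
#' variables have undefined rank correlations; those pairs are treated as
#' below the cutoff and a warning is logged.
#'
#' @param x Numeric data frame or matrix of candidate variables.
#' @param cutoff Absolute Spearman correlation above which a pair is pruned.
#' @return List with `kept`, `dropped`, and a `log` data frame recording
#'   each decision (pair, rho, which member was dropped).
#' @export
spearman_prune <- function(x, cutoff = 0.85) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  vars <- names(x)
  const <- vapply(x, function(v) stats::var(v, na.rm = TRUE) %in% c(0, NA) ||
                    is.na(stats::var(v, na.rm = TRUE)), logical(1))
  if (any(const)) {
    warning("constant variable(s) with undefined rank correlation: ",
            paste(vars[const], collapse = ", "), call. = FALSE)
  }
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  n_miss <- vapply(x, function(v) sum(is.na(v)), integer(1))

  pairs <- which(upper.tri(rho) & !is.na(rho) & abs(rho) > cutoff,
                 arr.ind = TRUE)
  log <- data.frame(var1 = character(), var2 = character(),
                    rho = numeric(), dropped = character(),
                    stringsAsFactors = FALSE)
  dropped <- character()
  if (nrow(pairs)) {
    ord <- order(-abs(rho[pairs]), vars[pairs[, 1L]], vars[pairs[, 2L]])
    pairs <- pairs[ord, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      v1 <- vars[pairs[r, 1L]]; v2 <- vars[pairs[r, 2L]]
      if (v1 %in% dropped || v2 %in% dropped) next
      loser <- if (n_miss[[v1]] > n_miss[[v2]]) v1
               else if (n_miss[[v2]] > n_miss[[v1]]) v2
               else max(v1, v2)  # lexicographically later name
      dropped <- c(dropped, loser)
      log <- rbind(log, data.frame(var1 = v1, var2 = v2,
                                   rho = rho[pairs[r, 1L], pairs[r, 2L]],
                                   dropped = loser,
                                   stringsAsFactors = FALSE))
    }
  }
  list(kept = setdiff(vars, dropped), dropped = dropped, log = log)
}

#' Three-year exposure window average
#'
#' Averages an environmental exposure series over the three calendar years
#' immediately preceding the sample year. If any of those three years is
#' absent, the three most recent available years strictly before the sample
#' year are used instead (flagged `fallback`); fewer than three available
#' years are averaged as-is and flagged `short_window`; no preceding years
#' at all yields a flagged missing value.
#'
#' @param series Named numeric vector, names = calendar years.
#' @param sample_year Calendar year of sample collection.
#' @return Numeric value with attributes `years_used`, and flags
#'   `fallback` / `short_window` / `no_data` where applicable.
#' @export
average_three_year_window <- function(series, sample_year) {
  yrs <- as.integer(names(series))
  stopifnot(!anyNA(yrs))
  want <- sample_year - (1:3)
  prior <- sort(yrs[yrs < sample_year], decreasing = TRUE)
  if (length(prior) == 0L) {
    return(set_flag(set_flag(NA_real_, "no_data"), "years_used", integer()))
  }
  if (all(want %in% yrs)) {
    used <- want
    out <- mean(series[as.character(want)])
  } else {
    used <- prior[seq_len(min(3L, length(prior)))]
    out <- mean(series[as.character(used)])
    out <- set_flag(out, "fallback")
    if (length(used) < 3L) out <- set_flag(out, "short_window")
  }
  set_flag(out, "years_used", used)
}

#' Regional representative mycotoxin concentration
#'
#' The representative concentration of toxin k in region j is the detection
#' rate times the median concentration among positive samples:
#' `C_jk = D_jk * M_jk` (ug/kg).
#'
#' @param detection_rate Detection rate in \[0, 1\].
#' @param median_concentration Median concentration (ug/kg, >= 0).
#' @export
regional_concentration <- function(detection_rate, median_concentration) {
  if (any(detection_rate < 0 | detection_rate > 1, na.rm = TRUE)) {
    fail_field("detection_rate", "must lie in [0, 1]")
  }
  if (any(median_concentration < 0, na.rm = TRUE)) {
    fail_field("median_concentration", "must be >= 0")
  }
  detection_rate * median_concentration
}

#' Individual mycotoxin exposure estimate
#'
#' Weighted dietary dose `E_ik = C_jk * sum_f(F_if * W_f)` (ug/day), where
#' `F` are coded intake frequencies (times/day) for the grain, dairy, and
#' nut food groups and `W` the dimensionless weights reflecting each group's
#' contamination risk hierarchy; defaults W = (0.5, 0.3, 0.2).
#'
#' @param concentration Regional representative concentration (ug/kg).
#' @param frequencies Numeric length-3 vector `(grains, dairy, nuts)` of
#'   coded intake frequencies (>= 0).
#' @param weights Length-3 weights; default `c(0.5, 0.3, 0.2)`.
#' @export
individual_mycotoxin_exposure <- function(concentration, frequencies,
                                          weights = c(0.5, 0.3, 0.2)) {
  if (any(concentration < 0, na.rm = TRUE)) {
    fail_field("concentration", "must be >= 0")
  }
  if (any(frequencies < 0, na.rm = TRUE)) {
    fail_field("frequencies", "must be >= 0")
  }
  stopifnot(length(frequencies) == 3L, length(weights) == 3L)
  concentration * sum(frequencies * weights)
}

#' Assign a participant to a city center within 5 km
#'
#' Great-circle (haversine, mean Earth radius 6371 km) distance from the
#' participant to every center; the participant is assigned to the nearest
#' center at distance <= `radius_km`, ties broken by lexicographic city id,
#' or to none.
#'
#' @param lat,lon Participant coordinates (decimal degrees, WGS84).
#' @param centers Data frame with columns `city`, `lat`, `lon`.
#' @param radius_km Assignment radius in km (default 5).
#' @return The city id, or `NA_character_` if no center qualifies.
#' @export
assign_city <- function(lat, lon, centers, radius_km = 5) {
  if (abs(lat) > 90) fail_field("lat", "must lie in [-90, 90]")
  if (abs(lon) > 180) fail_field("lon", "must lie in [-180, 180]")
  stopifnot(all(c("city", "lat", "lon") %in% names(centers)))
  d_km <- geosphere::distHaversine(
    c(lon, lat), cbind(centers$lon, centers$lat), r = 6371000
  ) / 1000
  ok <- which(d_km <= radius_km)
  if (!length(ok)) return(NA_character_)
  ok <- ok[order(d_km[ok], as.character(centers$city)[ok])]
  as.character(centers$city)[ok[1L]]
}
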