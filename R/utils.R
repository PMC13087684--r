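#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a validation message naming the offending field
#' @noRd
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Attach a flag to a value without changing its class semantics
#' @noRd
set_flag <- function(x, flag, value = TRUE) {
  attr(x, flag) <- value
  x
}

has_flag <- function(x, flag) isTRUE(attr(x, flag))

#' Derive a reproducible 32-bit sub-seed from a base seed and a stream index
#' @noRd
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2039L + as.integer(k) %% 2039L
}

#' Listwise-complete row index over a set of vectors/data frame columns
#' @noRd
complete_rows <- function(...) {
  cols <- list(...)
  ok <- rep(TRUE, length(cols[[1L]]))
  for (v in cols) ok <- ok & !is.na(v)
  which(ok)
}
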