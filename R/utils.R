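# Internal helpers shared across modules.

#' Evaluate code with a local random seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so stochastic generators take explicit seeds without touching
#' global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Check a repetition-time schedule
#'
#' @param trs Numeric vector of repetition times in seconds.
#' @keywords internal
check_tr_schedule <- function(trs) {
  if (!is.numeric(trs) || length(trs) < 1L) {
    stopf("tr_schedule must be a non-empty numeric vector")
  }
  if (any(trs <= 0)) {
    stopf("tr_schedule entries must be > 0; offending entries: %s",
          paste(format(trs[trs <= 0]), collapse = ", "))
  }
  bad <- which(diff(trs) <= 0)
  if (length(bad)) {
    pairs <- vapply(bad, function(i) sprintf("%g >= %g", trs[i], trs[i + 1L]),
                    character(1))
    stopf("tr_schedule must be strictly increasing; offending entries: %s",
          paste(pairs, collapse = "; "))
  }
  invisible(trs)
}
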