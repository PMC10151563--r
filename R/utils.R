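# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporarily fixed RNG state
#'
#' Pins the generator kind (Mersenne-Twister / Inversion / Rejection) so that
#' draws are reproducible across platforms, runs `code`, then restores the
#' caller's RNG state.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state as-is.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit(do.call(RNGkind, as.list(old_kind)), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a master seed; stays below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i) %% 2147483647)
}

stop_msi <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_msi(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    stop_msi(sprintf("'%s' must be a %s integer", name,
                     if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

# Longest run of a given character in a string.
max_char_run <- function(s, ch) {
  r <- rle(strsplit(s, "")[[1]])
  hits <- r$lengths[r$values == ch]
  if (length(hits) == 0L) 0L else max(hits)
}
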