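# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Saves and restores `.Random.seed` so seeded routines are pure functions of
#' their inputs and never perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

# Deterministic per-fold seed derived from a run seed, kept inside 32-bit
# integer range. `salt` separates independent consumers (OCC vs TCC folds,
# model fits vs splits).
derive_seed <- function(seed, index, salt = 0L) {
  base <- (as.double(seed) %% 2147483647) + 1
  s <- (base * 48271 + index * 69621 + salt * 30269) %% 2147483647
  as.integer(s)
}

# Fixed float formatting used by all writers: 6 significant digits, no
# scientific notation surprises across platforms.
format_num <- function(x) {
  out <- formatC(x, digits = 6L, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

stop_ctx <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}
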