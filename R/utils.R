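# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG with `seed`, evaluates `expr`, and restores the
#' previous RNG state on exit, so package functions never perturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

stop_validation <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_validation("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

is_proportion <- function(x) is.na(x) | (x >= 0 & x <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
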