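# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}

# scalar numeric check with a named reason, used by config validators
check_scalar <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (strict_min && x <= min) {
    rlang::abort(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    rlang::abort(sprintf("`%s` must be >= %s", name, format(min)))
  }
  if (x > max) {
    rlang::abort(sprintf("`%s` must be <= %s", name, format(max)))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    rlang::abort(sprintf("`%s` must be a whole number", name))
  }
  invisible(x)
}

# Deterministic derived seeds: keeps independent stages reproducible from one
# global seed without sharing a stream. Stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %%
               (.Machine$integer.max - 1L)) + 1L
}

with_seed <- function(seed, code) {
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
  force(code)
}
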