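# Internal helpers shared across modules.

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic seed splitting: every stochastic routine draws its own seed
#' from the master seed plus a purpose string, so independent stages never
#' share or reuse RNG streams. The result is always below 2^31 - 1 (a valid
#' R integer).
#'
#' @param seed Master seed (single number).
#' @param key Purpose string naming the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_input <- function(msg, class = "canopyn_input_error") {
  rlang::abort(msg, class = class)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    stop_input(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_input(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    stop_input(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}
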