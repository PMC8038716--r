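#' Round half away from zero
#'
#' Presentation rounding used throughout the package outputs. Base R's
#' `round()` rounds half to even; reported tables in this field use the
#' conventional "round half up" (away from zero for negatives), so 0.19955
#' prints as 0.1995 -> 0.1996 and -2.8214 at 3 decimals prints as -2.821.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministically derives independent 31-bit sub-seeds so that each
#' stochastic sub-model (collapse draws, fire origins, fire spread, start
#' times, batch runs) has its own stream: toggling one hazard does not shift
#' another's draws.
#'
#' @param master integer master seed
#' @param index integer stream index (>= 1)
#' @return a single integer seed in [0, 2^31)
#' @export
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1, length(index) == 1, index >= 1)
  # splitmix-style integer scramble, kept in 31-bit signed range
  x <- (as.double(master) %% 2147483647) + 1
  for (i in seq_len(index)) {
    x <- (x * 48271) %% 2147483647
  }
  as.integer(floor(x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so library
#' internals never perturb user RNG state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# small stable content hash (FNV-1a over the serialized text) used to stamp
# outputs with the configuration they came from
config_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
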