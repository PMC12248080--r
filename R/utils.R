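# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a dataset seed
#'
#' Generators that need several independent random streams derive one child
#' seed per stream from a single dataset seed, so that a dataset is fully
#' reproducible from one integer while its streams stay decoupled.
#'
#' @param seed integer dataset seed.
#' @param stream integer stream index (>= 1).
#' @return an integer in `[0, 2^31)` usable with [set.seed()].
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stream), length(stream) == 1, stream >= 0)
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  # LCG scramble; constants fit in double-precision exact integer range
  x <- (x * 48271 + 2654435769 * (as.numeric(stream) + 1)) %% m
  as.integer(x)
}

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

stop_taildyn <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "taildyn_error")))
}
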