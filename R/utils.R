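`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed
#'
#' Every stochastic operation in the package draws its randomness from a
#' child seed derived from one global integer seed and a short text tag, so
#' each stage is independently reproducible.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the operation (and, e.g., a variable).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(tag) == 1)
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 69621 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_sm <- function(...) stop(sprintf(...), call. = FALSE)

warn_sm <- function(...) warning(sprintf(...), call. = FALSE)
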