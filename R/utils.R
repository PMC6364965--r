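#' Derive a child seed from a master seed
#'
#' Hierarchical splitting of random streams: each (master, path) combination
#' maps to a fixed 31-bit seed, so e.g. site 7's weather stream is unchanged
#' when more sites are added to a configuration. Path components may be
#' integers or short strings.
#'
#' @param master integer master seed.
#' @param ... path components (integers or character scalars).
#' @return an integer in [1, 2^31 - 2] suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  s <- as.double(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- utf8ToInt(p) else p <- as.double(p)
    for (x in p) {
      # LCG-style fold; constants from Numerical Recipes ranqd1
      s <- (s * 69069 + x + 1013904223) %% 2147483647
    }
  }
  as.integer(s %% 2147483646 + 1)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}
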