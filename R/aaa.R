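#' The seven torsion features, in canonical order
#'
#' Fixed feature order used throughout: tie-breaks in tree splitting, CSV
#' column order and report layout all follow it.
#' @export
ANGLE_NAMES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")

# run expr under an explicit seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
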