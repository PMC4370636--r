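#' Derive a reproducible sub-stream seed
#'
#' All randomized stages take one master seed and derive per-unit seeds from
#' it, so that (for example) per-site null distributions do not depend on
#' the order sites are processed in. The derivation is a 31-bit polynomial
#' hash of the master seed and a label (a site id, a stage name, a replicate
#' number), always below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Character or integer scalar naming the sub-stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  bytes <- utf8ToInt(paste0(as.character(label)))
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# run expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
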