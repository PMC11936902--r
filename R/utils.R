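## Internal helpers: argument checks and seeded evaluation.

assertRaster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", name), call. = FALSE)
  if (any(dim(x) < 2L))
    stop(sprintf("%s must be at least 2 x 2", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", name), call. = FALSE)
  invisible(x)
}

assertIntensityRaster <- function(x, name = deparse(substitute(x))) {
  assertRaster(x, name)
  if (min(x) < 0 || max(x) > 1)
    stop(sprintf("%s intensities must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

assertMask <- function(x, name = deparse(substitute(x))) {
  assertRaster(x, name)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (values in {0,1})", name),
         call. = FALSE)
  invisible(x)
}

assertSameShape <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

## Evaluate expr under a temporary RNG state; restores (or removes) the
## caller's .Random.seed so package functions never disturb the session RNG.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Derive deterministic sub-seeds (< 2^31) from a master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
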