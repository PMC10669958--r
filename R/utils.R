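# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertGeometryMatch <- function(a, b, what = "inputs") {
  if (!all(dim(a@data) == dim(b@data)))
    stop(sprintf("%s have mismatching grid shapes (%s vs %s)", what,
                 paste(dim(a@data), collapse = "x"),
                 paste(dim(b@data), collapse = "x")))
  if (max(abs(a@spacing - b@spacing)) > 1e-9)
    stop(sprintf("%s have mismatching voxel spacing", what))
  invisible(TRUE)
}

# clamp continuous values into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic child seeds below 2^31 from one master seed
.spawnSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(masterSeed %% .Machine$integer.max)
  sample.int(2147483646L, n)
}

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
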