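# Internal helpers: seeded random streams, argument checks, coordinates.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generator entry points use this so a
# single SimConfig seed gives bit-identical output regardless of what the
# session RNG was doing.
with_stream <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Child seed for a named generator stage, derived from the master seed by a
# fixed offset so stages are reproducible independently of call order.
child_seed <- function(seed, stage) {
  offsets <- c(chromatin = 101L, tracks = 202L, movie = 303L,
               coalescence = 404L, phase = 505L, frap = 606L)
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) + offsets[[stage]]) %% 2147483647
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

# 0-based pixel index convention: the physical coordinate of pixel centre
# (i, j) (R's 1-based row/col) is ((i - 1) + 0.5) * pixel_size.
px_to_um <- function(idx1, pixel_size) (idx1 - 0.5) * pixel_size
um_to_px <- function(um, pixel_size) um / pixel_size + 0.5

`%||%` <- function(a, b) if (is.null(a)) b else a
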