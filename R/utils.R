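# Internal helpers shared across modules.

# Run `code` under a temporarily-seeded RNG, restoring the caller's RNG state.
# All stochastic functions in the package route their randomness through this,
# so results are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Even-odd ray-casting point-in-polygon test; polygon is a two-column matrix
# of vertices (closed implicitly). Points on edges are treated as inside.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]
  py <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
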