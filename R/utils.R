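# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
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
  force(code)
}

# Nearest-point snap of continuous times onto the simulation grid {0, dt, ...}.
# Exact half-way ties round DOWN (towards the earlier grid point); the
# learning rule samples efficacy functions at these snapped times.
snap_index <- function(t, dt) {
  r <- t / dt
  i <- floor(r + 0.5)
  frac <- r - floor(r)
  tie <- frac == 0.5
  i[tie] <- floor(r[tie])
  as.integer(i)
}

stop_usage <- function(...) {
  stop(structure(
    class = c("usage_error", "error", "condition"),
    list(message = sprintf(...), call = NULL)
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}
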