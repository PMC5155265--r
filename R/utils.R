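# internal helpers shared across modules

# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("direction must be non-zero", call. = FALSE)
  v / n
}

# orthonormal rotation R such that R %*% d = (0, 0, 1)
rotation_to_z <- function(d) {
  d <- unit3(d)
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  rbind(u, v, d, deparse.level = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
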