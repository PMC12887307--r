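# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One Dirichlet draw; zero-concentration components stay exactly zero.
rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a <= 0) 0 else stats::rgamma(1L, shape = a), 0)
  if (sum(g) <= 0) stop("degenerate Dirichlet draw: all concentrations are zero")
  g / sum(g)
}

# Shannon entropy (nats) of a non-negative weight vector.
shannon_entropy <- function(x) {
  x <- x[x > 0]
  if (!length(x)) stop("shannon_entropy() needs at least one positive weight")
  p <- x / sum(x)
  -sum(p * log(p))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
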