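# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Used to give each stochastic component of
# the simulator its own named substream derived from one master seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream name.
# A small string hash keeps substreams (sources, mixing, noise, counts, ...)
# independent of each other while the whole run stays a function of one seed.
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

stopif_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
}

stopif_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# Symmetric positive semi-definiteness check used for noise covariances.
check_psd <- function(S, name = "noise_cov", tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(sprintf("`%s` must be positive semi-definite", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Source-state index for a 2 x T matrix of binary sources.
# States are ordered (0,0), (1,0), (0,1), (1,1) -> 1..4 throughout the package.
state_index <- function(u) {
  if (!is.matrix(u) || nrow(u) != 2L) stop("`u` must be a 2 x n_events matrix", call. = FALSE)
  as.integer(1L + u[1L, ] + 2L * u[2L, ])
}

state_labels <- function() c("u00", "u10", "u01", "u11")

`%||%` <- function(a, b) if (is.null(a)) b else a
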