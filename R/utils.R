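# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error classes.
stop_fflnet <- function(msg, class = "fflnet_error", ...) {
  rlang::abort(msg, class = c(class, "fflnet_error"), ...)
}

# z-score of a numeric vector; constant vectors map to all-zero (the score is
# used additively, so a degenerate feature contributes nothing).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All package randomness funnels through this.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific 31-bit sub-seed so independent stages fed from one
# master seed do not share RNG streams.
derive_seed <- function(seed, stream) {
  offsets <- c(
    expression = 11L, catalog = 23L, clinical = 37L, methylation = 43L,
    cnv = 53L, noise = 67L, permutation = 79L, pipeline = 97L
  )
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 2654435761 + off) %% 2147483647)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x != floor(x)) {
    stop_fflnet(sprintf("`%s` must be a single positive integer, got %s", name, deparse(x)))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_fflnet(sprintf("`%s` must be a single value in [0, 1]", name))
  }
  as.double(x)
}
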