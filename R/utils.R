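# Internal helpers: seeded evaluation and seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Counter-based derivation of per-run seeds from a master seed.
# Stays within the 32-bit integer range and is injective for
# index < 1000003 at fixed master.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((abs(as.numeric(master)) * 1000003 + as.numeric(index)) %% 2147483647)
}

# Fast median/MAD without S3 dispatch overhead (hot paths of the
# permutation FDR and s0 search).
fmedian <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  if (n == 2L) return((x[1] + x[2]) / 2)
  if (n == 3L) { # median-of-three without sorting
    a <- x[1]; b <- x[2]; c <- x[3]
    return(max(min(a, b), min(max(a, b), c)))
  }
  h <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(x, partial = h)[h]
  } else {
    xs <- sort.int(x, partial = c(h, h + 1L))
    (xs[h] + xs[h + 1L]) / 2
  }
}

fmad <- function(x) 1.4826 * fmedian(abs(x - fmedian(x)))

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
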