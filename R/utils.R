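# Small internal helpers shared across modules.

# Round a price UP to the next cent. Rounding down in floor/markup inversions
# would violate the feasibility constraint (burden < 100%, profit >= cost);
# the 1e-9 slack only absorbs binary floating-point noise so that amounts
# that are mathematically an exact cent are not pushed up a cent.
round_up_cent <- function(x) ceiling(x * 100 - 1e-9) / 100

weighted_mean <- function(x, w) {
  if (sum(w) == 0) return(NA_real_)
  sum(x * w) / sum(w)
}

# Run code with a locally seeded, fully specified RNG so identical seeds give
# byte-identical output regardless of the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
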