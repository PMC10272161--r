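# Internal helpers shared across modules.

# Derive a child seed from a parent seed and a stream label, so one global
# seed fans out to independent per-generator substreams. Kept below 2^31-1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Count events in a half-open window [a, b).
count_in_window <- function(times, a, b) {
  sum(times >= a & times < b)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}
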