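# Deterministic seed substreams.  All randomness in the package flows from a
# single experiment seed; each stage/subject derives its own substream seed by
# hashing the parent seed together with a string key, so fixtures are
# reproducible and statistically independent across stages.

#' Derive a substream seed
#'
#' Hashes a parent seed and one or more key strings (stage name, subject id,
#' repetition index, ...) into a new seed in `[0, 2^31 - 2]`.  The same
#' arguments always yield the same seed.
#'
#' @param seed parent integer seed.
#' @param ... key components, coerced to character.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, "")), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
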