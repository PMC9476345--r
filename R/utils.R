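# Seed plumbing shared by the generators and the pipeline. All stage seeds
# derive deterministically from one global seed; the caller's RNG state is
# always restored.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a global seed and a short tag; stays < 2^31.
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 10007 + h * 131) %% 2147483629)
}

.isTrue <- function(x) isTRUE(as.logical(x))
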