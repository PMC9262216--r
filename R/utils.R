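# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    expr
}

# Derive a deterministic child seed from a root seed and a stream label,
# kept inside the 32-bit signed integer range.
deriveSeed <- function(seed, stream) {
    h <- rlang::hash(list(as.integer(seed), as.character(stream)))
    bits <- strtoi(substr(h, 1L, 7L), base = 16L)
    as.integer(bits %% .Machine$integer.max)
}

stopIf <- function(cond, ...) {
    if (cond) stop(sprintf(...), call. = FALSE)
}
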