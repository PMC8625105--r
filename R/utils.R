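## Seed handling: every stochastic operation in the package runs inside
## withSeed(), so generation is deterministic per seed and never leaks state
## into (or depends on) the caller's random number stream.

withSeed <- function(seed, expr) {
    if (is.null(seed) || !is.finite(seed))
        stopEem("eemBadConfig", "a finite integer seed is required")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## derive a sub-seed for a pipeline stage; kept below 2^31
deriveSeed <- function(seed, offset) {
    (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}
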