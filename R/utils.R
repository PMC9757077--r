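## internal helpers shared across modules

.assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name),
             call. = FALSE)
    bad <- if (strict) (x <= lower || x >= upper) else (x < lower || x > upper)
    if (bad)
        stop(sprintf("'%s' must lie in %s%g, %g%s (got %g)", name,
                     if (strict) "(" else "[", lower, upper,
                     if (strict) ")" else "]", x), call. = FALSE)
    invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x != round(x) || x < min)
        stop(sprintf("'%s' must be an integer >= %d", name, min),
             call. = FALSE)
    invisible(as.integer(x))
}

## Run expr under a locally seeded Mersenne-Twister RNG, restoring any
## pre-existing global RNG state afterwards (one explicit RNG per call).
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)  # promise forced unseeded
    seed <- .assertCount(seed, "seed", min = 0L)
    withr::with_seed(seed, expr,
                     .rng_kind = "Mersenne-Twister",
                     .rng_normal_kind = "Inversion",
                     .rng_sample_kind = "Rejection")
}
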