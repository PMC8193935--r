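# Internal helpers: local RNG scoping and deterministic seed derivation.

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# derive a child seed from a master seed; stays inside 32-bit integer range
childSeed <- function(seed, i) {
    as.integer((as.double(seed) * 2654435.0 + i * 40503.0 + 97.0) %%
               2147483647)
}

# stratified fold assignment: per class, subjects are shuffled and dealt
# round-robin into `folds` folds; returns integer fold id per row
stratifiedFolds <- function(labels, folds, seed) {
    withSeed(seed, {
        fold <- integer(length(labels))
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            if (length(idx) < folds)
                stop("class '", cl, "' has fewer members (", length(idx),
                     ") than folds (", folds, ")")
            fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
        }
        fold
    })
}

# truncated-normal draws by rejection; bounds are in the same units as mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
    if (lower >= upper) stop("infeasible truncation bounds")
    if (pnorm(upper, mean, sd) - pnorm(lower, mean, sd) < 1e-6)
        stop("infeasible truncation bounds: mass below 1e-6")
    out <- numeric(0)
    while (length(out) < n) {
        draw <- rnorm(2 * (n - length(out)) + 8, mean, sd)
        out <- c(out, draw[draw >= lower & draw <= upper])
    }
    out[seq_len(n)]
}
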