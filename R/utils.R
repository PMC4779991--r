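# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

clip01 <- function(x) {
    x[x < 0] <- 0
    x[x > 1] <- 1
    x
}

# Pearson r of each row of `m` (features x samples) with vector `y`.
# Rows with zero variance get r = 0.
rowPearson <- function(m, y) {
    yc <- y - mean(y)
    syy <- sum(yc^2)
    mc <- m - rowMeans(m)
    sxx <- rowSums(mc^2)
    num <- as.vector(mc %*% yc)
    r <- ifelse(sxx > 0 & syy > 0, num / sqrt(sxx * syy), 0)
    r
}
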