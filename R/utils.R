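# Internal helpers shared across modules.

# Evaluate expr under a local, seeded RNG stream, restoring the caller's
# RNG state afterwards so package functions never perturb user randomness.
withSeed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a child seed from a base seed and an index, kept inside the 32-bit
# signed integer range.
childSeed <- function(seed, index) {
    as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647)
}

# Child seed keyed by a string (e.g. a protein group id), so per-series
# random streams do not depend on table ordering.
stringSeed <- function(seed, name) {
    h <- 0
    for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
    childSeed(seed, h)
}

rowMedians_ <- function(m, na.rm = TRUE) apply(m, 1L, stats::median, na.rm = na.rm)
colMedians_ <- function(m, na.rm = TRUE) apply(m, 2L, stats::median, na.rm = na.rm)

# Stratified fold assignment: balanced fold sizes within each class.
stratifiedFolds <- function(y, k) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- which(y == cl)
        if (length(idx) < k)
            stop("class with fewer members (", length(idx),
                 ") than folds (", k, ")")
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
}

checkBinaryLabels <- function(y) {
    u <- unique(y[!is.na(y)])
    if (!all(u %in% c(0, 1)) || length(u) < 2L)
        stop("labels must be binary with both classes present")
    invisible(TRUE)
}
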