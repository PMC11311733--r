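# Shared fixture builders; everything is generated in code.

# Small complete random quant table (one or more NPs).
randomQuant <- function(n_prot = 10, n_samp = 8, n_np = 1, seed = 1,
                        mean = 15, sd = 2, miss = 0) {
    set.seed(seed)
    prot <- sprintf("P%02d", seq_len(n_prot))
    samp <- sprintf("S%02d", seq_len(n_samp))
    assays <- lapply(seq_len(n_np), function(j) {
        m <- matrix(rnorm(n_prot * n_samp, mean, sd), n_prot, n_samp,
                    dimnames = list(prot, samp))
        if (miss > 0) m[runif(length(m)) < miss] <- NA_real_
        m
    })
    names(assays) <- paste0("NP", seq_len(n_np))
    NPQuant(assays)
}

# Minimal sample metadata for design functions.
randomMeta <- function(n = 40, seed = 1, case_fraction = 0.5) {
    set.seed(seed)
    n_case <- round(case_fraction * n)
    data.frame(
        sample_id = sprintf("S%03d", seq_len(n)),
        case_status = sample(rep(c(1, 0), c(n_case, n - n_case))),
        age = rnorm(n, 64, 7),
        psa = pmin(pmax(rlnorm(n, log(5), 0.8), 0.1), 50),
        cohort = sample(c("FCS", "SABOR"), n, replace = TRUE),
        race_ethnicity = sample(c("groupA", "groupB"), n, replace = TRUE),
        stringsAsFactors = FALSE)
}

# Independent brute-force Benjamini-Hochberg step-up.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rep(NA_real_, m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# Independent Mann-Whitney U (member side) by pair counting.
uOracle <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exhaustive threshold-sweep average precision oracle.
apOracle <- function(scores, y) {
    ths <- sort(unique(scores), decreasing = TRUE)
    n1 <- sum(y == 1)
    ap <- 0; prev_rec <- 0
    for (t in ths) {
        sel <- scores >= t
        prec <- sum(y[sel] == 1) / sum(sel)
        rec <- sum(y[sel] == 1) / n1
        ap <- ap + (rec - prev_rec) * prec
        prev_rec <- rec
    }
    ap
}

# Pairwise AUC oracle.
aucOracle <- function(scores, y) {
    uOracle(scores[y == 1], scores[y == 0]) / (sum(y == 1) * sum(y == 0))
}

# Naive reading of the coverage-aware correlation filter rule.
corrFilterOracle <- function(X, ranked, rho, coverage, top_pool = 1000) {
    pool <- head(ranked, top_pool)
    kept <- character()
    for (f in pool) {
        others <- setdiff(pool, f)
        corr <- others[vapply(others, function(g) {
            cc <- suppressWarnings(cor(X[, f], X[, g]))
            isTRUE(cc > rho)
        }, TRUE)]
        if (!any(coverage[corr] > coverage[f])) kept <- c(kept, f)
    }
    kept
}

# Exhaustive best-k coverage (brute force over all subsets).
optCoverage <- function(M, k) {
    combs <- utils::combn(nrow(M), k)
    best <- 0L
    for (j in seq_len(ncol(combs))) {
        cov <- sum(colSums(M[combs[, j], , drop = FALSE]) > 0)
        if (cov > best) best <- cov
    }
    best
}
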