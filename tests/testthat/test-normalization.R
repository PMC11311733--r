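test_that("reference set uses an inclusive detection boundary", {
    # protein detected in 8/10 samples is included at 0.8, 79/100 is not
    m <- matrix(1, 2, 10, dimnames = list(c("Pin", "Pout"), paste0("s", 1:10)))
    m["Pin", 9:10] <- NA
    m["Pout", 8:10] <- NA
    q <- NPQuant(list(NP1 = m))
    expect_identical(referenceSet(q, 0.8), "Pin")
    expect_setequal(referenceSet(q, 0), c("Pin", "Pout"))

    m2 <- matrix(1, 1, 100, dimnames = list("P79", paste0("s", 1:100)))
    m2[1, 1:21] <- NA
    expect_length(suppressWarnings(
        referenceSet(NPQuant(list(NP1 = m2)), 0.8)), 0)
})

test_that("fold-change shifts match a hand-computed 3x3 oracle", {
    m <- matrix(c(10, 11, 13,
                  20, 21, 23,
                  30, 31, 34), nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"), c("s1", "s2", "s3")))
    qn <- foldChangeNormalize(NPQuant(list(NP1 = m)), ref = rownames(m))
    # protein medians: 11, 21, 31; fold changes per sample:
    # s1: (-1,-1,-1), s2: (0,0,0), s3: (2,2,3) -> shifts -1, 0, 2
    sh <- normShifts(qn)
    expect_equal(sh$shift, c(-1, 0, 2))
    expect_equal(unname(SummarizedExperiment::assay(qn, 1)["P3", ]),
                 c(31, 31, 32))
})

test_that("normalization is exactly idempotent", {
    q <- randomQuant(n_prot = 50, n_samp = 30, n_np = 2, seed = 10,
                     miss = 0.1)
    qn <- foldChangeNormalize(q)
    qn2 <- foldChangeNormalize(qn)
    expect_lt(max(abs(normShifts(qn2)$shift)), 1e-9)
    expect_equal(SummarizedExperiment::assay(qn2, 1),
                 SummarizedExperiment::assay(qn, 1), tolerance = 1e-12)
})

test_that("normalization is exactly location-equivariant", {
    q <- randomQuant(n_prot = 50, n_samp = 30, seed = 12)
    qn <- foldChangeNormalize(q)
    pr <- referenceProfile(qn)
    m2 <- SummarizedExperiment::assay(q, 1)
    m2[, 7] <- m2[, 7] + 3.14
    qn2 <- foldChangeNormalize(NPQuant(list(NP1 = m2)), profile = pr)
    d <- normShifts(qn2)$shift - normShifts(qn)$shift
    expect_equal(d[7], 3.14, tolerance = 1e-9)
    expect_true(all(abs(d[-7]) < 1e-12))
    expect_equal(SummarizedExperiment::assay(qn2, 1),
                 SummarizedExperiment::assay(qn, 1), tolerance = 1e-9)
})

test_that("runs without reference observations get zero shift", {
    m <- matrix(c(1, 2, NA,
                  2, 3, NA,
                  5, 6, 7), nrow = 3, byrow = TRUE,
                dimnames = list(c("R1", "R2", "Px"), paste0("s", 1:3)))
    qn <- foldChangeNormalize(NPQuant(list(NP1 = m)), ref = c("R1", "R2"))
    expect_equal(normShifts(qn)$shift[3], 0)
})

test_that("composition covariate responds to constructed shifts", {
    q <- randomQuant(n_prot = 20, n_samp = 10, n_np = 2, seed = 13)
    ann <- list(Extracellular = rownames(q)[1:8])
    # identical samples: covariate 0 everywhere
    m <- matrix(rep(rnorm(20, 15, 2), 10), 20, 10,
                dimnames = dimnames(SummarizedExperiment::assay(q, 1)))
    flat <- NPQuant(list(NP1 = m))
    expect_true(all(abs(compositionCovariate(flat, ann)) < 1e-12))
    # +1 on all extracellular proteins of one sample
    m2 <- m; m2[1:8, 4] <- m2[1:8, 4] + 1
    cc <- compositionCovariate(NPQuant(list(NP1 = m2)), ann)
    expect_equal(unname(cc[4]), 1)
    expect_true(all(abs(cc[-4]) < 1e-12))
    expect_error(compositionCovariate(q, list(Extracellular = "absent")),
                 "no annotated protein")
})

test_that("composition recovery tracks simulated truth", {
    sim <- simulateCohort(simParams(n_subjects = 80, n_proteins = 150,
                                    composition_sd = 0.5, seed = 14))
    qn <- foldChangeNormalize(sim$quant)
    cc <- compositionCovariate(qn, sim$annotations)
    expect_gt(cor(cc, sim$truth$samples$true_composition), 0.9)
})

test_that("detection filter applies the 60%-missing rule", {
    m <- matrix(1, 3, 10, dimnames = list(c("P6", "P5", "P0"),
                                          paste0("s", 1:10)))
    m["P6", 1:6] <- NA  # 60% missing: excluded (inclusive rule)
    m["P5", 1:5] <- NA  # 50% missing: kept
    q <- NPQuant(list(NP1 = m))
    qf <- detectionFilter(q, 0.6)
    expect_setequal(rownames(qf), c("P5", "P0"))
    # classifier rule is strict: 60% kept, >60% dropped
    qs <- detectionFilter(q, 0.6, inclusive = FALSE)
    expect_setequal(rownames(qs), c("P6", "P5", "P0"))
    m["P6", 7] <- NA   # 70% missing
    qs2 <- detectionFilter(NPQuant(list(NP1 = m)), 0.6, inclusive = FALSE)
    expect_setequal(rownames(qs2), c("P5", "P0"))
    # fully observed tables pass through unchanged
    qful <- randomQuant(5, 6, seed = 2)
    expect_equal(SummarizedExperiment::assay(detectionFilter(qful), 1),
                 SummarizedExperiment::assay(qful, 1))
})

test_that("detection filter is monotone in its threshold", {
    q <- randomQuant(n_prot = 30, n_samp = 12, n_np = 2, seed = 15,
                     miss = 0.4)
    kept <- lapply(c(0.3, 0.5, 0.7, 0.9), function(t)
        rownames(detectionFilter(q, t)))
    for (i in 1:3) expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("best-NP selection matches a brute-force count", {
    m1 <- matrix(c(1, NA, 3, 4, 5), 1, 5,
                 dimnames = list("P1", paste0("s", 1:5)))
    m2 <- matrix(c(1, 2, 3, 4, 5), 1, 5,
                 dimnames = list("P1", paste0("s", 1:5)))
    q <- NPQuant(list(NP1 = m1, NP2 = m2))
    expect_equal(selectBestNP(q, "P1"), "NP2")
    # tie breaks to the first channel
    q2 <- NPQuant(list(NP1 = m2, NP3 = m2))
    expect_equal(selectBestNP(q2, "P1"), "NP1")
    expect_error(selectBestNP(q, "nope"), "unknown protein")

    q3 <- randomQuant(n_prot = 12, n_samp = 9, n_np = 4, seed = 16,
                      miss = 0.3)
    for (p in rownames(q3)) {
        cnt <- vapply(npNames(q3), function(np)
            sum(!is.na(SummarizedExperiment::assay(q3, np)[p, ])), 0L)
        expect_equal(selectBestNP(q3, p), names(cnt)[which.max(cnt)])
    }
})

test_that("MNAR imputation draws from the downshifted normal", {
    q <- randomQuant(n_prot = 40, n_samp = 25, seed = 17)
    params <- imputationParams(q)
    x <- rep(NA_real_, 1e5)
    filled <- imputeMNAR(x, params, seed = 20)
    expect_equal(mean(filled), params$I0 - 1.8 * params$sigma,
                 tolerance = 0.01)
    expect_equal(sd(filled), 0.3 * params$sigma, tolerance = 0.01)
    expect_lt(mean(filled), params$I0)

    # observed entries untouched; no-missing series returned unchanged
    y <- c(1, NA, 3)
    y2 <- imputeMNAR(y, params, seed = 1)
    expect_identical(y2[c(1, 3)], c(1, 3))
    expect_identical(imputeMNAR(c(1, 2), params), c(1, 2))
    expect_identical(imputeMNAR(y, params, seed = 5),
                     imputeMNAR(y, params, seed = 5))

    expect_error(imputationParams(matrix(2, 3, 3)), "sigma")
})
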