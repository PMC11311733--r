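test_that("classification metrics match exhaustive sweep oracles", {
    set.seed(27)
    for (i in 1:40) {
        n <- sample(6:50, 1)
        y <- rbinom(n, 1, 0.5)
        if (length(unique(y)) < 2) next
        # mix continuous scores and heavy ties
        scores <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.25), n, TRUE)
        m <- evaluateMetrics(scores, y)
        expect_equal(unname(m["auc"]), aucOracle(scores, y),
                     tolerance = 1e-12)
        expect_equal(unname(m["avg_ppv"]), apOracle(scores, y),
                     tolerance = 1e-12)
        expect_equal(unname(m["avg_npv"]), apOracle(-scores, 1 - y),
                     tolerance = 1e-12)
    }
})

test_that("metric edge cases are analytic", {
    y <- c(1, 1, 1, 0, 0, 0)
    perfect <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
    expect_equal(unname(evaluateMetrics(perfect, y)), c(1, 1, 1))
    # constant scores: AUC 1/2, avg PPV = prevalence, avg NPV = 1 - prevalence
    yc <- rep(c(1, 0), c(3, 7))
    m <- evaluateMetrics(rep(0.4, 10), yc)
    expect_equal(unname(m), c(0.5, 0.3, 0.7))
    # label flip symmetry for AUC
    s <- runif(20); yy <- rep(c(1, 0), 10)
    expect_equal(aucMW(s, yy), 1 - aucMW(-s, yy), tolerance = 1e-12)
    expect_error(evaluateMetrics(s, rep(1, 20)), "binary")
})

test_that("Wilcoxon feature ranking matches independent statistics", {
    set.seed(28)
    n <- 8
    y <- rep(c(1, 0), each = 4)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    X[, 1] <- y * 10 + rnorm(n, 0, 0.01)   # perfectly separating
    X[, 2] <- rep(1:4, 2)                  # identical across classes
    rk <- rankFeaturesWilcoxon(X, y)
    expect_equal(rk$feature[1], "f1")
    expect_equal(rk$p[rk$feature == "f2"], 1, tolerance = 1e-9)
    # independent normal-approximation oracle with tie correction
    for (f in colnames(X)) {
        ours <- rk$p[rk$feature == f]
        ref <- suppressWarnings(wilcox.test(
            X[y == 1, f], X[y == 0, f], exact = FALSE,
            correct = TRUE)$p.value)
        expect_equal(ours, ref, tolerance = 1e-12)
        U <- uOracle(X[y == 1, f], X[y == 0, f])
        expect_equal(rk$rank_biserial[rk$feature == f],
                     2 * U / 16 - 1, tolerance = 1e-12)
    }
    expect_error(rankFeaturesWilcoxon(X, rep(1, n)), "binary")
})

test_that("correlation filter follows the coverage rule exactly", {
    set.seed(29)
    n <- 30
    # duplicate columns: the lower-coverage copy is excluded
    x <- rnorm(n)
    X <- cbind(a = x, b = x + rnorm(n, 0, 1e-6), c = rnorm(n))
    cov <- c(a = 0.9, b = 0.8, c = 0.5)
    kept <- correlationFilter(X, c("a", "b", "c"), rho = 0.5, coverage = cov)
    expect_setequal(kept, c("a", "c"))
    # rho = 1 retains everything (correlation cannot exceed 1)
    expect_setequal(correlationFilter(X, colnames(X), 1, cov), colnames(X))
    # exclusion compares against the full pool, not retained survivors
    # chain: f1 ~ f2 ~ f3 with coverage 0.5 < 0.9 < 0.7:
    z <- rnorm(n)
    Xc <- cbind(f1 = z + rnorm(n, 0, 0.1), f2 = z + rnorm(n, 0, 0.1),
                f3 = rnorm(n))
    Xc[, "f3"] <- Xc[, "f2"] + rnorm(n, 0, 0.1)
    covc <- c(f1 = 0.5, f2 = 0.9, f3 = 0.7)
    keptc <- correlationFilter(Xc, colnames(Xc), rho = 0.6, coverage = covc)
    oracle <- corrFilterOracle(Xc, colnames(Xc), 0.6, covc)
    expect_identical(keptc, oracle)
})

test_that("correlation filter equals the naive oracle on random pools", {
    set.seed(30)
    for (i in 1:30) {
        n <- 25; d <- sample(5:20, 1)
        base <- matrix(rnorm(n * 3), n, 3)
        X <- sapply(seq_len(d), function(j)
            base[, sample(3, 1)] + rnorm(n, 0, runif(1, 0.05, 2)))
        colnames(X) <- sprintf("g%02d", seq_len(d))
        coverage <- setNames(round(runif(d), 2), colnames(X))
        ranked <- sample(colnames(X))
        rho <- sample(c(0.5, 0.6, 0.7, 0.8), 1)
        expect_identical(
            correlationFilter(X, ranked, rho, coverage),
            corrFilterOracle(X, ranked, rho, coverage))
    }
})

test_that("composite selection maximizes summed z-scores", {
    one <- data.frame(config = "only", auc = 0.6, avg_ppv = 0.5,
                      avg_npv = 0.5)
    expect_equal(compositeSelect(one), "only")
    dom <- data.frame(config = c("a", "b", "c"),
                      auc = c(0.9, 0.6, 0.5), avg_ppv = c(0.8, 0.5, 0.4),
                      avg_npv = c(0.9, 0.6, 0.5))
    expect_equal(compositeSelect(dom), "a")
    # hand-computed z-sums on a 4-config table
    tab <- data.frame(config = c("c1", "c2", "c3", "c4"),
                      m = c(20, 40, 20, 40), rho = c(0.5, 0.5, 0.8, 0.8),
                      auc = c(0.70, 0.65, 0.60, 0.72),
                      avg_ppv = c(0.55, 0.70, 0.50, 0.60),
                      avg_npv = c(0.66, 0.60, 0.70, 0.62))
    z <- function(x) (x - mean(x)) / sd(x)
    zsum <- z(tab$auc) + z(tab$avg_ppv) + z(tab$avg_npv)
    expect_equal(compositeSelect(tab), tab$config[which.max(zsum)])
    # sd = 0 metrics contribute nothing; ties break to smaller m then rho
    tied <- data.frame(config = c("big", "small"), m = c(40, 20),
                       rho = c(0.5, 0.5), auc = c(0.6, 0.6),
                       avg_ppv = c(0.5, 0.5), avg_npv = c(0.5, 0.5))
    expect_equal(compositeSelect(tied), "small")
})

test_that("feature preprocessing residualizes plate and composition", {
    sim <- simulateCohort(simParams(n_subjects = 60, n_proteins = 25,
                                    n_differential = 0, plate_sd = 1,
                                    seed = 31))
    q <- sim$quant
    pre <- preprocessFeatures(q, sim$annotations)
    expect_false(anyNA(pre$X))
    expect_true(all(pre$coverage > 0.4 & pre$coverage <= 1))
    # residual features are centred within every plate
    meta <- sampleMeta(q)
    for (f in colnames(pre$X)[1:10]) {
        pm <- tapply(pre$X[, f], meta$plate_id, mean)
        expect_lt(max(abs(pm)), 3 * sd(pre$X[, f]))
    }
    # a feature with >60% missingness is excluded
    a1 <- SummarizedExperiment::assay(q, "NP1")
    a1[3, 1:37] <- NA   # 61.7% missing
    q2 <- NPQuant(setNames(c(list(a1), lapply(npNames(q)[-1], function(np)
        SummarizedExperiment::assay(q, np))), npNames(q)),
        meta = sampleMeta(q))
    pre2 <- preprocessFeatures(q2, sim$annotations)
    expect_false(paste0(rownames(q)[3], "|NP1") %in% colnames(pre2$X))
})

test_that("degenerate preprocessing reduces to centred inputs", {
    # no missingness, one plate, and extracellular proteins constant
    # across samples, so the composition covariate is exactly 0
    set.seed(32)
    # antisymmetric noise pairs make every per-sample fold-change median
    # exactly zero, so normalization shifts and composition are both 0
    mu <- rnorm(20, 15, 1)
    e <- matrix(rnorm(8 * 12), 8, 12)
    m <- matrix(0, 20, 12, dimnames = list(sprintf("P%02d", 1:20),
                                           sprintf("S%02d", 1:12)))
    m[1:4, ] <- mu[1:4]
    m[5:12, ] <- mu[5:12] + e
    m[13:20, ] <- mu[13:20] - e
    meta <- data.frame(sample_id = colnames(m), plate_id = "p1",
                       case_status = rep(0:1, 6))
    q <- NPQuant(list(NP1 = m), meta = meta)
    ann <- list(Extracellular = rownames(m)[1:4])
    pre <- preprocessFeatures(q, ann)
    # residuals equal the normalized values minus their mean
    qn <- foldChangeNormalize(q, ref = rownames(m))
    for (p in rownames(m)[5:10]) {
        f <- paste0(p, "|NP1")
        v <- SummarizedExperiment::assay(qn, 1)[p, ]
        expect_equal(unname(pre$X[, f]), unname(v - mean(v)),
                     tolerance = 1e-8)
    }
})

test_that("nested CV scores every subject once per configuration", {
    sim <- simulateCohort(simParams(n_subjects = 40, n_proteins = 15,
                                    n_differential = 5,
                                    effect_size_log2 = 2, seed = 33))
    grid <- expand.grid(m = c(5L, 10L), rho = 0.8)
    fp <- nestedCV(sim$quant, sim$annotations, grid = grid, n_outer = 4,
                   n_inner = 3, seeds = 1:2, n_trees = 60,
                   mtry_grid = c(2L, 4L))
    expect_s4_class(fp, "FoldPredictions")
    expect_false(anyNA(fp@scores))
    expect_true(all(fp@pooled >= 0 & fp@pooled <= 1))
    expect_equal(dim(fp@pooled), c(40L, 2L))
    # folds partition subjects per seed
    for (s in 1:2) expect_true(all(table(fp@folds[, s]) >= 8))
    # determinism: identical run gives identical object
    fp2 <- nestedCV(sim$quant, sim$annotations, grid = grid, n_outer = 4,
                    n_inner = 3, seeds = 1:2, n_trees = 60,
                    mtry_grid = c(2L, 4L))
    expect_identical(serialize(fp@scores, NULL), serialize(fp2@scores, NULL))
    # planted signal is learnable
    cm <- configMetrics(fp)
    expect_gt(max(cm$auc), 0.7)
})

test_that("validation-fold labels never influence training-fold selection", {
    sim <- simulateCohort(simParams(n_subjects = 30, n_proteins = 12,
                                    n_differential = 4,
                                    effect_size_log2 = 2, seed = 34))
    meta <- sampleMeta(sim$quant)
    y <- meta$case_status
    folds <- matrix(rep_len(1:3, 30), ncol = 1,
                    dimnames = list(meta$sample_id, "seed1"))
    grid <- data.frame(m = 5L, rho = 0.8)
    fp1 <- nestedCV(sim$quant, sim$annotations, grid = grid, n_outer = 3,
                    n_inner = 2, seeds = 1, n_trees = 50, mtry_grid = 2L,
                    folds = folds)
    # scramble the labels of fold-1 subjects only (fold 1 is the held-out
    # set when its training fold is built)
    q2 <- sim$quant
    flip <- folds[, 1] == 1
    SummarizedExperiment::colData(q2)$case_status[flip] <-
        1 - SummarizedExperiment::colData(q2)$case_status[flip]
    fp2 <- nestedCV(q2, sim$annotations, grid = grid, n_outer = 3,
                    n_inner = 2, seeds = 1, n_trees = 50, mtry_grid = 2L,
                    folds = folds)
    sel1 <- Filter(function(r) r$fold == 1, fp1@importance)[[1]]$features
    sel2 <- Filter(function(r) r$fold == 1, fp2@importance)[[1]]$features
    expect_identical(sel1, sel2)
})
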