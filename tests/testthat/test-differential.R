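# Build a long per-protein data.frame for direct fitProteinLmm tests.
lmmData <- function(n_sub = 40, n_np = 3, n_plate = 4, delta = 1,
                    resid_sd = 0.3, plate_sd = 0, seed = 1) {
    set.seed(seed)
    d <- expand.grid(subject = sprintf("S%02d", seq_len(n_sub)),
                     np = paste0("NP", seq_len(n_np)),
                     stringsAsFactors = FALSE)
    sub_idx <- as.integer(factor(d$subject))
    plate <- rep_len(seq_len(n_plate), n_sub)[sub_idx]
    case <- rep_len(c(1, 0), n_sub)[sub_idx]  # balanced within plates
    d$plate <- sprintf("p%d", plate)
    d$pc_status <- case
    d$age <- rnorm(n_sub, 64, 7)[sub_idx]
    d$draw_year <- sample(2000:2016, n_sub, TRUE)[sub_idx]
    d$appearance_outlier <- 0
    d$composition <- rnorm(n_sub, 0, 0.5)[sub_idx]
    d$y <- delta * d$pc_status + 0.01 * d$age + 0.3 * d$composition +
        rnorm(n_plate, 0, plate_sd)[plate] + rnorm(nrow(d), 0, resid_sd)
    d
}

test_that("noise-free planted effect is recovered exactly", {
    d <- lmmData(n_sub = 30, delta = 1, resid_sd = 1e-6)
    fit <- fitProteinLmm(d)
    expect_true(fit$converged)
    expect_equal(fit$beta, 1, tolerance = 1e-4)
    expect_lt(fit$p, 1e-100)
    expect_equal(fit$n_np_used, 3L)
})

test_that("balanced one-NP fits equal the OLS coefficient", {
    d <- lmmData(n_sub = 40, n_np = 1, delta = 0.5, resid_sd = 0.4,
                 seed = 2)
    fit <- fitProteinLmm(d)
    ols <- lm(y ~ pc_status + age + draw_year + composition, data = d)
    expect_equal(fit$beta, unname(coef(ols)["pc_status"]),
                 tolerance = 1e-6)
    # single-NP fits keep only the plate random intercept
    expect_equal(fit$var_np, 0)
    expect_equal(fit$var_platenp, 0)
    expect_equal(fit$var_subject, 0)
})

test_that("degenerate case-status input is rejected", {
    d <- lmmData(n_sub = 20, seed = 3)
    d$pc_status <- 1
    expect_error(fitProteinLmm(d), "case-status")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
    set.seed(4)
    for (i in 1:25) {
        p <- runif(sample(1:20, 1))
        expect_equal(p.adjust(p, method = "BH"), bhOracle(p),
                     tolerance = 1e-12)
    }
})

test_that("differential results are well-formed and BH-consistent", {
    sim <- simulateCohort(simParams(n_subjects = 60, n_proteins = 30,
                                    n_differential = 6, seed = 18))
    qn <- foldChangeNormalize(sim$quant)
    de <- runDifferential(qn, sim$annotations, seed = 7)
    expect_true(all(de$q >= de$p - 1e-12, na.rm = TRUE))
    conv <- de[de$converged, ]
    expect_equal(conv$q, p.adjust(conv$p, "BH"), tolerance = 1e-12)
    expect_equal(attr(de, "p_method"), "Wald z on REML fit")
    # planted effects dominate the significant set
    tr <- sim$truth$proteins
    hits <- de$protein_group[!is.na(de$q) & de$q < 0.05]
    expect_gt(mean(tr$is_differential[match(hits, tr$protein_group)]), 0.5)
    # deterministic under the imputation seed
    de2 <- runDifferential(qn, sim$annotations, seed = 7)
    expect_identical(de, de2)
})

test_that("single eligible protein gives q equal to p", {
    sim <- simulateCohort(simParams(n_subjects = 40, n_proteins = 12,
                                    n_differential = 0, seed = 19))
    qn <- foldChangeNormalize(sim$quant)
    qn1 <- qn[1, ]
    de <- runDifferential(qn1, NULL, seed = 1)
    expect_equal(nrow(de), 1L)
    expect_equal(de$q, de$p)
})

test_that("type-I error is calibrated on null cohorts", {
    sim <- simulateCohort(simParams(n_subjects = 60, n_proteins = 100,
                                    n_differential = 0, seed = 20))
    de <- runDifferential(foldChangeNormalize(sim$quant), sim$annotations,
                          seed = 8)
    frac <- mean(de$p[de$converged] < 0.05)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.10)
    expect_equal(sum(de$q < 0.05, na.rm = TRUE), 0)
})

test_that("contrast comparison recovers exact correlations", {
    r1 <- data.frame(protein_group = paste0("P", 1:10),
                     beta = rnorm(10), q = c(rep(0.01, 6), rep(0.5, 4)))
    r2 <- r1
    expect_equal(compareContrasts(r1, r2)$pearson_r, 1)
    r3 <- r1; r3$beta <- -r3$beta
    expect_equal(compareContrasts(r1, r3)$pearson_r, -1)
    # union of significant proteins defines the paired set
    expect_equal(nrow(compareContrasts(r1, r2)$betas), 6L)
    r4 <- r1[1:2, ]; r4$q <- 0.01
    expect_warning(out <- compareContrasts(r4, r4), "fewer than 3")
    expect_true(is.na(out$pearson_r))
})

test_that("results are invariant to sample and protein ordering", {
    sim <- simulateCohort(simParams(n_subjects = 40, n_proteins = 15,
                                    n_differential = 3, seed = 22))
    qn <- foldChangeNormalize(sim$quant)
    de <- runDifferential(qn, NULL, seed = 3)
    qp <- qn[sample(rownames(qn)), sample(colnames(qn))]
    # re-freeze the same profile so only ordering differs
    S4Vectors::metadata(qp)$norm_profile <- referenceProfile(qn)
    dep <- runDifferential(qp, NULL, seed = 3)
    dep <- dep[match(de$protein_group, dep$protein_group), ]
    # invariant up to optimizer jitter from permuted row order
    expect_equal(de$p, dep$p, tolerance = 1e-3)
    expect_equal(de$beta, dep$beta, tolerance = 1e-3)
})
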