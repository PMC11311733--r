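#' Fit the feature preprocessing stage on a training cohort
#'
#' Builds the classifier feature pipeline on training data only, so it can
#' be applied without leakage to held-out samples: (1) protein-NP features
#' missing in more than `max_missing` of training samples are excluded;
#' (2) intensities are fold-change normalized against training protein
#' medians; (3) the extracellular composition covariate is computed; (4)
#' each feature is residualized against a random-plate-intercept +
#' composition linear mixed model, and residuals replace the intensities;
#' (5) remaining missing entries are zero-imputed. Per-feature coverage
#' (training non-missing fraction) is retained for the correlation filter.
#'
#' @param q an [NPQuant-class] of log2 intensities for training samples.
#' @param annotations annotation list providing the `"Extracellular"` term.
#' @param max_missing feature missingness cutoff, strict (default 0.6).
#' @param psa_window optional numeric length-2: restrict to samples with
#'   PSA inside `[psa_window[1], psa_window[2]]` before fitting.
#' @return object of class `featurePreprocessor`; use [applyPreprocessor()].
#' @export
featurePreprocessor <- function(q, annotations, max_missing = 0.6,
                                psa_window = NULL) {
    meta <- sampleMeta(q)
    if (!is.null(psa_window)) {
        keep <- meta$psa >= psa_window[1] & meta$psa <= psa_window[2]
        q <- q[, keep]
        meta <- meta[keep, , drop = FALSE]
    }
    n <- ncol(q)
    ref <- referenceSet(q)
    if (!length(ref)) ref <- rownames(q)
    ext <- intersect(annotations[["Extracellular"]], rownames(q))
    models <- list()
    medians <- list()
    normed <- list()
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    plate <- meta$plate_id
    ## pass 1: fold-change normalization against training medians
    for (np in npNames(q)) {
        m <- assay(q, np)
        med <- rowMedians_(m)
        medians[[np]] <- med
        norm <- m - med  # fold change vs training median
        sh <- colMedians_(norm[intersect(ref, rownames(m)), , drop = FALSE])
        sh[is.na(sh)] <- 0
        normed[[np]] <- sweep(norm, 2L, sh, `-`)
    }
    ## composition covariate on the normalized table; the protein-wise
    ## normalized medians are frozen for held-out application
    ext_medians <- lapply(normed, function(m)
        rowMedians_(m[ext, , drop = FALSE]))
    comp <- colMedians_(do.call(rbind, lapply(npNames(q), function(np)
        normed[[np]][ext, , drop = FALSE] - ext_medians[[np]])))
    comp[is.na(comp)] <- 0
    ## pass 2: per-feature residualization models
    for (np in npNames(q)) {
        m <- assay(q, np)
        miss <- rowMeans(is.na(m))
        keepf <- miss <= max_missing
        norm <- normed[[np]]
        for (prot in rownames(m)[keepf]) {
            yv <- norm[prot, ]
            obs <- !is.na(yv)
            d <- data.frame(y = yv[obs], comp = comp[obs],
                            plate = plate[obs])
            fit <- NULL
            if (length(unique(d$plate)) > 1L && stats::sd(d$y) > 0)
                fit <- tryCatch(suppressMessages(
                    lme4::lmer(y ~ comp + (1 | plate), data = d,
                               REML = TRUE, control = ctrl)),
                    error = function(e) NULL)
            if (is.null(fit)) {
                lmfit <- stats::lm(y ~ comp, data = d)
                cf <- stats::coef(lmfit)
                cf[is.na(cf)] <- 0
                models[[paste(prot, np, sep = "|")]] <- list(
                    type = "lm", coef = cf,
                    coverage = mean(obs))
            } else {
                re <- lme4::ranef(fit)$plate
                models[[paste(prot, np, sep = "|")]] <- list(
                    type = "lmm", coef = lme4::fixef(fit),
                    plate_effects = setNames(re[[1L]], rownames(re)),
                    coverage = mean(obs))
            }
        }
    }
    structure(list(models = models, medians = medians, ref = ref,
                   psa_window = psa_window, ext = ext,
                   ext_medians = ext_medians,
                   annotations = annotations),
              class = "featurePreprocessor")
}

#' Apply a fitted preprocessor to a cohort
#'
#' Normalization shifts and the composition covariate of new samples are
#' computed from their own intensities against the training protein
#' medians; residuals use the training fixed effects and plate effects
#' (unseen plates contribute 0), and missing entries are zero-imputed.
#'
#' @param pp a `featurePreprocessor`.
#' @param q an [NPQuant-class] with the same protein/NP universe.
#' @return list with `X` (samples x features residual matrix, no missing
#'   entries) and `coverage` (named training coverage per feature).
#' @export
applyPreprocessor <- function(pp, q) {
    meta <- sampleMeta(q)
    if (!is.null(pp$psa_window)) {
        keep <- meta$psa >= pp$psa_window[1] & meta$psa <= pp$psa_window[2]
        q <- q[, keep]
        meta <- meta[keep, , drop = FALSE]
    }
    feats <- names(pp$models)
    n <- ncol(q)
    ## normalize new samples against the frozen training medians
    normed <- list()
    for (np in npNames(q)) {
        norm <- assay(q, np) - pp$medians[[np]]
        sh <- colMedians_(norm[intersect(pp$ref, rownames(norm)), ,
                               drop = FALSE])
        sh[is.na(sh)] <- 0
        normed[[np]] <- sweep(norm, 2L, sh, `-`)
    }
    ## composition of the new samples vs frozen normalized ext medians
    comp <- colMedians_(do.call(rbind, lapply(npNames(q), function(np)
        normed[[np]][pp$ext, , drop = FALSE] - pp$ext_medians[[np]])))
    comp[is.na(comp)] <- 0
    X <- matrix(0, n, length(feats),
                dimnames = list(colnames(q), feats))
    for (np in npNames(q)) {
        norm <- normed[[np]]
        np_feats <- feats[endsWith(feats, paste0("|", np))]
        for (f in np_feats) {
            prot <- sub("\\|[^|]+$", "", f)
            mod <- pp$models[[f]]
            yv <- norm[prot, ]
            pred <- mod$coef[["(Intercept)"]] +
                (if ("comp" %in% names(mod$coef)) mod$coef[["comp"]] * comp
                 else 0)
            if (mod$type == "lmm") {
                pe <- mod$plate_effects[meta$plate_id]
                pe[is.na(pe)] <- 0
                pred <- pred + pe
            }
            resid <- yv - pred
            resid[is.na(resid)] <- 0  # zero imputation
            X[, f] <- resid
        }
    }
    coverage <- vapply(pp$models, `[[`, 0, "coverage")
    list(X = X, coverage = coverage, labels_meta = meta)
}

#' One-step feature preprocessing
#'
#' Fits [featurePreprocessor()] and applies it to the same cohort — the
#' whole-cohort (non-cross-validated) variant of the classifier
#' preprocessing stage.
#'
#' @inheritParams featurePreprocessor
#' @return see [applyPreprocessor()].
#' @export
preprocessFeatures <- function(q, annotations, max_missing = 0.6,
                               psa_window = NULL) {
    pp <- featurePreprocessor(q, annotations, max_missing = max_missing,
                              psa_window = psa_window)
    applyPreprocessor(pp, q)
}

#' Rank features by Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum p-value per feature for cases versus controls;
#' features are returned in ascending p order, ties broken by descending
#' absolute rank-biserial correlation and then by feature name.
#'
#' @param X samples x features matrix.
#' @param y binary labels (1 = case).
#' @return data.frame `feature`, `p`, `rank_biserial`, in rank order.
#' @export
rankFeaturesWilcoxon <- function(X, y) {
    checkBinaryLabels(y)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    p <- numeric(ncol(X)); rb <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
        xj <- X[, j]
        r <- rank(xj)
        U <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
        rb[j] <- 2 * U / (n1 * n0) - 1
        p[j] <- suppressWarnings(
            stats::wilcox.test(xj[y == 1], xj[y == 0], exact = FALSE,
                               correct = TRUE)$p.value)
        if (is.na(p[j])) p[j] <- 1
    }
    out <- data.frame(feature = colnames(X), p = p, rank_biserial = rb,
                      stringsAsFactors = FALSE)
    out <- out[order(out$p, -abs(out$rank_biserial), out$feature), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Coverage-aware correlation redundancy filter
#'
#' Within the top `top_pool` ranked features, a feature F is excluded when
#' any other pool feature whose (signed Pearson) correlation with F exceeds
#' `rho` has strictly higher coverage than F; comparisons are made against
#' the full pool regardless of the other features' own retention status.
#'
#' @param X samples x features matrix (residualized entries).
#' @param ranked character vector of features in rank order.
#' @param rho correlation cutoff.
#' @param coverage named coverage vector per feature.
#' @param top_pool pool size (default 1000).
#' @param absolute compare `|cor|` instead of the signed value.
#' @return retained features, in rank order.
#' @export
correlationFilter <- function(X, ranked, rho, coverage, top_pool = 1000L,
                              absolute = FALSE) {
    pool <- utils::head(ranked, top_pool)
    if (length(pool) < 2L) return(pool)
    C <- suppressWarnings(stats::cor(X[, pool, drop = FALSE]))
    C[is.na(C)] <- 0
    if (absolute) C <- abs(C)
    keep <- logical(length(pool))
    for (i in seq_along(pool)) {
        f <- pool[i]
        corr <- pool[C[f, ] > rho & pool != f]
        keep[i] <- !any(coverage[corr] > coverage[f])
    }
    pool[keep]
}

#' Select the best configuration by summed standardized metrics
#'
#' Each metric (AUC, average PPV, average NPV) is z-scored across
#' configurations (a zero-variance metric contributes 0) and the
#' configuration maximizing the sum is selected; ties break to the smaller
#' `m`, then smaller `rho`, then configuration name.
#'
#' @param metrics data.frame with columns `config`, `auc`, `avg_ppv`,
#'   `avg_npv` and optionally `m`, `rho`.
#' @return the selected row's `config` value.
#' @export
compositeSelect <- function(metrics) {
    stopifnot(nrow(metrics) >= 1L)
    z <- function(x) {
        s <- stats::sd(x)
        if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    }
    score <- z(metrics$auc) + z(metrics$avg_ppv) + z(metrics$avg_npv)
    ord <- order(-score,
                 if (!is.null(metrics$m)) metrics$m else seq_len(nrow(metrics)),
                 if (!is.null(metrics$rho)) metrics$rho else
                     seq_len(nrow(metrics)),
                 as.character(metrics$config))
    metrics$config[ord[1L]]
}

## Inner-CV tuning of the random-forest mtry by AUC, then a final fit.
tuneRandomForest <- function(X, y, n_inner, mtry_grid, n_trees, seed) {
    if (is.null(mtry_grid)) {
        s <- sqrt(ncol(X))
        mtry_grid <- sort(unique(pmax(1L, round(c(s / 2, s, 2 * s)))))
    }
    mtry_grid <- mtry_grid[mtry_grid <= ncol(X)]
    if (!length(mtry_grid)) mtry_grid <- max(1L, floor(sqrt(ncol(X))))
    best_mtry <- mtry_grid[1L]
    if (length(mtry_grid) > 1L) {
        k <- min(n_inner, min(table(y)))
        fold <- stratifiedFolds(y, k)
        aucs <- vapply(mtry_grid, function(mt) {
            pred <- numeric(length(y))
            for (f in seq_len(k)) {
                tr <- fold != f
                rf <- ranger::ranger(
                    x = X[tr, , drop = FALSE], y = factor(y[tr]),
                    num.trees = n_trees, mtry = mt, probability = TRUE,
                    num.threads = 1L, seed = childSeed(seed, mt * 100L + f))
                pred[!tr] <- stats::predict(
                    rf, X[!tr, , drop = FALSE],
                    num.threads = 1L)$predictions[, "1"]
            }
            aucMW(pred, y)
        }, 0)
        best_mtry <- mtry_grid[which.max(aucs)]
    }
    ranger::ranger(x = X, y = factor(y), num.trees = n_trees,
                   mtry = best_mtry, probability = TRUE,
                   importance = "permutation",
                   scale.permutation.importance = TRUE,
                   num.threads = 1L, seed = childSeed(seed, 1L))
}

#' Nested cross-validation over the pipeline configuration grid
#'
#' For each repeat seed, subjects are split into `n_outer` stratified
#' folds. All feature-selection stages — preprocessing/residualization
#' models, Wilcoxon ranking, and the correlation filter — are refit on each
#' outer-training portion only (no leakage). For every configuration
#' (number of retained features `m` and correlation cutoff `rho`), the top
#' `m` surviving features feed a random forest tuned by inner
#' cross-validation on AUC over the `mtry` grid; out-of-fold class-1
#' probabilities are recorded for every subject.
#'
#' @param q an [NPQuant-class] with sample metadata in `colData`.
#' @param annotations annotation list (for the composition covariate).
#' @param grid data.frame with columns `m` and `rho`; the default is the
#'   full evaluation grid `m` in (20, 40, 50, 80, 100, 125, 160, 200) by
#'   `rho` in (0.5, 0.6, 0.7, 0.8).
#' @param case_def 1 (cancer vs no cancer) or 2 (grade group >= 2 vs rest).
#' @param psa_window optional PSA restriction, e.g. `c(4, 10)`.
#' @param n_outer,n_inner outer and inner fold counts (defaults 10).
#' @param seeds CV repeat seeds (default `1:3`).
#' @param top_pool correlation-filter pool size (default 1000).
#' @param n_trees random-forest trees (default 500).
#' @param mtry_grid integers to tune over; default
#'   `round(c(sqrt(d)/2, sqrt(d), 2 sqrt(d)))`.
#' @param max_missing feature missingness cutoff (strict, default 0.6).
#' @param folds optional pre-computed subjects x seeds matrix of outer-fold
#'   ids (e.g. to audit fold-wise behaviour); default stratified folds per
#'   seed.
#' @return a [FoldPredictions-class] object.
#' @export
nestedCV <- function(q, annotations, grid = defaultGrid(), case_def = 1L,
                     psa_window = NULL, n_outer = 10L, n_inner = 10L,
                     seeds = 1:3, top_pool = 1000L, n_trees = 500L,
                     mtry_grid = NULL, max_missing = 0.6, folds = NULL) {
    meta <- sampleMeta(q)
    if (!is.null(psa_window)) {
        keep <- meta$psa >= psa_window[1] & meta$psa <= psa_window[2]
        q <- q[, keep]
        meta <- meta[keep, , drop = FALSE]
    }
    y <- if (case_def == 1L) as.numeric(meta$case_status) else
        as.numeric(meta$grade_group >= 2)
    names(y) <- meta$sample_id
    checkBinaryLabels(y)
    n <- length(y)
    grid$config <- sprintf("m%d_rho%g", grid$m, grid$rho)
    n_cfg <- nrow(grid)
    scores <- array(NA_real_, c(n, n_cfg, length(seeds)),
                    dimnames = list(meta$sample_id, grid$config,
                                    paste0("seed", seeds)))
    fold_mat <- matrix(NA_integer_, n, length(seeds),
                       dimnames = list(meta$sample_id, paste0("seed", seeds)))
    importance <- list()
    for (si in seq_along(seeds)) {
        sd_ <- seeds[si]
        k <- min(n_outer, min(table(y)))
        fold <- if (!is.null(folds)) as.integer(folds[, si]) else
            withSeed(childSeed(sd_, 0L), stratifiedFolds(y, k))
        k <- max(fold)
        fold_mat[, si] <- fold
        for (f in seq_len(k)) {
            tr <- fold != f
            q_tr <- q[, tr]
            pp <- featurePreprocessor(q_tr, annotations,
                                      max_missing = max_missing)
            dtr <- applyPreprocessor(pp, q_tr)
            dte <- applyPreprocessor(pp, q[, !tr])
            ranked <- rankFeaturesWilcoxon(dtr$X, y[tr])
            retained <- lapply(unique(grid$rho), function(r)
                correlationFilter(dtr$X, ranked$feature, r, dtr$coverage,
                                  top_pool = top_pool))
            names(retained) <- as.character(unique(grid$rho))
            for (g in seq_len(n_cfg)) {
                feats <- utils::head(retained[[as.character(grid$rho[g])]],
                                     grid$m[g])
                rf <- tuneRandomForest(dtr$X[, feats, drop = FALSE], y[tr],
                                       n_inner, mtry_grid, n_trees,
                                       seed = childSeed(sd_, f * 1000L + g))
                pred <- stats::predict(rf, dte$X[, feats, drop = FALSE],
                                       num.threads = 1L)$predictions[, "1"]
                scores[!tr, g, si] <- pred
                importance[[length(importance) + 1L]] <- list(
                    config = grid$config[g], seed = sd_, fold = f,
                    features = feats,
                    importance = rf$variable.importance)
            }
        }
    }
    pooled <- apply(scores, c(1, 2), mean)
    new("FoldPredictions", scores = scores, pooled = pooled, labels = y,
        configs = grid, folds = fold_mat, importance = importance,
        seeds = as.integer(seeds))
}

#' Default configuration evaluation grid
#'
#' @return data.frame crossing `m` in (20, 40, 50, 80, 100, 125, 160, 200)
#'   with `rho` in (0.5, 0.6, 0.7, 0.8).
#' @export
defaultGrid <- function() {
    expand.grid(m = c(20L, 40L, 50L, 80L, 100L, 125L, 160L, 200L),
                rho = c(0.5, 0.6, 0.7, 0.8))
}

#' Per-configuration pooled cross-validation metrics
#'
#' @param fp a [FoldPredictions-class] object.
#' @return data.frame of `config`, `m`, `rho`, `auc`, `avg_ppv`, `avg_npv`
#'   computed on the pooled (seed-averaged) out-of-fold scores.
#' @export
configMetrics <- function(fp) {
    out <- fp@configs
    met <- t(apply(fp@pooled, 2L, evaluateMetrics, y = fp@labels))
    out$auc <- met[, "auc"]; out$avg_ppv <- met[, "avg_ppv"]
    out$avg_npv <- met[, "avg_npv"]
    out
}
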