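#' Bootstrapped bias-corrected cross-validation (BBC-CV)
#'
#' Corrects the winner's-curse optimism of selecting a pipeline
#' configuration on pooled cross-validation predictions. Subjects (rows of
#' the pooled out-of-fold score matrix) are resampled with replacement `B`
#' times; in each iteration the best configuration is selected on the
#' in-bag rows by [compositeSelect()], and its metrics — together with the
#' benchmark score's, on exactly the same subjects — are evaluated on the
#' out-of-bag rows. Iterations whose in-bag or out-of-bag set is
#' single-class are redrawn so `B` stays fixed. Point estimates are means
#' over iterations, with 2.5/97.5 percentile confidence intervals.
#'
#' @param fp a [FoldPredictions-class] object, or a subjects x
#'   configurations score matrix (then `labels` must be given).
#' @param labels binary labels, required when `fp` is a matrix.
#' @param benchmark optional per-subject clinical benchmark scores aligned
#'   with the rows of `fp`.
#' @param B bootstrap iterations (default 500; below 50 a warning is
#'   issued).
#' @param seed integer seed.
#' @return a [BBCResult-class] object.
#' @export
bbcEvaluate <- function(fp, labels = NULL, benchmark = NULL, B = 500L,
                        seed = 1L) {
    if (is(fp, "FoldPredictions")) {
        P <- fp@pooled
        y <- fp@labels
        cfg <- fp@configs
    } else {
        P <- as.matrix(fp)
        if (is.null(labels)) stop("labels are required with a score matrix")
        y <- labels
        cn <- colnames(P)
        if (is.null(cn)) cn <- paste0("cfg", seq_len(ncol(P)))
        cfg <- data.frame(config = cn, stringsAsFactors = FALSE)
    }
    if (B < 50L) warning("B < 50 gives unstable percentile intervals")
    n <- nrow(P)
    checkBinaryLabels(y)
    has_bench <- !is.null(benchmark)
    metrics_names <- c("auc", "avg_ppv", "avg_npv")
    it <- vector("list", B)
    withSeed(seed, {
        for (b in seq_len(B)) {
            repeat {
                idx <- sample.int(n, n, replace = TRUE)
                oob <- setdiff(seq_len(n), unique(idx))
                if (length(oob) >= 2L &&
                    length(unique(y[idx])) == 2L &&
                    length(unique(y[oob])) == 2L) break
            }
            inb_met <- cfg
            met <- t(apply(P[idx, , drop = FALSE], 2L, evaluateMetrics,
                           y = y[idx]))
            inb_met$auc <- met[, "auc"]; inb_met$avg_ppv <- met[, "avg_ppv"]
            inb_met$avg_npv <- met[, "avg_npv"]
            sel <- compositeSelect(inb_met)
            j <- match(sel, cfg$config)
            mod <- evaluateMetrics(P[oob, j], y[oob])
            row <- data.frame(b = b, selected_config = sel,
                              auc = mod["auc"], avg_ppv = mod["avg_ppv"],
                              avg_npv = mod["avg_npv"])
            if (has_bench) {
                ben <- evaluateMetrics(benchmark[oob], y[oob])
                row$bench_auc <- ben["auc"]
                row$bench_avg_ppv <- ben["avg_ppv"]
                row$bench_avg_npv <- ben["avg_npv"]
                row$delta_auc <- mod["auc"] - ben["auc"]
                row$delta_avg_ppv <- mod["avg_ppv"] - ben["avg_ppv"]
                row$delta_avg_npv <- mod["avg_npv"] - ben["avg_npv"]
            }
            it[[b]] <- row
        }
    })
    iters <- do.call(rbind, it)
    rownames(iters) <- NULL
    summ <- do.call(rbind, lapply(
        setdiff(colnames(iters), c("b", "selected_config")),
        function(mn) {
            v <- iters[[mn]]
            data.frame(metric = mn, estimate = mean(v),
                       lower = unname(stats::quantile(v, 0.025)),
                       upper = unname(stats::quantile(v, 0.975)))
        }))
    freq <- table(factor(iters$selected_config, levels = cfg$config)) / B
    new("BBCResult", iterations = iters, summary = summ,
        selectionFrequency = setNames(as.numeric(freq), cfg$config),
        B = as.integer(B))
}

#' Held-out validation comparison against a benchmark
#'
#' One-sided tests of whether the signature outperforms the benchmark on
#' the validation set: the AUC difference uses the paired DeLong variance
#' estimate; average PPV and NPV differences use a paired bootstrap
#' (mid-p, so identical score vectors give p = 0.5).
#'
#' @param model_scores,benchmark_scores per-subject scores on the
#'   validation set.
#' @param y binary validation labels.
#' @param n_boot bootstrap resamples for the PPV/NPV tests (default 10000).
#' @param seed integer seed.
#' @return data.frame per metric: model value, benchmark value, delta, and
#'   one-sided p (alternative: model greater).
#' @export
holdoutValidate <- function(model_scores, benchmark_scores, y,
                            n_boot = 10000L, seed = 1L) {
    checkBinaryLabels(y)
    mod <- evaluateMetrics(model_scores, y)
    ben <- evaluateMetrics(benchmark_scores, y)
    ## AUC: paired DeLong one-sided
    if (isTRUE(all.equal(as.numeric(model_scores),
                         as.numeric(benchmark_scores)))) {
        p_auc <- 0.5
    } else {
        rt <- suppressMessages(pROC::roc.test(
            pROC::roc(y, model_scores, quiet = TRUE, direction = "<"),
            pROC::roc(y, benchmark_scores, quiet = TRUE, direction = "<"),
            method = "delong", paired = TRUE, alternative = "greater"))
        p_auc <- rt$p.value
    }
    ## PPV/NPV: paired bootstrap mid-p
    n <- length(y)
    dppv <- numeric(n_boot); dnpv <- numeric(n_boot)
    withSeed(seed, {
        b <- 0L
        while (b < n_boot) {
            idx <- sample.int(n, n, replace = TRUE)
            if (length(unique(y[idx])) < 2L) next
            b <- b + 1L
            mm <- evaluateMetrics(model_scores[idx], y[idx])
            bb <- evaluateMetrics(benchmark_scores[idx], y[idx])
            dppv[b] <- mm["avg_ppv"] - bb["avg_ppv"]
            dnpv[b] <- mm["avg_npv"] - bb["avg_npv"]
        }
    })
    midp <- function(d) mean(d < 0) + 0.5 * mean(d == 0)
    data.frame(
        metric = c("auc", "avg_ppv", "avg_npv"),
        model = unname(mod), benchmark = unname(ben),
        delta = unname(mod - ben),
        p_one_sided = c(p_auc, midp(dppv), midp(dnpv)))
}

#' Summarize feature importance across the BBC-CV selection
#'
#' A feature's score is the selection-frequency-weighted mean (over
#' configurations selected in the BBC-CV) of its average permutation
#' importance across CV folds and repeat seeds, with folds that did not
#' select the feature contributing 0. The inclusion frequency is the
#' weighted fraction of (config, seed, fold) fits containing the feature.
#' Features never selected by any selected configuration are absent.
#'
#' @param fp a [FoldPredictions-class] with importance records.
#' @param bbc a [BBCResult-class] from [bbcEvaluate()].
#' @return data.frame `feature`, `score`, `inclusion_frequency`, sorted by
#'   descending score.
#' @export
summarizeImportance <- function(fp, bbc) {
    freq <- bbc@selectionFrequency
    freq <- freq[freq > 0]
    if (!length(freq)) stop("empty configuration selection frequencies")
    scores <- list(); incl <- list()
    for (cf in names(freq)) {
        recs <- Filter(function(r) r$config == cf, fp@importance)
        if (!length(recs)) next
        nf <- length(recs)
        imp <- list(); cnt <- list()
        for (r in recs) {
            for (f in r$features) {
                imp[[f]] <- (if (is.null(imp[[f]])) 0 else imp[[f]]) +
                    (if (f %in% names(r$importance)) r$importance[[f]] else 0)
                cnt[[f]] <- (if (is.null(cnt[[f]])) 0L else cnt[[f]]) + 1L
            }
        }
        for (f in names(imp)) {
            scores[[f]] <- (if (is.null(scores[[f]])) 0 else scores[[f]]) +
                freq[[cf]] * imp[[f]] / nf
            incl[[f]] <- (if (is.null(incl[[f]])) 0 else incl[[f]]) +
                freq[[cf]] * cnt[[f]] / nf
        }
    }
    out <- data.frame(feature = names(scores),
                      score = unlist(scores),
                      inclusion_frequency = unlist(incl) / sum(freq),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
    out
}
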