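#' Fit the per-protein linear mixed model
#'
#' Fits, by REML, the model
#' `y ~ contrast + age + draw_year + appearance_outlier + composition +
#' (1|plate) + (1|np) + (1|plate:np) + (1|plate:subject)`
#' on the long data of one protein pooled across nanoparticle channels.
#' When only a single NP contributes observations, the NP, plate-by-NP and
#' subject random effects are dropped and only the plate intercept is kept.
#' The reported coefficient is the case-status log2 fold change; its p-value
#' uses the Wald statistic with a normal reference (recorded in the output).
#' Fits that fail are retried on a reduced random-effect structure (dropping
#' plate:NP, then NP); a protein whose reduced fits all fail is returned
#' with `converged = FALSE`.
#'
#' @param df long data.frame with columns `y`, `pc_status` (numeric 0/1 or a
#'   factor for the three-level contrast), `age`, `draw_year`,
#'   `appearance_outlier`, `composition`, `plate`, `np`, `subject`.
#' @param reml use REML (default `TRUE`).
#' @return one-row data.frame: `beta`, `se`, `p`, `n_np_used`, `converged`,
#'   `var_plate`, `var_np`, `var_platenp`, `var_subject`, `var_resid`, and
#'   for a three-level contrast also `beta_gg1`/`se_gg1`.
#' @export
fitProteinLmm <- function(df, reml = TRUE) {
    df <- df[!is.na(df$y), , drop = FALSE]
    n_np <- length(unique(df$np))
    if (length(unique(df$pc_status)) < 2L)
        stop("fewer than two case-status levels present")
    three <- is.factor(df$pc_status) && nlevels(df$pc_status) > 2L
    fixed <- y ~ pc_status + age + draw_year + appearance_outlier + composition
    ## drop fixed covariates that are constant in this cohort
    for (v in c("age", "draw_year", "appearance_outlier", "composition"))
        if (length(unique(df[[v]])) < 2L)
            fixed <- stats::update(fixed, paste(". ~ . -", v))
    res <- c("(1|plate)", "(1|np)", "(1|plate:np)", "(1|plate:subject)")
    chains <- if (n_np > 1L) list(res, res[c(1, 2, 4)], res[c(1, 4)], res[1])
              else list(res[1])
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    fit <- NULL
    for (ch in chains) {
        form <- stats::as.formula(paste(deparse(fixed, width.cutoff = 500),
                                        "+", paste(ch, collapse = " + ")))
        fit <- tryCatch(
            suppressMessages(lme4::lmer(form, data = df, REML = reml,
                                        control = ctrl)),
            error = function(e) NULL)
        if (!is.null(fit)) break
    }
    vc0 <- c(var_plate = NA_real_, var_np = NA_real_,
             var_platenp = NA_real_, var_subject = NA_real_,
             var_resid = NA_real_)
    if (is.null(fit)) {
        return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                          n_np_used = n_np, converged = FALSE, t(vc0)))
    }
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    coefname <- if (three) grep("^pc_status", names(b), value = TRUE)[
        nlevels(df$pc_status) - 1L] else "pc_status"
    beta <- unname(b[coefname])
    se <- sqrt(V[coefname, coefname])
    p <- 2 * stats::pnorm(-abs(beta / se))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) {
        i <- match(g, vc$grp)
        if (is.na(i)) 0 else vc$vcov[i]
    }
    vcs <- c(var_plate = getv("plate"), var_np = getv("np"),
             var_platenp = getv("plate:np"),
             var_subject = getv("plate:subject"),
             var_resid = vc$vcov[vc$grp == "Residual"])
    out <- data.frame(beta = beta, se = se, p = p, n_np_used = n_np,
                      converged = TRUE, t(vcs))
    if (three) {
        c1 <- grep("^pc_status", names(b), value = TRUE)[1L]
        out$beta_gg1 <- unname(b[c1])
        out$se_gg1 <- sqrt(V[c1, c1])
    }
    out
}

#' Differential abundance across a cohort
#'
#' Runs the full per-protein pipeline on a fold-change-normalized table:
#' detection filtering (protein-NP series missing in >= 60% of samples are
#' excluded), MNAR imputation of the best-covered NP series per protein
#' (other channels contribute observed values only), and the per-protein
#' linear mixed model, followed by Benjamini-Hochberg correction over
#' converged fits.
#'
#' @param q a fold-change-normalized [NPQuant-class] (see
#'   [foldChangeNormalize()]); sample metadata must be in `colData`.
#' @param annotations annotation list for the composition covariate, or
#'   `NULL` to omit it.
#' @param contrast `"caseDef1"` (cancer vs no cancer), `"caseDef2"`
#'   (grade group >= 2 vs the rest), or `"threeLevel"`.
#' @param max_missing detection-filter threshold (default 0.6, inclusive).
#' @param seed seed for the imputation draws; one derived stream per
#'   protein so results do not depend on iteration order.
#' @param reml use REML (default `TRUE`).
#' @return data.frame with one row per eligible protein: `protein_group`,
#'   `contrast`, `beta`, `se`, `p`, `q` (BH over converged fits),
#'   `n_np_used`, `converged` and variance components. Attribute
#'   `"p_method"` records the Wald-normal definition used.
#' @export
runDifferential <- function(q, annotations = NULL,
                            contrast = c("caseDef1", "caseDef2", "threeLevel"),
                            max_missing = 0.6, seed = 1L, reml = TRUE) {
    contrast <- match.arg(contrast)
    meta <- sampleMeta(q)
    stopifnot(all(c("case_status", "plate_id") %in% colnames(meta)))
    qf <- detectionFilter(q, max_missing = max_missing, inclusive = TRUE)
    params <- imputationParams(qf)
    comp <- if (!is.null(annotations))
        compositionCovariate(q, annotations) else NULL
    if (!is.null(comp) && anyNA(comp))
        comp[is.na(comp)] <- mean(comp, na.rm = TRUE)

    status <- switch(contrast,
        caseDef1 = as.numeric(meta$case_status),
        caseDef2 = as.numeric(meta$grade_group >= 2),
        threeLevel = factor(pmin(meta$grade_group, 2L), levels = 0:2))
    covar <- function(v, default) if (v %in% colnames(meta))
        meta[[v]] else rep(default, nrow(meta))

    rows <- vector("list", nrow(qf))
    for (i in seq_len(nrow(qf))) {
        protein <- rownames(qf)[i]
        series <- lapply(npNames(qf), function(np) assay(qf, np)[protein, ])
        names(series) <- npNames(qf)
        present <- vapply(series, function(s) any(!is.na(s)), TRUE)
        if (!any(present)) next
        series <- series[present]
        best <- names(series)[which.max(vapply(series,
                                               function(s) sum(!is.na(s)), 0L))]
        series[[best]] <- imputeMNAR(series[[best]], params,
                                     seed = stringSeed(seed, protein))
        d <- do.call(rbind, lapply(names(series), function(np) {
            data.frame(y = series[[np]], np = np,
                       sample_id = meta$sample_id,
                       stringsAsFactors = FALSE)
        }))
        d$pc_status <- status[match(d$sample_id, meta$sample_id)]
        d$age <- covar("age", 0)[match(d$sample_id, meta$sample_id)]
        d$draw_year <- covar("draw_year", 0)[match(d$sample_id, meta$sample_id)]
        d$appearance_outlier <-
            covar("appearance_outlier", 0)[match(d$sample_id, meta$sample_id)]
        d$composition <- if (is.null(comp)) 0 else comp[d$sample_id]
        d$plate <- meta$plate_id[match(d$sample_id, meta$sample_id)]
        d$subject <- d$sample_id
        d <- d[!is.na(d$y), , drop = FALSE]
        if (length(unique(d$pc_status[!is.na(d$pc_status)])) < 2L) next
        r <- fitProteinLmm(d, reml = reml)
        r$protein_group <- protein
        rows[[i]] <- r
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out) || !nrow(out))
        return(data.frame(protein_group = character(), beta = numeric(),
                          se = numeric(), p = numeric(), q = numeric()))
    out$contrast <- contrast
    out$q <- NA_real_
    conv <- which(out$converged & !is.na(out$p))
    out$q[conv] <- stats::p.adjust(out$p[conv], method = "BH")
    out <- out[, c("protein_group", "contrast",
                   setdiff(colnames(out), c("protein_group", "contrast")))]
    rownames(out) <- NULL
    attr(out, "p_method") <- "Wald z on REML fit"
    out
}

#' Fold-change agreement between two contrasts
#'
#' Pearson correlation of the mixed-model log2 fold changes over proteins
#' significant (q below `q_threshold`) in either contrast and present in
#' both.
#'
#' @param r1,r2 results of [runDifferential()].
#' @param q_threshold significance threshold (default 0.05).
#' @return list with `pearson_r` and the paired `betas` data.frame.
#' @export
compareContrasts <- function(r1, r2, q_threshold = 0.05) {
    sig <- union(r1$protein_group[!is.na(r1$q) & r1$q < q_threshold],
                 r2$protein_group[!is.na(r2$q) & r2$q < q_threshold])
    common <- intersect(intersect(sig, r1$protein_group), r2$protein_group)
    betas <- data.frame(
        protein_group = common,
        beta1 = r1$beta[match(common, r1$protein_group)],
        beta2 = r2$beta[match(common, r2$protein_group)])
    if (nrow(betas) < 3L) {
        warning("fewer than 3 paired significant proteins; r undefined")
        return(list(pearson_r = NA_real_, betas = betas))
    }
    list(pearson_r = stats::cor(betas$beta1, betas$beta2), betas = betas)
}
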