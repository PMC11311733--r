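#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<-
NULL

#' Multi-nanoparticle protein quantification container
#'
#' `NPQuant` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay per nanoparticle (NP) channel. Rows are protein groups, columns are
#' samples, and entries are log2 MaxLFQ protein-group intensities with `NA`
#' marking observations that were not quantified. All assays share dimensions
#' and dimnames; `colData` carries the per-sample clinical and design
#' covariates (see [sampleMeta()]).
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("NPQuant", contains = "SummarizedExperiment")

setValidity("NPQuant", function(object) {
    msg <- character()
    if (length(assays(object)) < 1L)
        msg <- c(msg, "at least one nanoparticle assay is required")
    nms <- assayNames(object)
    if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
        msg <- c(msg, "assay (nanoparticle) names must be unique and non-empty")
    for (i in seq_along(assays(object))) {
        a <- assays(object)[[i]]
        if (!is.numeric(a))
            msg <- c(msg, sprintf("assay %d is not numeric", i))
        else if (any(is.infinite(a)))
            msg <- c(msg, sprintf("assay %d contains non-finite intensities", i))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein group rownames must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample colnames must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct an NPQuant object
#'
#' @param assays named list of numeric matrices (proteins x samples), one per
#'   nanoparticle channel; all must share dimensions and dimnames.
#' @param meta optional `data.frame`/`DataFrame` of per-sample metadata whose
#'   rownames (or `sample_id` column) match the assay column names.
#' @param metadata optional list stored in the object metadata.
#' @return an [NPQuant-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
#' q <- NPQuant(list(NP1 = m))
#' @export
NPQuant <- function(assays, meta = NULL, metadata = list()) {
    if (is.null(names(assays)))
        names(assays) <- paste0("NP", seq_along(assays))
    if (!is.null(meta)) {
        meta <- as.data.frame(meta)
        if ("sample_id" %in% colnames(meta) &&
            !identical(rownames(meta), as.character(meta$sample_id)))
            rownames(meta) <- meta$sample_id
        meta <- meta[colnames(assays[[1L]]), , drop = FALSE]
        cd <- DataFrame(meta)
    } else {
        cd <- DataFrame(row.names = colnames(assays[[1L]]))
    }
    se <- SummarizedExperiment(assays = assays, colData = cd,
                               metadata = metadata)
    new("NPQuant", se)
}

#' @describeIn NPQuant nanoparticle channel names.
#' @param x an `NPQuant` object.
#' @export
npNames <- function(x) assayNames(x)

#' @describeIn NPQuant per-sample metadata as a plain data.frame with a
#'   `sample_id` column.
#' @export
sampleMeta <- function(x) {
    df <- as.data.frame(colData(x))
    df$sample_id <- colnames(x)
    df
}

#' @export
setMethod("show", "NPQuant", function(object) {
    cat("NPQuant:", nrow(object), "protein groups x", ncol(object),
        "samples,", length(assays(object)), "nanoparticle channels (",
        paste(assayNames(object), collapse = ", "), ")\n")
    nmiss <- vapply(assays(object), function(a) mean(is.na(a)), 0)
    cat("  missingness per NP:",
        paste(sprintf("%s=%.1f%%", assayNames(object), 100 * nmiss),
              collapse = " "), "\n")
    if (isTRUE(metadata(object)$normalized))
        cat("  fold-change normalized\n")
})

#' Simulation parameters for a synthetic serum cohort
#'
#' Defaults encode the desk-scale study conditions the generator emulates:
#' 200 subjects on plates of 15 with 5 nanoparticle channels, log-normal
#' protein base abundance spanning a 10 log2-unit dynamic range,
#' plate/NP/plate-by-NP/subject variance components, a per-sample
#' extracellular composition shift, intensity-dependent (left-censored)
#' missingness, 10% planted case-associated proteins at a mean |log2FC| of 1,
#' and a clinical benchmark score with AUC 0.70.
#'
#' @slot n_subjects,n_proteins,n_np,n_per_plate cohort dimensions.
#' @slot case_fraction fraction of subjects that are cases.
#' @slot n_differential number of planted differential proteins.
#' @slot effect_size_log2 mean absolute planted log2 fold change.
#' @slot plate_sd,np_sd,platenp_sd,subject_sd,resid_sd random-effect and
#'   residual standard deviations on the log2 scale.
#' @slot composition_sd sd of the per-sample extracellular composition scalar.
#' @slot missing_intercept,missing_slope logistic model of the missingness
#'   probability versus centred intensity; a negative slope makes low
#'   intensities more often missing (MNAR) and `missing_slope = 0` gives
#'   MCAR. The defaults place a steep censor near the low end of the
#'   dynamic range (50% missing two sd below the grand mean), emulating an
#'   instrument detection limit.
#' @slot extracellular_fraction fraction of proteins annotated Extracellular
#'   and carrying a nonzero composition loading.
#' @slot benchmark_auc target AUC of the simulated clinical benchmark score.
#' @slot seed integer seed; same seed implies byte-identical cohorts.
#' @export
setClass("SimParams", representation(
    n_subjects = "integer", n_proteins = "integer", n_np = "integer",
    n_per_plate = "integer", case_fraction = "numeric",
    n_differential = "integer", effect_size_log2 = "numeric",
    plate_sd = "numeric", np_sd = "numeric", platenp_sd = "numeric",
    subject_sd = "numeric", resid_sd = "numeric", composition_sd = "numeric",
    missing_intercept = "numeric", missing_slope = "numeric",
    extracellular_fraction = "numeric", benchmark_auc = "numeric",
    seed = "integer"),
    prototype(
        n_subjects = 200L, n_proteins = 300L, n_np = 5L, n_per_plate = 15L,
        case_fraction = 0.5, n_differential = 30L, effect_size_log2 = 1,
        plate_sd = 0.2, np_sd = 0.3, platenp_sd = 0.1, subject_sd = 0.3,
        resid_sd = 0.3, composition_sd = 0.5,
        missing_intercept = -6, missing_slope = -2,
        extracellular_fraction = 0.25, benchmark_auc = 0.7, seed = 1L))

setValidity("SimParams", function(object) {
    msg <- character()
    sds <- c(object@plate_sd, object@np_sd, object@platenp_sd,
             object@subject_sd, object@resid_sd, object@composition_sd)
    if (any(sds < 0)) msg <- c(msg, "standard deviations must be >= 0")
    fr <- c(object@case_fraction, object@extracellular_fraction)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@n_differential > object@n_proteins)
        msg <- c(msg, "n_differential must be <= n_proteins")
    if (object@n_subjects < 1L || object@n_proteins < 1L ||
        object@n_np < 1L || object@n_per_plate < 1L)
        msg <- c(msg, "cohort dimensions must be positive")
    if (object@benchmark_auc <= 0.5 || object@benchmark_auc >= 1)
        msg <- c(msg, "benchmark_auc must lie in (0.5, 1)")
    if (length(msg)) msg else TRUE
})

#' Create simulation parameters
#'
#' @param ... slot values overriding the defaults of [SimParams-class].
#' @return a validated `SimParams` object.
#' @examples
#' p <- simParams(n_subjects = 60, n_proteins = 50, seed = 7)
#' @export
simParams <- function(...) {
    args <- list(...)
    ints <- c("n_subjects", "n_proteins", "n_np", "n_per_plate",
              "n_differential", "seed")
    for (nm in intersect(names(args), ints)) args[[nm]] <- as.integer(args[[nm]])
    ## keep the 10% planted fraction when only the protein count is changed
    if ("n_proteins" %in% names(args) && !"n_differential" %in% names(args))
        args$n_differential <- as.integer(round(0.1 * args$n_proteins))
    do.call(new, c(list("SimParams"), args))
}

#' @export
setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        "SimParams: %d subjects x %d proteins x %d NPs (plates of %d)\n",
        object@n_subjects, object@n_proteins, object@n_np, object@n_per_plate))
    cat(sprintf("  %d differential proteins, mean |log2FC| %.2f, seed %d\n",
                object@n_differential, object@effect_size_log2, object@seed))
})

#' Pooled out-of-fold classifier predictions
#'
#' Result container of [nestedCV()]: out-of-fold class-1 probabilities for
#' every subject under every pipeline configuration and repeat seed — the
#' substrate of bootstrapped bias-corrected cross-validation.
#'
#' @slot scores numeric array subjects x configurations x seeds of
#'   out-of-fold scores.
#' @slot pooled subjects x configurations matrix, scores averaged over seeds.
#' @slot labels named binary vector of subject class labels.
#' @slot configs data.frame of configurations (columns `config`, `m`, `rho`).
#' @slot folds integer matrix subjects x seeds of outer-fold ids.
#' @slot importance list of per (config, seed, fold) records with selected
#'   features and permutation importances.
#' @slot seeds integer vector of CV repeat seeds.
#' @export
setClass("FoldPredictions", representation(
    scores = "array", pooled = "matrix", labels = "numeric",
    configs = "data.frame", folds = "matrix", importance = "list",
    seeds = "integer"))

setValidity("FoldPredictions", function(object) {
    msg <- character()
    if (any(is.na(object@pooled)))
        msg <- c(msg, "every subject must be scored for every configuration")
    if (nrow(object@pooled) != length(object@labels))
        msg <- c(msg, "labels must match pooled score rows")
    if (ncol(object@pooled) != nrow(object@configs))
        msg <- c(msg, "configs must match pooled score columns")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "FoldPredictions", function(object) {
    cat(sprintf(
        "FoldPredictions: %d subjects x %d configurations x %d seed repeats\n",
        nrow(object@pooled), ncol(object@pooled), length(object@seeds)))
    cat(sprintf("  prevalence %.2f\n", mean(object@labels)))
})

#' Bootstrapped bias-corrected cross-validation result
#'
#' @slot iterations data.frame with one row per bootstrap iteration: the
#'   in-bag selected configuration, out-of-bag AUC / average PPV / average
#'   NPV for the signature and (if supplied) the benchmark, and their
#'   differences.
#' @slot summary data.frame of point estimates (means over iterations) and
#'   2.5/97.5 percentile confidence limits per metric.
#' @slot selectionFrequency named numeric vector, fraction of iterations in
#'   which each configuration was selected (sums to 1).
#' @slot B number of bootstrap iterations.
#' @export
setClass("BBCResult", representation(
    iterations = "data.frame", summary = "data.frame",
    selectionFrequency = "numeric", B = "integer"))

#' @export
setMethod("show", "BBCResult", function(object) {
    cat(sprintf("BBCResult: %d bootstrap iterations\n", object@B))
    s <- object@summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-14s %.3f (%.3f, %.3f)\n", s$metric[i],
                    s$estimate[i], s$lower[i], s$upper[i]))
})
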