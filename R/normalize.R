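#' High-coverage reference protein set
#'
#' Protein groups detected (in any nanoparticle channel) in at least
#' `min_detect` of the samples; these inform the per-(sample, NP)
#' normalization shifts.
#'
#' @param q an [NPQuant-class] object.
#' @param min_detect minimum detection fraction (default 0.8, boundary
#'   inclusive).
#' @return character vector of protein groups.
#' @export
referenceSet <- function(q, min_detect = 0.8) {
    det <- Reduce(`|`, lapply(npNames(q), function(np) !is.na(assay(q, np))))
    frac <- rowMeans(det)
    ref <- rownames(q)[frac >= min_detect]
    if (!length(ref))
        warning("empty reference set; shifts will be computed over all proteins")
    ref
}

#' Fold-change normalization of log2 intensities
#'
#' For each nanoparticle channel, the fold change of a protein in a sample
#' is its log2 intensity minus the protein's cohort median (the reference
#' profile). The shift of a (sample, NP) run is the median fold change over
#' the reference proteins, and every intensity of that run is normalized by
#' subtracting the shift. Only reference proteins inform shifts; all
#' proteins are normalized. Runs with no reference-protein observation get
#' shift 0.
#'
#' The reference profile is estimated once per cohort and frozen: it is
#' stored in the object metadata, and normalizing an already-normalized
#' object (or passing `profile` explicitly, e.g. one fitted on training
#' samples) computes shifts against that frozen profile. A sample's shift
#' then depends only on its own intensities, which makes the normalizer
#' exactly idempotent and exactly location-equivariant; use `refit = TRUE`
#' to force re-estimation of the profile from the current table.
#'
#' @param q an [NPQuant-class] object of log2 intensities.
#' @param ref reference protein set, default [referenceSet()] of `q` (all
#'   proteins when empty). Ignored when a frozen profile is used, which
#'   carries its own reference set.
#' @param profile optional frozen reference profile from
#'   [referenceProfile()].
#' @param refit re-estimate the profile even for already-normalized input.
#' @return an [NPQuant-class] with normalized assays; per-(sample, NP)
#'   shifts in `metadata()$shifts`, the frozen profile in
#'   `metadata()$norm_profile`, and `metadata()$normalized` set.
#' @export
foldChangeNormalize <- function(q, ref = NULL, profile = NULL,
                                refit = FALSE) {
    if (is.null(profile) && !refit)
        profile <- metadata(q)$norm_profile
    if (!is.null(profile)) {
        medians <- profile$medians
        ref <- profile$ref
    } else {
        if (is.null(ref)) ref <- referenceSet(q)
        if (!length(ref)) ref <- rownames(q)
        medians <- lapply(npNames(q), function(np) rowMedians_(assay(q, np)))
        names(medians) <- npNames(q)
    }
    assays_out <- list()
    shifts <- list()
    for (np in npNames(q)) {
        m <- assay(q, np)
        med <- medians[[np]][rownames(m)]
        fc <- m - med
        sh <- colMedians_(fc[intersect(ref, rownames(m)), , drop = FALSE])
        sh[is.na(sh)] <- 0
        assays_out[[np]] <- sweep(m, 2L, sh, `-`)
        shifts[[np]] <- data.frame(sample_id = colnames(m), np_id = np,
                                   shift = unname(sh),
                                   stringsAsFactors = FALSE)
    }
    md <- metadata(q)
    md$shifts <- do.call(rbind, shifts)
    md$normalized <- TRUE
    md$norm_profile <- list(medians = medians, ref = ref)
    NPQuant(assays_out, meta = as.data.frame(colData(q)), metadata = md)
}

#' Frozen normalization reference profile
#'
#' @param q a normalized [NPQuant-class].
#' @return list with `medians` (per-NP named vectors of protein cohort
#'   medians) and `ref` (the reference protein set).
#' @export
referenceProfile <- function(q) {
    pr <- metadata(q)$norm_profile
    if (is.null(pr)) stop("object carries no reference profile")
    pr
}

#' Per-(sample, NP) normalization shifts
#'
#' @param q an [NPQuant-class] returned by [foldChangeNormalize()].
#' @return data.frame with columns `sample_id`, `np_id`, `shift`.
#' @export
normShifts <- function(q) {
    sh <- metadata(q)$shifts
    if (is.null(sh)) stop("object carries no shifts; normalize it first")
    sh
}

#' Extracellular sample-composition covariate
#'
#' One scalar per sample: the median log2 fold change (relative to each
#' protein's cohort median within its NP channel) over all observed
#' (protein, NP) pairs annotated with `term` (default the "Extracellular"
#' GO Cellular Component). It adjusts downstream models for variability in
#' blood subfraction enrichment of the nanoparticle corona. Samples with no
#' annotated observation get `NA`; downstream consumers mean-impute.
#'
#' @param q an [NPQuant-class] object.
#' @param annotations named list mapping term to protein groups.
#' @param term annotation term to use.
#' @return named numeric vector over samples.
#' @export
compositionCovariate <- function(q, annotations, term = "Extracellular") {
    prot <- intersect(annotations[[term]], rownames(q))
    if (!length(prot))
        stop("no annotated protein is present in the quantification table")
    fcs <- lapply(npNames(q), function(np) {
        m <- assay(q, np)[prot, , drop = FALSE]
        m - rowMedians_(m)
    })
    stacked <- do.call(rbind, fcs)
    out <- colMedians_(stacked)
    setNames(out, colnames(q))
}

#' Detection filter on (protein, NP) series
#'
#' Excludes a protein-NP pair when its missing fraction across samples
#' reaches the threshold. With `inclusive = TRUE` (default, the differential
#' analysis rule) a series missing in >= `max_missing` of samples is
#' dropped; with `inclusive = FALSE` (the classifier rule) only strictly
#' greater missingness is dropped.
#'
#' @param q an [NPQuant-class] object.
#' @param max_missing maximum missing fraction (default 0.6).
#' @param inclusive drop at the boundary (default `TRUE`).
#' @param drop remove proteins left with no surviving NP series
#'   (default `TRUE`).
#' @return filtered [NPQuant-class]; excluded series are set entirely `NA`.
#' @export
detectionFilter <- function(q, max_missing = 0.6, inclusive = TRUE,
                            drop = TRUE) {
    assays_out <- list()
    keep_any <- rep(FALSE, nrow(q))
    for (np in npNames(q)) {
        m <- assay(q, np)
        miss <- rowMeans(is.na(m))
        out <- if (inclusive) miss >= max_missing else miss > max_missing
        m[out, ] <- NA_real_
        assays_out[[np]] <- m
        keep_any <- keep_any | !out
    }
    md <- metadata(q)
    res <- NPQuant(assays_out, meta = as.data.frame(colData(q)),
                   metadata = md)
    if (drop) res[keep_any, ] else res
}

#' Nanoparticle channel with the most complete series for a protein
#'
#' @param q an [NPQuant-class] object.
#' @param protein protein group id.
#' @return NP name with the maximal non-missing count; ties go to the
#'   first channel in assay order.
#' @export
selectBestNP <- function(q, protein) {
    if (!protein %in% rownames(q)) stop("unknown protein group: ", protein)
    cnt <- vapply(npNames(q),
                  function(np) sum(!is.na(assay(q, np)[protein, ])), 0L)
    npNames(q)[which.max(cnt)]
}

#' Global imputation parameters for left-censored missingness
#'
#' `I0` and `sigma` are the mean and standard deviation of all non-missing
#' protein log2 intensities in the dataset; imputed values are drawn from
#' `Normal(I0 - downshift * sigma, width * sigma)`.
#'
#' @param q an [NPQuant-class] object or numeric vector/matrix of log2
#'   intensities.
#' @param downshift mean downshift in sd units (default 1.8).
#' @param width width of the imputation distribution in sd units
#'   (default 0.3).
#' @param per_sample estimate `I0`/`sigma` per sample instead of globally
#'   (sensitivity-analysis variant; default `FALSE`).
#' @return list of class `ImputationParams` with `I0`, `sigma`, `downshift`,
#'   `width` (vectors over samples when `per_sample`).
#' @export
imputationParams <- function(q, downshift = 1.8, width = 0.3,
                             per_sample = FALSE) {
    vals <- if (is(q, "NPQuant")) {
        if (per_sample) {
            m <- do.call(rbind, lapply(npNames(q), function(np) assay(q, np)))
            list(I0 = colMeans(m, na.rm = TRUE),
                 sigma = apply(m, 2L, stats::sd, na.rm = TRUE))
        } else {
            v <- unlist(lapply(npNames(q), function(np) assay(q, np)))
            list(I0 = mean(v, na.rm = TRUE), sigma = stats::sd(v, na.rm = TRUE))
        }
    } else {
        v <- as.numeric(q)
        list(I0 = mean(v, na.rm = TRUE), sigma = stats::sd(v, na.rm = TRUE))
    }
    if (any(!is.finite(vals$sigma)) || any(vals$sigma <= 0))
        stop("sigma must be positive; too few observed intensities")
    structure(c(vals, list(downshift = downshift, width = width)),
              class = "ImputationParams")
}

#' Impute missing values from a downshifted normal (MNAR model)
#'
#' Each missing entry is replaced by an independent draw from
#' `Normal(I0 - downshift * sigma, width * sigma)`, encoding the assumption
#' that missing intensities sit below the detection limit. Observed entries
#' are untouched; draws are deterministic under `seed`.
#'
#' @param x numeric vector or matrix with `NA`s.
#' @param params an `ImputationParams` object from [imputationParams()].
#' @param seed integer seed.
#' @return `x` with missing entries imputed.
#' @export
imputeMNAR <- function(x, params, seed = 1L) {
    stopifnot(inherits(params, "ImputationParams"))
    miss <- which(is.na(x))
    if (!length(miss)) return(x)
    ## draws are assigned in name order so that results do not depend on
    ## the storage order of a named series
    ord <- if (!is.null(names(x))) miss[order(names(x)[miss])] else miss
    withSeed(seed, {
        x[ord] <- stats::rnorm(length(ord),
                               params$I0 - params$downshift * params$sigma,
                               params$width * params$sigma)
    })
    x
}
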