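#' Simulate a synthetic serum protein-corona cohort with ground truth
#'
#' Generates a cohort with the statistical structure the downstream analysis
#' assumes: per-protein base abundances drawn over a wide (10 log2-unit)
#' dynamic range; an observation model
#' `y = base + case * log2FC + plate + NP + plate:NP + subject +
#' composition * loading + noise` with independent Gaussian variance
#' components; per-sample extracellular composition scalars loading only on
#' proteins annotated "Extracellular"; left-censored missingness through a
#' logistic model in the true intensity (lower intensities are more often
#' missing when `missing_slope < 0`); plates filled in blocks with
#' stratified case/control allocation; and a binormal clinical benchmark
#' score at the requested AUC. Output is byte-identical for a given seed.
#'
#' @param params a [SimParams-class] object, see [simParams()].
#' @return list with elements
#'   \describe{
#'     \item{quant}{an [NPQuant-class] of log2 intensities with sample
#'       metadata in `colData`}
#'     \item{annotations}{named list of annotation terms to protein groups
#'       (includes `"Extracellular"`)}
#'     \item{truth}{list with `proteins` (per-protein `is_differential`,
#'       `true_log2fc`, `composition_loading`) and `samples` (per-sample
#'       `true_composition`, `plate_effect`) data.frames}
#'   }
#' @examples
#' sim <- simulateCohort(simParams(n_subjects = 30, n_proteins = 20, seed = 3))
#' sim$quant
#' @export
simulateCohort <- function(params) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    p <- params
    withSeed(p@seed, {
        ns <- p@n_subjects; npr <- p@n_proteins; nnp <- p@n_np
        sample_id <- sprintf("S%03d", seq_len(ns))
        proteins <- sprintf("PG%04d", seq_len(npr))
        nps <- paste0("NP", seq_len(nnp))

        ## clinical metadata
        n_case <- round(p@case_fraction * ns)
        case <- sample(rep(c(1L, 0L), c(n_case, ns - n_case)))
        gg <- ifelse(case == 1L, sample(1:2, ns, replace = TRUE), 0L)
        psa <- pmin(pmax(stats::rlnorm(ns, log(5), 0.8), 0.1), 50)
        age <- stats::rnorm(ns, 64, 7)
        draw_year <- sample(2000:2016, ns, replace = TRUE)
        race <- sample(c("groupA", "groupB", "groupC"), ns, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15))
        appearance <- stats::rbinom(ns, 1L, 0.02)

        ## plates: round-robin within shuffled case and control streams;
        ## controls fill plates in reverse order so remainders of the two
        ## streams land on different plates and no plate exceeds its size
        n_plate <- ceiling(ns / p@n_per_plate)
        plate <- integer(ns)
        for (cl in c(1L, 0L)) {
            idx <- sample(which(case == cl))
            ids <- if (cl == 1L) seq_len(n_plate) else rev(seq_len(n_plate))
            plate[idx] <- rep_len(ids, length(idx))
        }
        plate_id <- sprintf("plate%02d", plate)

        ## protein truth
        mu <- stats::runif(npr, 10, 20)
        is_diff <- rep(FALSE, npr)
        if (p@n_differential > 0L)
            is_diff[sample.int(npr, p@n_differential)] <- TRUE
        fc_mag <- stats::rgamma(npr, shape = 4,
                                rate = 4 / max(p@effect_size_log2, 1e-12))
        fc <- ifelse(is_diff, fc_mag * sample(c(-1, 1), npr, TRUE), 0)
        n_extra <- round(p@extracellular_fraction * npr)
        extracellular <- rep(FALSE, npr)
        if (n_extra > 0L) extracellular[sample.int(npr, n_extra)] <- TRUE
        loading <- ifelse(extracellular, stats::runif(npr, 0.5, 1.5), 0)

        ## variance components, drawn per protein: each protein's model
        ## (fit separately downstream) has its own plate, NP, plate x NP
        ## and subject-within-plate effects
        u_pp <- matrix(stats::rnorm(npr * n_plate, 0, p@plate_sd),
                       npr, n_plate)
        v_pn <- matrix(stats::rnorm(npr * nnp, 0, p@np_sd), npr, nnp)
        w_ppn <- array(stats::rnorm(npr * n_plate * nnp, 0, p@platenp_sd),
                       c(npr, n_plate, nnp))
        z_ps <- matrix(stats::rnorm(npr * ns, 0, p@subject_sd), npr, ns)
        comp <- stats::rnorm(ns, 0, p@composition_sd)

        assays <- vector("list", nnp)
        grand <- NULL
        full <- vector("list", nnp)
        for (j in seq_len(nnp)) {
            base <- matrix(mu, npr, ns) +
                outer(fc, as.numeric(case)) +
                u_pp[, plate, drop = FALSE] +
                v_pn[, j] +
                w_ppn[, plate, j] +
                z_ps +
                outer(loading, comp) +
                matrix(stats::rnorm(npr * ns, 0, p@resid_sd), npr, ns)
            dimnames(base) <- list(proteins, sample_id)
            full[[j]] <- base
        }
        grand <- mean(unlist(lapply(full, as.vector)))
        for (j in seq_len(nnp)) {
            pm <- stats::plogis(p@missing_intercept +
                                p@missing_slope * (full[[j]] - grand))
            miss <- matrix(stats::runif(npr * ns), npr, ns) < pm
            a <- full[[j]]
            a[miss] <- NA_real_
            assays[[j]] <- a
        }
        names(assays) <- nps

        benchmark <- simulateBenchmarkScores(case, p@benchmark_auc,
                                             seed = childSeed(p@seed, 777L))
        meta <- data.frame(
            sample_id = sample_id, subject_id = sample_id, cohort = "SYNTH",
            case_status = case, grade_group = gg, psa = psa, age = age,
            draw_year = draw_year, race_ethnicity = race,
            appearance_outlier = appearance, plate_id = plate_id,
            split = "unassigned", benchmark_score = benchmark,
            stringsAsFactors = FALSE, row.names = sample_id)

        annotations <- list(Extracellular = proteins[extracellular])
        ## a few random terms so enrichment is exercisable out of the box
        for (t in 1:3)
            annotations[[paste0("term", t)]] <-
                sort(sample(proteins, max(3L, round(npr / 10))))

        truth <- list(
            proteins = data.frame(
                protein_group = proteins, is_differential = is_diff,
                true_log2fc = fc, composition_loading = loading,
                base_mean = mu, stringsAsFactors = FALSE),
            samples = data.frame(
                sample_id = sample_id, true_composition = comp,
                plate = plate_id,
                mean_plate_effect = colMeans(u_pp)[plate],
                stringsAsFactors = FALSE))

        list(quant = NPQuant(assays, meta = meta), annotations = annotations,
             truth = truth)
    })
}

#' Simulate a sample-by-peptide identification matrix
#'
#' Peptide detection probabilities are drawn from a heavy-tailed Beta law so
#' that cumulative unique-identification curves saturate, emulating spectral
#' library accumulation behaviour.
#'
#' @param n_samples,n_peptides matrix dimensions.
#' @param shape1,shape2 Beta parameters of the per-peptide detection
#'   probability (defaults Beta(0.2, 2)).
#' @param seed integer seed.
#' @return logical matrix with sample rownames and peptide colnames.
#' @export
simulateIdMatrix <- function(n_samples, n_peptides, shape1 = 0.2,
                             shape2 = 2, seed = 1L) {
    stopifnot(n_samples >= 1L, n_peptides >= 1L)
    withSeed(seed, {
        prob <- stats::rbeta(n_peptides, shape1, shape2)
        m <- matrix(stats::runif(n_samples * n_peptides) <
                        rep(prob, each = n_samples),
                    n_samples, n_peptides,
                    dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                    sprintf("pep%05d", seq_len(n_peptides))))
        m
    })
}

#' Simulate a clinical benchmark risk score with a target AUC
#'
#' Scores follow the binormal model: controls are standard normal and cases
#' are shifted by `sqrt(2) * qnorm(target_auc)`, then mapped monotonically
#' to [0, 1], so the expected AUC equals `target_auc`.
#'
#' @param case_status binary vector (1 = case).
#' @param target_auc target AUC in (0.5, 1).
#' @param seed integer seed.
#' @return numeric score vector in [0, 1].
#' @export
simulateBenchmarkScores <- function(case_status, target_auc, seed = 1L) {
    if (target_auc < 0.5 || target_auc >= 1)
        stop("target_auc must lie in [0.5, 1)")
    delta <- sqrt(2) * stats::qnorm(target_auc)
    withSeed(seed, {
        raw <- stats::rnorm(length(case_status), mean = delta * case_status)
        stats::plogis(raw)
    })
}
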