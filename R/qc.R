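#' Percent coefficient of variation per protein, NP and stratum
#'
#' Computes %CV of the unnormalized, linear-scale intensities (`2^log2`) for
#' each protein group within each nanoparticle channel, separately per sample
#' stratum (typically cancer status). The sample standard deviation (n-1
#' denominator) is used; the CV is undefined (`NA`) when fewer than two
#' observations are available or the mean is zero.
#'
#' @param q an [NPQuant-class] object of log2 intensities.
#' @param strata named character/factor vector mapping `sample_id` to a
#'   stratum; samples not named are pooled into stratum `"all"`. `NULL`
#'   (default) computes one stratum for the whole cohort.
#' @return data.frame with columns `protein_group`, `np_id`, `stratum`,
#'   `cv_percent`, `n_obs`.
#' @export
computeCV <- function(q, strata = NULL) {
    samples <- colnames(q)
    if (is.null(strata)) {
        strata <- setNames(rep("all", length(samples)), samples)
    } else {
        strata <- setNames(as.character(strata)[match(samples, names(strata))],
                           samples)
        strata[is.na(strata)] <- "all"
    }
    out <- list()
    for (np in npNames(q)) {
        m <- 2^assay(q, np)
        for (st in unique(strata)) {
            sub <- m[, strata == st, drop = FALSE]
            n_obs <- rowSums(!is.na(sub))
            mu <- rowMeans(sub, na.rm = TRUE)
            sd_ <- apply(sub, 1L, stats::sd, na.rm = TRUE)
            cv <- ifelse(n_obs >= 2L & mu != 0, 100 * sd_ / mu, NA_real_)
            out[[length(out) + 1L]] <- data.frame(
                protein_group = rownames(m), np_id = np, stratum = st,
                cv_percent = cv, n_obs = n_obs, stringsAsFactors = FALSE,
                row.names = NULL)
        }
    }
    if (!length(out))
        return(data.frame(protein_group = character(), np_id = character(),
                          stratum = character(), cv_percent = numeric(),
                          n_obs = integer()))
    do.call(rbind, out)
}

#' Flag samples with outlier protein identification counts
#'
#' A sample is flagged when its number of distinct protein groups with at
#' least one quantified intensity falls below a fraction (default 25%) of
#' the mean identification count of the remaining samples (leave-one-out
#' mean, so a single collapsed sample cannot drag the threshold down with
#' it). Single-sample tables are never flagged.
#'
#' @param q an [NPQuant-class] object.
#' @param fraction flagging threshold as a fraction of the mean count.
#' @param per_np if `TRUE`, count identifications per nanoparticle channel
#'   and flag a sample when any channel falls below the threshold of that
#'   channel's mean; the default counts a protein once if seen in any NP.
#' @return named logical vector over samples.
#' @export
flagOutlierSamples <- function(q, fraction = 0.25, per_np = FALSE) {
    looFlag <- function(cnt) {
        n <- length(cnt)
        if (n < 2L) return(rep(FALSE, n))
        loo_mean <- (sum(cnt) - cnt) / (n - 1)
        cnt < fraction * loo_mean
    }
    if (per_np) {
        flags <- rep(FALSE, ncol(q))
        for (np in npNames(q))
            flags <- flags | looFlag(colSums(!is.na(assay(q, np))))
        return(setNames(flags, colnames(q)))
    }
    det <- Reduce(`|`, lapply(npNames(q), function(np) !is.na(assay(q, np))))
    setNames(looFlag(colSums(det)), colnames(q))
}

#' Flag outlier peptide recovery on a plate
#'
#' Flags a preparation when its recovered peptide mass is more than 2-fold
#' above or below 0.5-fold of the median mass across all samples on the same
#' plate for the same nanoparticle.
#'
#' @param masses data.frame with columns `plate_id`, `sample_id`, `np_id`,
#'   `mass` (micrograms, strictly positive).
#' @param fold flagging fold-change bound (default 2).
#' @return `masses` with added columns `ratio` and `flagged`.
#' @export
flagPeptideRecovery <- function(masses, fold = 2) {
    masses <- as.data.frame(masses)
    if (any(!is.finite(masses$mass)) || any(masses$mass <= 0))
        stop("peptide masses must be positive")
    grp <- interaction(masses$plate_id, masses$np_id, drop = TRUE)
    med <- stats::ave(masses$mass, grp, FUN = stats::median)
    masses$ratio <- masses$mass / med
    masses$flagged <- masses$ratio > fold | masses$ratio < 1 / fold
    masses
}
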