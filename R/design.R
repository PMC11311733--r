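#' Stratified plate (batch) randomization with balance checks
#'
#' Cases and controls are allocated round-robin across plates within
#' shuffled strata so approximately equal numbers of cases and controls
#' land on each plate, mirroring batch randomization for plates of 15
#' experimental samples. Balance of age and PSA across plates is checked
#' with Kruskal-Wallis tests and of cohort and race/ethnicity with chi-square
#' tests; the plan is rerandomized while any balance p-value falls below
#' `alpha_balance`, up to `max_attempts`, after which the best-balanced plan
#' seen is returned with a warning flag.
#'
#' @param meta sample metadata data.frame with columns `sample_id`,
#'   `case_status`, `age`, `psa`, `cohort`, `race_ethnicity`.
#' @param n_per_plate maximum experimental samples per plate (default 15).
#' @param max_attempts maximum rerandomizations (default 20).
#' @param alpha_balance balance-test significance threshold (default 0.05).
#' @param seed integer seed; the accepted plan and the number of
#'   rerandomizations are reproducible.
#' @return list of class `DesignPlan` with elements `plate` (named character
#'   vector), `balance` (per-variable statistic and p), `n_rerandomizations`,
#'   and `warning` (TRUE when `max_attempts` was exhausted).
#' @export
assignPlates <- function(meta, n_per_plate = 15L, max_attempts = 20L,
                         alpha_balance = 0.05, seed = 1L) {
    meta <- as.data.frame(meta)
    stopifnot(all(c("sample_id", "case_status") %in% colnames(meta)))
    n <- nrow(meta)
    n_plate <- ceiling(n / n_per_plate)
    withSeed(seed, {
        best <- NULL; best_minp <- -Inf; attempt <- 0L
        repeat {
            plate <- integer(n)
            cls <- unique(meta$case_status)
            for (ci in seq_along(cls)) {
                idx <- sample(which(meta$case_status == cls[ci]))
                ids <- if (ci %% 2L) seq_len(n_plate) else
                    rev(seq_len(n_plate))
                plate[idx] <- rep_len(ids, length(idx))
            }
            ## round-robin from two streams can overfill a plate by one;
            ## bump the plate count and redo if so
            if (max(tabulate(plate, n_plate)) > n_per_plate) {
                n_plate <- n_plate + 1L
                next
            }
            bal <- plateBalance(meta, plate)
            minp <- suppressWarnings(min(bal$p, na.rm = TRUE))
            if (!is.finite(minp)) minp <- 1
            if (minp > best_minp) {
                best <- list(plate = plate, balance = bal)
                best_minp <- minp
            }
            ok <- minp >= alpha_balance
            if (ok || attempt >= max_attempts) {
                plan <- list(
                    plate = setNames(sprintf("plate%02d", best$plate),
                                     meta$sample_id),
                    balance = best$balance,
                    n_rerandomizations = attempt,
                    warning = !ok)
                class(plan) <- "DesignPlan"
                return(plan)
            }
            attempt <- attempt + 1L
        }
    })
}

# Balance tests across plates: rank tests for continuous covariates,
# chi-square on counts for categorical ones. Degenerate variables
# (single level, all missing) yield p = NA.
plateBalance <- function(meta, plate) {
    res <- list()
    test_cont <- function(v) {
        x <- meta[[v]]
        if (is.null(x) || length(unique(x)) < 2L || length(unique(plate)) < 2L)
            return(c(NA_real_, NA_real_))
        k <- stats::kruskal.test(x, factor(plate))
        c(unname(k$statistic), k$p.value)
    }
    test_cat <- function(v) {
        x <- meta[[v]]
        if (is.null(x) || length(unique(x)) < 2L || length(unique(plate)) < 2L)
            return(c(NA_real_, NA_real_))
        k <- suppressWarnings(stats::chisq.test(table(x, plate)))
        c(unname(k$statistic), k$p.value)
    }
    vars <- list(age = "cont", psa = "cont",
                 cohort = "cat", race_ethnicity = "cat")
    for (v in names(vars)) {
        r <- if (vars[[v]] == "cont") test_cont(v) else test_cat(v)
        res[[v]] <- data.frame(variable = v, statistic = r[1L], p = r[2L])
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Stratified train/validation split
#'
#' Assigns a target fraction of samples to the training set within each
#' cross-stratum of case status, race/ethnicity, and quartile bins of age
#' and PSA, so both sets are proportionally representative. Within a
#' stratum of size n, `round(train_fraction * n)` samples go to training;
#' strata of size 1 are assigned to training.
#'
#' @param meta sample metadata with `sample_id`, `case_status`,
#'   `race_ethnicity`, `age`, `psa`.
#' @param train_fraction target training fraction (default 0.7).
#' @param seed integer seed.
#' @return named character vector over samples with values `"train"` or
#'   `"validation"`.
#' @export
splitTrainValidation <- function(meta, train_fraction = 0.7, seed = 1L) {
    meta <- as.data.frame(meta)
    qbin <- function(x) {
        if (is.null(x) || length(unique(x)) < 4L) return(factor(rep(1, nrow(meta))))
        cut(x, breaks = unique(stats::quantile(x, 0:4 / 4)),
            include.lowest = TRUE)
    }
    strat <- interaction(meta$case_status, meta$race_ethnicity,
                         qbin(meta$age), qbin(meta$psa), drop = TRUE)
    split <- setNames(rep("validation", nrow(meta)), meta$sample_id)
    withSeed(seed, {
        for (s in levels(strat)) {
            idx <- which(strat == s)
            n_train <- if (length(idx) == 1L) 1L else
                round(train_fraction * length(idx))
            take <- if (length(idx) == 1L) idx else
                sample(idx, n_train)
            split[take] <- "train"
        }
    })
    split
}
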