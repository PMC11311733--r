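#' 1D annotation enrichment on protein scores
#'
#' Rank-based enrichment of annotation terms in a vector of per-protein
#' values (typically mixed-model log2 fold changes of significant
#' proteins). For each term, members are compared with non-members by a
#' two-sided Mann-Whitney test, and the enrichment score is the
#' rank-biserial statistic `s = 2U/(n1*n2) - 1` in [-1, 1]: positive when
#' member values rank above non-members. Midranks are used for ties; the
#' p-value is exact when `n1*n2 <= 400` and tie-free, otherwise the normal
#' approximation with tie correction is used. Term p-values are BH-adjusted.
#'
#' @param values named numeric vector over proteins.
#' @param annotations named list mapping term to member protein groups.
#' @param min_members minimum scored members per term (default 3).
#' @return data.frame with `term`, `n_members_scored`, `s`, `p`, `q`,
#'   ordered by p.
#' @export
enrich1D <- function(values, annotations, min_members = 3L) {
    stopifnot(!is.null(names(values)), all(is.finite(values)))
    rows <- list()
    for (term in names(annotations)) {
        members <- intersect(annotations[[term]], names(values))
        n1 <- length(members)
        n2 <- length(values) - n1
        if (n1 < min_members || n2 < 1L) next
        x <- values[members]
        yv <- values[setdiff(names(values), members)]
        if (length(unique(values)) == 1L) {
            s <- 0; p <- 1
        } else {
            r <- rank(values)
            U <- sum(r[members]) - n1 * (n1 + 1) / 2
            s <- 2 * U / (n1 * n2) - 1
            exact <- n1 * n2 <= 400 && !anyDuplicated(values)
            p <- suppressWarnings(
                stats::wilcox.test(x, yv, exact = exact,
                                   correct = TRUE)$p.value)
            if (is.na(p)) p <- 1
        }
        rows[[term]] <- data.frame(term = term, n_members_scored = n1,
                                   s = s, p = p, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(term = character(), n_members_scored = integer(),
                          s = numeric(), p = numeric(), q = numeric()))
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Enrichment of differential-abundance results
#'
#' Convenience wrapper applying [enrich1D()] to the betas of a
#' [runDifferential()] table, by default restricted to proteins significant
#' at `q < 0.05` (set `significant_only = FALSE` to score all proteins).
#'
#' @param de result of [runDifferential()].
#' @param annotations named list mapping term to protein groups.
#' @param significant_only restrict to `q < q_threshold` proteins.
#' @param q_threshold significance cutoff (default 0.05).
#' @param min_members minimum scored members per term.
#' @return see [enrich1D()].
#' @export
enrichDifferential <- function(de, annotations, significant_only = TRUE,
                               q_threshold = 0.05, min_members = 3L) {
    keep <- if (significant_only)
        !is.na(de$q) & de$q < q_threshold else !is.na(de$p)
    values <- setNames(de$beta[keep], de$protein_group[keep])
    enrich1D(values, annotations, min_members = min_members)
}
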