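#' Greedy maximum-coverage sample selection (MaxID)
#'
#' Selects the samples that jointly maximize the number of unique peptide
#' identifications for spectral-library building: at each step the sample
#' adding the most not-yet-covered peptides is chosen, with ties broken to
#' the lexicographically smallest sample id. Selection stops after `k`
#' samples, when the cumulative coverage reaches `target` of all peptides
#' identified in the matrix, or when the marginal gain hits zero.
#'
#' @param M logical sample x peptide identification matrix with sample
#'   rownames.
#' @param k number of samples to select (default all).
#' @param target optional coverage target in (0, 1] of total unique
#'   peptides; overrides `k` as a stopping rule when reached first.
#' @return data.frame of class `SelectionResult`: `step`, `sample_id`,
#'   `marginal_gain`, `cumulative_unique`.
#' @export
maxidSelect <- function(M, k = NULL, target = NULL) {
    if (is.null(dim(M)) || nrow(M) == 0L || ncol(M) == 0L)
        stop("identification matrix is empty")
    M <- M != 0
    if (is.null(rownames(M))) rownames(M) <- sprintf("S%03d", seq_len(nrow(M)))
    if (is.null(k)) k <- nrow(M)
    stopifnot(k >= 1L, k <= nrow(M))
    if (!is.null(target)) stopifnot(target > 0, target <= 1)
    total <- sum(colSums(M) > 0L)
    covered <- rep(FALSE, ncol(M))
    remaining <- rownames(M)
    ord <- order(remaining)  # lexicographic tie-break baked into which.max
    sel <- character(); gain <- integer(); cum <- integer()
    for (step in seq_len(k)) {
        gains <- vapply(remaining, function(s) sum(M[s, ] & !covered), 0L)
        gains <- gains[order(names(gains))]
        g <- max(gains)
        if (g == 0L && step > 1L) break
        pick <- names(gains)[which.max(gains)]
        covered <- covered | M[pick, ]
        sel <- c(sel, pick); gain <- c(gain, g)
        cum <- c(cum, sum(covered))
        remaining <- setdiff(remaining, pick)
        if (!is.null(target) && sum(covered) >= target * total) break
    }
    out <- data.frame(step = seq_along(sel), sample_id = sel,
                      marginal_gain = gain, cumulative_unique = cum,
                      stringsAsFactors = FALSE)
    class(out) <- c("SelectionResult", class(out))
    out
}

#' Cumulative unique identification (saturation) curve
#'
#' @param M logical sample x peptide matrix.
#' @param order character vector of sample ids; each must be a row of `M`.
#' @return data.frame `step`, `sample_id`, `cumulative_unique`.
#' @export
saturationCurve <- function(M, order) {
    M <- M != 0
    if (!all(order %in% rownames(M)))
        stop("unknown sample id(s) in order: ",
             paste(setdiff(order, rownames(M)), collapse = ", "))
    covered <- rep(FALSE, ncol(M))
    cum <- integer(length(order))
    for (i in seq_along(order)) {
        covered <- covered | M[order[i], ]
        cum[i] <- sum(covered)
    }
    data.frame(step = seq_along(order), sample_id = order,
               cumulative_unique = cum, stringsAsFactors = FALSE)
}
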