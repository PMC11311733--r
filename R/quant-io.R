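#' Read a protein-group quantification table
#'
#' Reads a long-format delimited table with columns `sample_id`, `np_id`,
#' `protein_group`, `log2_intensity` (extra columns are ignored), or a wide
#' proteins x samples matrix for a single nanoparticle channel, and returns a
#' validated [NPQuant-class] object. Explicit `NA`/empty intensities and
#' absent records are treated identically: both become `NA` entries.
#'
#' @param path path to a TSV/CSV file; the delimiter is inferred from the
#'   extension (`.csv` is comma, anything else tab) unless `sep` is given.
#' @param format `"long"` (default) or `"wide"`.
#' @param np_id nanoparticle channel name, required when `format = "wide"`.
#' @param sep optional field delimiter override.
#' @return an [NPQuant-class] object.
#' @seealso [writeQuantTable()], [longQuant()]
#' @export
readQuantTable <- function(path, format = c("long", "wide"), np_id = NULL,
                           sep = NULL) {
    format <- match.arg(format)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
    if (format == "wide") {
        if (is.null(np_id))
            stop("np_id is required for wide-format input")
        prot <- as.character(df[[1L]])
        m <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- prot
        long <- data.frame(
            sample_id = rep(colnames(m), each = nrow(m)),
            np_id = np_id,
            protein_group = rep(prot, times = ncol(m)),
            log2_intensity = as.vector(m),
            stringsAsFactors = FALSE)
        return(npQuantFromLong(long))
    }
    req <- c("sample_id", "np_id", "protein_group", "log2_intensity")
    missing_cols <- setdiff(req, colnames(df))
    if (length(missing_cols))
        stop("missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    npQuantFromLong(df[, req])
}

#' Build an NPQuant from a long record table
#'
#' @param df data.frame with columns `sample_id`, `np_id`, `protein_group`,
#'   `log2_intensity`. Duplicate (sample, NP, protein) keys are an integrity
#'   error; non-finite intensities are rejected.
#' @param meta optional per-sample metadata.
#' @return an [NPQuant-class] object.
#' @export
npQuantFromLong <- function(df, meta = NULL) {
    df <- as.data.frame(df)
    df$log2_intensity <- as.numeric(df$log2_intensity)
    obs <- df[!is.na(df$log2_intensity), , drop = FALSE]
    if (any(is.infinite(obs$log2_intensity)))
        stop("non-finite log2_intensity values are not allowed")
    key <- paste(obs$sample_id, obs$np_id, obs$protein_group, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (sample_id, np_id, protein_group) records")
    samples <- sort(unique(as.character(df$sample_id)))
    proteins <- sort(unique(as.character(df$protein_group)))
    nps <- sort(unique(as.character(df$np_id)))
    assays <- lapply(nps, function(np) {
        m <- matrix(NA_real_, length(proteins), length(samples),
                    dimnames = list(proteins, samples))
        sub <- obs[obs$np_id == np, , drop = FALSE]
        m[cbind(as.character(sub$protein_group),
                as.character(sub$sample_id))] <- sub$log2_intensity
        m
    })
    names(assays) <- nps
    NPQuant(assays, meta = meta)
}

#' Melt an NPQuant to long records
#'
#' @param q an [NPQuant-class] object.
#' @param keep_missing keep `NA` entries as explicit records (default drops
#'   them, the canonical representation).
#' @return data.frame with columns `sample_id`, `np_id`, `protein_group`,
#'   `log2_intensity`, ordered by (np, sample, protein).
#' @export
longQuant <- function(q, keep_missing = FALSE) {
    out <- do.call(rbind, lapply(npNames(q), function(np) {
        m <- assay(q, np)
        data.frame(
            sample_id = rep(colnames(m), each = nrow(m)),
            np_id = np,
            protein_group = rep(rownames(m), times = ncol(m)),
            log2_intensity = as.vector(m),
            stringsAsFactors = FALSE)
    }))
    if (!keep_missing)
        out <- out[!is.na(out$log2_intensity), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write an NPQuant as a long-format UTF-8 TSV
#'
#' @param q an [NPQuant-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(q, path) {
    df <- longQuant(q)
    ## 17 significant digits so doubles round-trip bit-exactly through text
    df$log2_intensity <- sprintf("%.17g", df$log2_intensity)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a protein-to-term annotation table
#'
#' Accepts a two-column delimited table (`protein_group`, `term`) or a GAF
#' 2.x file (tab-separated, comment lines starting with `!`), from which the
#' Cellular Component aspect (`C`) is used: the object id (column 2) is the
#' protein group and the GO id (column 5) the term.
#'
#' @param path annotation file path.
#' @param gaf force GAF parsing; by default inferred from a leading `!` line.
#' @return named list mapping term to a character vector of protein groups.
#' @export
readAnnotations <- function(path, gaf = NA) {
    first <- readLines(path, n = 1L)
    if (is.na(gaf)) gaf <- startsWith(first, "!")
    if (gaf) {
        df <- utils::read.table(path, header = FALSE, sep = "\t",
                                comment.char = "!", quote = "",
                                stringsAsFactors = FALSE, fill = TRUE)
        df <- df[df[[9L]] == "C", , drop = FALSE]
        ann <- split(as.character(df[[2L]]), as.character(df[[5L]]))
    } else {
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
        ann <- split(as.character(df[[1L]]), as.character(df[[2L]]))
    }
    lapply(ann, unique)
}
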