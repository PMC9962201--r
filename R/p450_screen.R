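## Motif-based P450 candidate screen and fragment filter.
##
## A protein is a full-length P450 when it carries the K-helix EXXR tetrad,
## the heme-ligating CXG tripeptide in the C-terminal region (default last
## 40%, after the EXXR by default), and is at least 350 aa long. Candidates
## failing any condition but showing at least one motif (or pre-flagged as
## candidates) are fragments; proteins with no motif at all are not P450s.

#' Screening parameters
#'
#' @param min_length minimum full-length size in aa; shorter candidates are
#'   fragments (default 350, applied as `length < min_length` -> fragment).
#' @param exxr_pattern,cxg_pattern regular expressions for the two signature
#'   motifs (defaults `E..R` and `C.G`).
#' @param cxg_search_region fraction of the sequence, anchored at the C
#'   terminus, in which CXG is searched (default 0.4).
#' @param require_order if `TRUE` (default) some EXXR hit must precede some
#'   CXG hit, reflecting the K-helix -> heme-loop order of the P450 fold.
#' @return a list of class `screen_params`.
#' @export
screen_params <- function(min_length = 350L, exxr_pattern = "E..R",
                          cxg_pattern = "C.G", cxg_search_region = 0.4,
                          require_order = TRUE) {
    if (min_length <= 0)
        .stop2("arcp450_value_error", "min_length must be > 0")
    if (cxg_search_region <= 0 || cxg_search_region > 1)
        .stop2("arcp450_value_error", "cxg_search_region must be in (0, 1]")
    structure(list(min_length = as.integer(min_length),
                   exxr_pattern = exxr_pattern, cxg_pattern = cxg_pattern,
                   cxg_search_region = cxg_search_region,
                   require_order = require_order), class = "screen_params")
}

# all (overlapping) match start positions of a fixed-width pattern; 0-based
.motif_starts <- function(sequence, pattern) {
    m <- gregexpr(sprintf("(?=%s)", pattern), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for the P450 signature motifs
#'
#' Reports every EXXR occurrence anywhere in the sequence and every CXG
#' occurrence whose start lies in the configured C-terminal region.
#' Overlapping occurrences are all reported.
#'
#' @param sequence amino-acid string.
#' @param params a [screen_params()] object.
#' @return data.frame with columns motif_name, start (0-based), matched,
#'   sorted by start.
#' @export
scan_p450_motifs <- function(sequence, params = screen_params()) {
    if (!nzchar(sequence))
        .stop2("arcp450_value_error", "empty sequence")
    L <- nchar(sequence)
    exxr <- .motif_starts(sequence, params$exxr_pattern)
    cxg <- .motif_starts(sequence, params$cxg_pattern)
    # C-terminal region: 0-based start position >= L * (1 - region)
    cxg <- cxg[cxg >= L * (1 - params$cxg_search_region)]
    hits <- rbind(
        if (length(exxr)) data.frame(motif_name = "EXXR", start = exxr,
                                     matched = substring(sequence, exxr + 1L, exxr + 4L),
                                     stringsAsFactors = FALSE),
        if (length(cxg)) data.frame(motif_name = "CXG", start = cxg,
                                    matched = substring(sequence, cxg + 1L, cxg + 3L),
                                    stringsAsFactors = FALSE))
    if (is.null(hits))
        return(data.frame(motif_name = character(0), start = integer(0),
                          matched = character(0), stringsAsFactors = FALSE))
    hits[order(hits$start, hits$motif_name), , drop = FALSE]
}

#' Classify one protein as full-length P450, fragment, or not a P450
#'
#' @param record one-row protein record data.frame, or a list with elements
#'   `id` and `sequence`.
#' @param params a [screen_params()] object.
#' @param candidate set to `TRUE` for proteins pre-selected as P450
#'   candidates (e.g. by an external domain search); motif-free candidates
#'   are then called fragments rather than not_p450.
#' @return list of class `p450_call`: protein_id, status (`full_length`,
#'   `fragment`, `not_p450`), motif_hits, length, reasons.
#' @export
classify_p450 <- function(record, params = screen_params(), candidate = FALSE) {
    sequence <- record$sequence[1]; id <- record$id[1]
    hits <- scan_p450_motifs(sequence, params)
    L <- nchar(sequence)
    has_exxr <- any(hits$motif_name == "EXXR")
    has_cxg <- any(hits$motif_name == "CXG")
    reasons <- character(0)
    if (!has_exxr) reasons <- c(reasons, "missing EXXR")
    if (!has_cxg) reasons <- c(reasons, "missing CXG")
    order_ok <- TRUE
    if (params$require_order && has_exxr && has_cxg) {
        order_ok <- min(hits$start[hits$motif_name == "EXXR"]) <
            max(hits$start[hits$motif_name == "CXG"])
        if (!order_ok) reasons <- c(reasons, "EXXR not before CXG")
    }
    if (L < params$min_length)
        reasons <- c(reasons, sprintf("length<%d", params$min_length))
    status <- if (length(reasons) == 0L) "full_length"
        else if (has_exxr || has_cxg || isTRUE(candidate)) "fragment"
        else "not_p450"
    structure(list(protein_id = id, status = status, motif_hits = hits,
                   length = L, reasons = reasons), class = "p450_call")
}

#' Screen a whole proteome for P450s
#'
#' @param records protein record data.frame.
#' @param params a [screen_params()] object.
#' @param candidates optional character vector of protein ids pre-selected
#'   as P450 candidates (see [classify_p450()]).
#' @return list of class `p450_screen` with elements `calls` (data.frame:
#'   protein_id, status, length, n_exxr, n_cxg, reasons) and `summary`
#'   (named counts full_length/fragment/not_p450, summing to the input size).
#' @export
screen_proteome <- function(records, params = screen_params(), candidates = NULL) {
    if (nrow(records) == 0L)
        .stop2("arcp450_value_error", "no records to screen")
    calls <- lapply(seq_len(nrow(records)), function(i) {
        classify_p450(records[i, ], params,
                      candidate = records$id[i] %in% candidates)
    })
    df <- data.frame(
        protein_id = vapply(calls, `[[`, "", "protein_id"),
        status = vapply(calls, `[[`, "", "status"),
        length = vapply(calls, `[[`, 0L, "length"),
        n_exxr = vapply(calls, function(x) sum(x$motif_hits$motif_name == "EXXR"), 0L),
        n_cxg = vapply(calls, function(x) sum(x$motif_hits$motif_name == "CXG"), 0L),
        reasons = vapply(calls, function(x) paste(x$reasons, collapse = "; "), ""),
        stringsAsFactors = FALSE)
    summary <- c(full_length = sum(df$status == "full_length"),
                 fragment = sum(df$status == "fragment"),
                 not_p450 = sum(df$status == "not_p450"))
    structure(list(calls = df, summary = summary), class = "p450_screen")
}

#' @export
print.p450_screen <- function(x, ...) {
    cat(sprintf("P450 screen of %d proteins: %d full-length, %d fragment(s), %d not P450\n",
                sum(x$summary), x$summary["full_length"], x$summary["fragment"],
                x$summary["not_p450"]))
    invisible(x)
}
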