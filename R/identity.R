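## Pairwise global alignment and percent identity -- the quantitative core of
## CYP family/subfamily assignment. The alignment model is fixed by
## align_params(): affine gaps (open 10, extend 0.5), BLOSUM62, terminal gaps
## free, identity denominator = scored columns (terminal overhangs excluded).
## These are the EMBOSS-needle-style conventions common in P450 nomenclature
## work; every choice is a parameter so alternatives can be reproduced.

#' Alignment parameters
#'
#' @param substitution_table name of a Biostrings substitution matrix
#'   (default "BLOSUM62") or a numeric matrix with amino-acid dimnames.
#' @param gap_open,gap_extend non-negative affine gap penalties; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param terminal_gaps_free if `TRUE` (default) terminal gap runs are free
#'   (ends-free alignment).
#' @param identity_denominator what to divide identical columns by:
#'   `"scored_columns"` (alignment columns excluding terminal-gap overhangs,
#'   the default), `"shorter_seq"`, or `"alignment_length"`.
#' @return a list of class `align_params`.
#' @export
align_params <- function(substitution_table = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, terminal_gaps_free = TRUE,
                         identity_denominator = c("scored_columns",
                                                  "shorter_seq",
                                                  "alignment_length")) {
    if (gap_open < 0 || gap_extend < 0)
        .stop2("arcp450_value_error", "gap penalties must be >= 0")
    identity_denominator <- match.arg(identity_denominator)
    submat <- if (is.matrix(substitution_table)) substitution_table else
        .get_submat(substitution_table)
    structure(list(substitution_table = substitution_table, submat = submat,
                   gap_open = gap_open, gap_extend = gap_extend,
                   terminal_gaps_free = terminal_gaps_free,
                   identity_denominator = identity_denominator),
              class = "align_params")
}

.submat_cache <- new.env(parent = emptyenv())
.get_submat <- function(name) {
    if (!is.null(.submat_cache[[name]])) return(.submat_cache[[name]])
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    .submat_cache[[name]] <- m
    m
}

# map a residue string to 0-based indices into the substitution matrix
.encode_seq <- function(x, submat) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    idx <- match(chars, rownames(submat))
    if (anyNA(idx))
        .stop2("arcp450_value_error", "letter(s) not in substitution matrix: %s",
               paste(unique(chars[is.na(idx)]), collapse = ", "))
    idx - 1L
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch/Gotoh alignment under affine gap scoring, optionally with
#' free terminal gaps. Tie-breaking is deterministic: residue columns are
#' preferred over gaps, and gaps in `a` over gaps in `b`.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param params an [align_params()] object.
#' @return list of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `n_identical` and
#'   `n_columns_scored` (columns excluding terminal-gap overhangs).
#' @export
global_align <- function(a, b, params = align_params()) {
    if (!nzchar(a) || !nzchar(b))
        .stop2("arcp450_value_error", "sequences must be non-empty")
    submat <- params$submat
    res <- .nw_align(.encode_seq(a, submat), .encode_seq(b, submat), submat,
                     params$gap_open, params$gap_extend,
                     params$terminal_gaps_free)
    letters_tab <- rownames(submat)
    decode <- function(v) paste(ifelse(is.na(v), "-", letters_tab[v + 1L]),
                                collapse = "")
    aligned_a <- decode(res$a); aligned_b <- decode(res$b)
    sc <- .scored_span(aligned_a, aligned_b)
    structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                   score = res$score, n_identical = sc$n_identical,
                   n_columns_scored = sc$n_scored),
              class = "pairwise_alignment")
}

# identical columns and the scored span (columns between the first and last
# column where both sequences have a residue)
.scored_span <- function(aligned_a, aligned_b) {
    ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
    res_both <- which(ca != "-" & cb != "-")
    if (length(res_both) == 0L)
        return(list(n_identical = 0L, n_scored = 0L))
    span <- seq.int(min(res_both), max(res_both))
    list(n_identical = sum(ca[span] == cb[span] & ca[span] != "-"),
         n_scored = length(span))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
    cat(sprintf("pairwise alignment: score %.1f, %d/%d identical in scored span\n",
                x$score, x$n_identical, x$n_columns_scored))
    cat(substr(x$aligned_a, 1, 60), "\n", substr(x$aligned_b, 1, 60), "\n", sep = "")
    invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * n_identical / denominator`, reported to 0.1 precision. The default
#' denominator is the number of scored columns (terminal-gap overhangs
#' excluded); alternatives are the shorter sequence length and the full
#' alignment length.
#'
#' @param alignment a [global_align()] result.
#' @param params an [align_params()] object (only the denominator is used).
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment, params = align_params()) {
    den <- switch(params$identity_denominator,
        scored_columns = alignment$n_columns_scored,
        shorter_seq = min(nchar(gsub("-", "", alignment$aligned_a, fixed = TRUE)),
                          nchar(gsub("-", "", alignment$aligned_b, fixed = TRUE))),
        alignment_length = nchar(alignment$aligned_a))
    if (den == 0L)
        .stop2("arcp450_value_error", "zero identity denominator (no scored columns)")
    round(100 * alignment$n_identical / den, 1)
}

#' Pairwise identity of two sequences
#'
#' Convenience wrapper: align then compute percent identity.
#' @inheritParams global_align
#' @export
pair_identity <- function(a, b, params = align_params()) {
    percent_identity(global_align(a, b, params), params)
}

#' All-against-all percent-identity matrix
#'
#' @param records protein record data.frame (or a named character vector of
#'   sequences).
#' @param params an [align_params()] object.
#' @return symmetric numeric matrix in `[0, 100]` with a diagonal of 100 and
#'   ids as dimnames.
#' @export
identity_matrix <- function(records, params = align_params()) {
    if (is.data.frame(records)) {
        ids <- records$id; seqs <- records$sequence
    } else {
        ids <- names(records); seqs <- unname(records)
    }
    if (length(ids) < 2L)
        .stop2("arcp450_value_error", "need at least 2 records")
    if (anyDuplicated(ids))
        .stop2("arcp450_duplication_error", "duplicate id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    n <- length(ids)
    m <- matrix(100, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            v <- pair_identity(seqs[i], seqs[j], params)
            m[i, j] <- v; m[j, i] <- v
        }
    }
    m
}
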