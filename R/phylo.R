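## Distance-based phylogeny stage: percent-identity matrix -> distance
## matrix -> neighbor-joining tree. A transparent, testable stand-in for
## multiple-alignment + model-based inference; the resulting topologies are
## illustrative, and NJ is exact on additive distance matrices.

#' Convert a percent-identity matrix to a distance matrix
#'
#' `d = 1 - identity / 100`, with a zero diagonal.
#'
#' @param imat symmetric matrix of percent identities in `[0, 100]` (see
#'   [identity_matrix()]).
#' @return symmetric non-negative distance matrix.
#' @export
identity_to_distance <- function(imat) {
    if (any(imat < 0 | imat > 100))
        .stop2("arcp450_value_error", "identities must lie in [0, 100]")
    d <- 1 - imat / 100
    diag(d) <- 0
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ agglomeration; negative branch-length estimates are clamped
#' to zero with a warning.
#'
#' @param d symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
    if (!is.matrix(d) || nrow(d) < 3L)
        .stop2("arcp450_value_error", "neighbor joining needs at least 3 taxa")
    if (is.null(rownames(d)))
        .stop2("arcp450_value_error", "distance matrix must carry taxon ids")
    tree <- ape::nj(d)
    if (any(tree$edge.length < 0)) {
        warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                        sum(tree$edge.length < 0)), call. = FALSE)
        tree$edge.length[tree$edge.length < 0] <- 0
    }
    tree
}
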