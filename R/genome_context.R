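## Operon prediction and replicon-aware comparative statistics.
##
## Operons are predicted with a desk-reproducible heuristic: maximal runs of
## same-strand genes on one replicon whose intergenic gaps do not exceed a
## threshold (default 150 bp). This stands in for transcription-unit
## predictors and is adequate for the qualitative question the pipeline
## asks: do P450 operons carry redox partners?

#' Predict operons from gene coordinates
#'
#' @param features gene feature data.frame (see [gene_features()]).
#' @param max_gap_bp maximal intergenic gap (bp) within an operon;
#'   `gap = start(next) - end(prev) - 1` on 1-based inclusive coordinates.
#'   Overlapping same-strand genes are treated as gap 0 with a warning.
#' @return data.frame of class `operon_table`: operon_id, replicon_id,
#'   strand, n_genes, gene_ids (";"-joined, ordered by start). Every gene
#'   belongs to exactly one operon; singletons allowed.
#' @export
predict_operons <- function(features, max_gap_bp = 150L) {
    if (max_gap_bp < 0) .stop2("arcp450_value_error", "max_gap_bp must be >= 0")
    feats <- features[order(features$replicon_id, features$start), ]
    n <- nrow(feats)
    if (n == 0L)
        return(structure(data.frame(operon_id = character(0),
                                    replicon_id = character(0),
                                    strand = character(0), n_genes = integer(0),
                                    gene_ids = character(0),
                                    stringsAsFactors = FALSE),
                         class = c("operon_table", "data.frame")))
    new_block <- logical(n); new_block[1] <- TRUE
    overlaps <- 0L
    for (i in seq_len(n)[-1]) {
        same_rep <- feats$replicon_id[i] == feats$replicon_id[i - 1]
        same_strand <- feats$strand[i] == feats$strand[i - 1]
        gap <- feats$start[i] - feats$end[i - 1] - 1L
        if (same_rep && same_strand && gap < 0L) { overlaps <- overlaps + 1L; gap <- 0L }
        new_block[i] <- !(same_rep && same_strand && gap <= max_gap_bp)
    }
    if (overlaps > 0L)
        warning(sprintf("%d overlapping same-strand gene pair(s) treated as gap 0",
                        overlaps), call. = FALSE)
    block <- cumsum(new_block)
    sp <- split(seq_len(n), block)
    out <- data.frame(
        operon_id = sprintf("operon_%04d", seq_along(sp)),
        replicon_id = vapply(sp, function(ix) feats$replicon_id[ix[1]], ""),
        strand = vapply(sp, function(ix) feats$strand[ix[1]], ""),
        n_genes = vapply(sp, length, 0L),
        gene_ids = vapply(sp, function(ix) paste(feats$gene_id[ix], collapse = ";"), ""),
        stringsAsFactors = FALSE, row.names = NULL)
    structure(out, class = c("operon_table", "data.frame"))
}

#' Gene-to-operon membership
#' @param operons a [predict_operons()] result.
#' @return data.frame gene_id, operon_id.
#' @export
operon_membership <- function(operons) {
    genes <- strsplit(operons$gene_ids, ";", fixed = TRUE)
    data.frame(gene_id = unlist(genes),
               operon_id = rep(operons$operon_id, lengths(genes)),
               stringsAsFactors = FALSE)
}

#' Operon context of P450 genes
#'
#' One row per operon containing at least one full-length P450: which genes
#' it carries (with orientation) and whether a ferredoxin or an OFOR subunit
#' is co-transcribed.
#'
#' @param operons a [predict_operons()] result.
#' @param features gene feature data.frame linking genes to proteins.
#' @param p450_ids protein ids called full-length P450 (e.g. from
#'   [screen_proteome()]).
#' @param fdx_calls optional [classify_ferredoxins()] result; proteins with
#'   `fdx_type != "unclassified"` count as ferredoxins.
#' @param ofor_calls optional [find_ofor()] result.
#' @return data.frame: operon_id, replicon_id, strand, n_genes, genes
#'   (gene ids with orientation arrows), p450_protein_ids, has_ferredoxin,
#'   has_ofor.
#' @export
p450_operon_context <- function(operons, features, p450_ids,
                                fdx_calls = NULL, ofor_calls = NULL) {
    missing <- setdiff(p450_ids, features$protein_id)
    if (length(missing))
        .stop2("arcp450_linkage_error", "P450 call(s) with no gene feature: %s",
               paste(missing, collapse = ", "))
    memb <- operon_membership(operons)
    feat_by_gene <- features[match(memb$gene_id, features$gene_id), ]
    memb$protein_id <- feat_by_gene$protein_id
    memb$strand <- feat_by_gene$strand
    fdx_ids <- if (is.null(fdx_calls)) character(0) else
        fdx_calls$protein_id[fdx_calls$fdx_type != "unclassified"]
    ofor_ids <- if (is.null(ofor_calls)) character(0) else ofor_calls$protein_id
    keep <- vapply(seq_len(nrow(operons)), function(k) {
        any(memb$protein_id[memb$operon_id == operons$operon_id[k]] %in% p450_ids)
    }, logical(1))
    ops <- operons[keep, , drop = FALSE]
    rows <- lapply(seq_len(nrow(ops)), function(k) {
        mm <- memb[memb$operon_id == ops$operon_id[k], ]
        data.frame(operon_id = ops$operon_id[k], replicon_id = ops$replicon_id[k],
                   strand = ops$strand[k], n_genes = ops$n_genes[k],
                   genes = paste(sprintf("%s(%s)", mm$gene_id, mm$strand),
                                 collapse = "->"),
                   p450_protein_ids = paste(intersect(mm$protein_id, p450_ids),
                                            collapse = ";"),
                   has_ferredoxin = any(mm$protein_id %in% fdx_ids),
                   has_ofor = any(mm$protein_id %in% ofor_ids),
                   stringsAsFactors = FALSE)
    })
    if (length(rows) == 0L)
        return(data.frame(operon_id = character(0), replicon_id = character(0),
                          strand = character(0), n_genes = integer(0),
                          genes = character(0), p450_protein_ids = character(0),
                          has_ferredoxin = logical(0), has_ofor = logical(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Family co-presence across species
#'
#' Entry (f, g) counts the species containing at least one member of family
#' f and at least one of family g; the diagonal counts species containing f.
#' A species contributes once per family pair regardless of member counts.
#'
#' @param assignments a [assign_families()] result (or any data.frame with
#'   protein_id and family).
#' @param species_map named character vector protein_id -> species.
#' @return symmetric integer matrix with family labels as dimnames.
#' @export
copresence_counts <- function(assignments, species_map) {
    sp <- species_map[assignments$protein_id]
    if (anyNA(sp))
        .stop2("arcp450_linkage_error", "assignment(s) with no species mapping")
    fam <- sort(unique(assignments$family))
    pres <- table(unique(data.frame(species = sp, family = factor(assignments$family, fam))))
    pres <- (pres > 0) * 1L
    m <- t(pres) %*% pres
    storage.mode(m) <- "integer"
    dimnames(m) <- list(fam, fam)
    m
}

#' Per-family plasmid versus chromosome membership
#'
#' @param assignments a [assign_families()] result.
#' @param records protein record data.frame carrying replicon_type per
#'   protein.
#' @return data.frame family, plasmid_count, chromosome_count, total, sorted
#'   by descending total.
#' @export
replicon_family_comparison <- function(assignments, records) {
    rt <- records$replicon_type[match(assignments$protein_id, records$id)]
    if (anyNA(rt) || any(rt == "unknown"))
        .stop2("arcp450_linkage_error", "protein(s) with unresolvable replicon")
    fam <- sort(unique(assignments$family))
    out <- data.frame(
        family = fam,
        plasmid_count = vapply(fam, function(f)
            sum(assignments$family == f & rt == "plasmid"), 0L),
        chromosome_count = vapply(fam, function(f)
            sum(assignments$family == f & rt == "chromosome"), 0L),
        stringsAsFactors = FALSE, row.names = NULL)
    out$total <- out$plasmid_count + out$chromosome_count
    out[order(-out$total, out$family), , drop = FALSE]
}

#' Family saturation (accumulation) curve
#'
#' Mean cumulative number of distinct families after sampling k species, over
#' random orderings of the species — the rarefaction-style curve used to ask
#' whether family discovery is saturating. Exhaustive enumeration of all
#' orderings is available for small species counts.
#'
#' @param assignments a [assign_families()] result.
#' @param species_map named character vector protein_id -> species.
#' @param n_permutations Monte-Carlo orderings (default 100); ignored when
#'   `exhaustive = TRUE`.
#' @param seed integer seed making the Monte-Carlo curve reproducible.
#' @param exhaustive enumerate all species orderings (requires <= 8 species).
#' @return data.frame of class `saturation_curve`: n_species,
#'   mean_cumulative_families; attributes n_permutations, seed.
#' @export
family_saturation <- function(assignments, species_map, n_permutations = 100L,
                              seed = 1L, exhaustive = FALSE) {
    if (!exhaustive && n_permutations < 1L)
        .stop2("arcp450_value_error", "n_permutations must be >= 1")
    sp <- species_map[assignments$protein_id]
    if (anyNA(sp))
        .stop2("arcp450_linkage_error", "assignment(s) with no species mapping")
    fam_by_species <- lapply(split(assignments$family, sp), unique)
    species <- names(fam_by_species)
    N <- length(species)
    accumulate <- function(ord) {
        seen <- character(0)
        vapply(ord, function(s) {
            seen <<- union(seen, fam_by_species[[s]])
            length(seen)
        }, 0L)
    }
    if (exhaustive) {
        if (N > 8L)
            .stop2("arcp450_value_error",
                   "exhaustive enumeration limited to 8 species (%d given)", N)
        perms <- .permutations(N)
        curves <- vapply(seq_len(nrow(perms)),
                         function(r) accumulate(species[perms[r, ]]),
                         integer(N))
        n_used <- nrow(perms)
    } else {
        curves <- .with_local_seed(seed, {
            vapply(seq_len(n_permutations),
                   function(r) accumulate(sample(species)), integer(N))
        })
        n_used <- n_permutations
    }
    curves <- matrix(curves, nrow = N)
    out <- data.frame(n_species = seq_len(N),
                      mean_cumulative_families = rowMeans(curves))
    structure(out, class = c("saturation_curve", "data.frame"),
              n_permutations = n_used, seed = if (exhaustive) NA_integer_ else seed)
}

# all permutations of 1..n as a matrix (n! rows)
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
        cbind(k, sub + (sub >= k))))
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_local_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
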