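## Synthetic-study generator: complete proteome + gene-layout + metadata
## studies with known ground truth for every pipeline stage.
##
## Design rules: all randomness flows from one integer seed; identity bands
## are achieved by rejection/adjustment on *measured* identity (the identity
## module is the oracle), not by analytic mutation-rate formulas; P450 seeds
## embed EALR and CIG at fixed relative positions so screening ground truth
## is unambiguous; non-P450 proteins are built from a reduced alphabet
## lacking R and G (and C outside planted Fe-S motifs) so that no signature
## motif can arise by chance and planted composition is recovered exactly.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
           "F","P","S","T","W","Y","V")
.AA_NO_RG <- setdiff(.AA20, c("R", "G"))
.AA_NO_CRG <- setdiff(.AA20, c("C", "R", "G"))

.random_aa <- function(n, alphabet = .AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Build a P450 seed sequence
#'
#' Random sequence with the EXXR tetrad planted as "EALR" at ~35% of the
#' length and the heme-motif "CIG" at ~88% (inside the C-terminal 40%,
#' after the EXXR), so the motif screen's ground truth is unambiguous.
#'
#' @param length sequence length in aa (default 450, a typical P450).
#' @return list with `sequence` and `protected` (1-based motif positions).
#' @export
make_p450_seed <- function(length = 450L) {
    if (length < 50L) .stop2("arcp450_value_error", "seed too short")
    s <- strsplit(.random_aa(length), "")[[1]]
    e_at <- round(0.35 * length)
    c_at <- round(0.88 * length)
    s[e_at:(e_at + 3L)] <- c("E", "A", "L", "R")
    s[c_at:(c_at + 2L)] <- c("C", "I", "G")
    list(sequence = paste(s, collapse = ""),
         protected = c(e_at:(e_at + 3L), c_at:(c_at + 2L)))
}

#' Mutate a sequence to a target identity band
#'
#' Point substitutions at unprotected positions, adjusted until the measured
#' percent identity to the seed (via [pair_identity()]) lies within the
#' band. Deterministic for a fixed RNG state.
#'
#' @param seed_sequence the starting sequence.
#' @param target_band numeric length-2, percent identity (to the seed) band.
#' @param protected 1-based positions never mutated (e.g. motif residues).
#' @param aln an [align_params()] object used for measurement.
#' @param max_iter adjustment iterations before giving up.
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(seed_sequence, target_band,
                               protected = integer(0),
                               aln = align_params(), max_iter = 80L) {
    stopifnot(length(target_band) == 2L, target_band[1] <= target_band[2])
    if (target_band[1] >= 100) return(seed_sequence)
    chars <- strsplit(seed_sequence, "")[[1]]
    L <- length(chars)
    pool <- setdiff(seq_len(L), protected)
    target <- mean(target_band)
    k <- min(length(pool), max(1L, round(L * (1 - target / 100))))
    mutated <- sample(pool, k)
    cur <- chars
    cur[mutated] <- vapply(chars[mutated], function(a)
        sample(setdiff(.AA20, a), 1L), "")
    for (it in seq_len(max_iter)) {
        ident <- pair_identity(seed_sequence, paste(cur, collapse = ""), aln)
        if (ident >= target_band[1] && ident <= target_band[2])
            return(paste(cur, collapse = ""))
        step <- max(1L, round(abs(ident - target) / 100 * L * 0.8))
        if (ident > target_band[2]) {
            avail <- setdiff(pool, mutated)
            if (length(avail) == 0L)
                .stop2("arcp450_generation_error",
                       "identity band unreachable with the given protections")
            add <- sample(avail, min(step, length(avail)))
            cur[add] <- vapply(chars[add], function(a)
                sample(setdiff(.AA20, a), 1L), "")
            mutated <- c(mutated, add)
        } else {
            back <- sample(mutated, min(step, length(mutated)))
            cur[back] <- chars[back]
            mutated <- setdiff(mutated, back)
        }
    }
    .stop2("arcp450_generation_error",
           "failed to reach identity band [%s, %s] in %d iterations",
           target_band[1], target_band[2], max_iter)
}

#' Generate one planted P450 family
#'
#' Members are substitution variants of a common seed; the pairwise
#' within-family band is enforced by measurement (members are generated at
#' `(100 + band) / 2` identity to the seed and re-drawn until every pairwise
#' identity lies at or above the band floor). The family seed itself is
#' re-drawn until its identity to every previously generated family seed is
#' below 35%.
#'
#' @param name family name used in ids and ground truth.
#' @param n_members number of members (>= 1).
#' @param band numeric length-2, target pairwise within-family identity band.
#' @param seed_length length of the family seed sequence.
#' @param other_seeds character vector of previously generated family seeds
#'   (for the between-family check).
#' @param other_members character vector of previously generated family
#'   members; every new member is verified to stay below `cross_max`
#'   identity against all of them.
#' @param cross_max maximal tolerated between-family identity (percent).
#' @param aln an [align_params()] object.
#' @param max_retries re-draws allowed for the between/within checks.
#' @return list with `records` (protein record data.frame), `seed` (list as
#'   [make_p450_seed()]), `truth` (data.frame protein_id, family).
#' @export
generate_p450_family <- function(name, n_members, band = c(62, 70),
                                 seed_length = 450L, other_seeds = character(0),
                                 other_members = character(0), cross_max = 35,
                                 aln = align_params(), max_retries = 20L) {
    if (n_members < 1L) .stop2("arcp450_value_error", "n_members must be >= 1")
    seed <- NULL
    for (r in seq_len(max_retries)) {
        cand <- make_p450_seed(seed_length)
        cross <- vapply(other_seeds, function(s)
            pair_identity(cand$sequence, s, aln), 0, USE.NAMES = FALSE)
        if (all(cross < cross_max - 5)) { seed <- cand; break }
    }
    if (is.null(seed))
        .stop2("arcp450_generation_error",
               "could not draw a family seed below %s%% cross-family identity",
               cross_max - 5)
    to_seed_band <- (100 + band) / 2
    members <- character(n_members)
    cross_ok <- function(cand) {
        length(other_members) == 0L ||
            all(vapply(other_members, function(m)
                pair_identity(cand, m, aln), 0, USE.NAMES = FALSE) < cross_max)
    }
    for (i in seq_len(n_members)) {
        ok <- FALSE
        bump <- 0
        for (r in seq_len(max_retries)) {
            cand <- mutate_to_identity(seed$sequence,
                                       pmin(to_seed_band + bump, c(99, 100)),
                                       seed$protected, aln)
            pid <- if (i == 1L) numeric(0) else
                vapply(members[seq_len(i - 1L)], function(m)
                    pair_identity(cand, m, aln), 0, USE.NAMES = FALSE)
            if (all(pid >= band[1]) && cross_ok(cand)) {
                members[i] <- cand; ok <- TRUE; break
            }
            if (length(pid) && any(pid < band[1])) bump <- bump + 2
        }
        if (!ok)
            .stop2("arcp450_generation_error",
                   "could not keep member %d of %s inside its identity constraints",
                   i, name)
    }
    ids <- sprintf("%s_m%02d", name, seq_len(n_members))
    list(records = protein_records(id = ids, sequence = members,
                                   description = "cytochrome P450 (synthetic)"),
         seed = seed,
         truth = data.frame(protein_id = ids, family = name,
                            stringsAsFactors = FALSE))
}

#' Default signatures per ferredoxin type
#'
#' Signatures conforming to [default_fdx_rules()] and chosen so that the
#' greedy scanner recovers them unambiguously.
#' @export
default_fdx_signatures <- function() {
    list(
        "4Fe-4S"       = "C-2-C-2-C-3-C",
        "3Fe-4S"       = "C-6-C-28-C",
        "2Fe-2S"       = "C-5-C-2-C-29-C",
        "7Fe-8S"       = c("C-6-C-30-C", "C-2-C-2-C-3-C"),
        "2[4Fe-4S]"    = c("C-2-C-2-C-3-C", "C-2-C-2-C-3-C"),
        "2[4Fe-4S]Alv" = c("C-2-C-2-C-3-C", "C-2-C-2-C-9-C"))
}

# does a spacing vector conform to some rule class? returns class name or NA
.signature_class <- function(spacings, rules) {
    for (nm in names(rules$classes)) {
        cl <- rules$classes[[nm]]
        if (length(spacings) == cl$n_cys - 1L &&
            all(spacings >= cl$spacing_min) && all(spacings <= cl$spacing_max))
            return(nm)
    }
    NA_character_
}

#' Generate one synthetic ferredoxin
#'
#' The motif block(s) are embedded in a cysteine-free background so the
#' scanner recovers exactly the planted signature(s).
#'
#' @param type one of the six ferredoxin types.
#' @param signatures one signature (single-motif types) or two (composite
#'   types); defaults to [default_fdx_signatures()].
#' @param id protein id.
#' @param rules the motif rule set the signatures must conform to.
#' @return one-row protein record data.frame.
#' @export
generate_ferredoxin <- function(type, signatures = NULL, id = "fdx1",
                                rules = default_fdx_rules()) {
    if (!type %in% setdiff(.FDX_TYPES, "unclassified"))
        .stop2("arcp450_value_error", "unknown ferredoxin type: %s", type)
    if (is.null(signatures)) signatures <- default_fdx_signatures()[[type]]
    n_expected <- if (type %in% c("7Fe-8S", "2[4Fe-4S]", "2[4Fe-4S]Alv")) 2L else 1L
    if (length(signatures) != n_expected)
        .stop2("arcp450_value_error", "%s requires %d signature(s)", type, n_expected)
    blocks <- lapply(signatures, function(sig) {
        sp <- parse_fdx_signature(sig)
        if (is.na(.signature_class(sp, rules)))
            .stop2("arcp450_value_error",
                   "signature %s violates the motif rules", sig)
        paste(c("C", unlist(lapply(sp, function(g)
            c(strsplit(.random_aa(g, .AA_NO_CRG), "")[[1]], "C")))), collapse = "")
    })
    body <- paste(unlist(blocks),
                  collapse = .random_aa(12L, .AA_NO_CRG))
    seqn <- paste0(.random_aa(sample(6:14, 1L), .AA_NO_CRG), body,
                   .random_aa(sample(8:20, 1L), .AA_NO_CRG))
    rec <- protein_records(id = id, sequence = seqn,
                           description = sprintf("%s ferredoxin (synthetic)", type))
    # round-trip guarantee: the scanner must recover the planted call
    call <- assign_fdx_type(scan_fes_motifs(seqn, rules), rules, id)
    if (call$fdx_type != type || call$signature != paste(signatures, collapse = "|"))
        .stop2("arcp450_generation_error",
               "planted ferredoxin not recovered (%s vs %s)", call$fdx_type, type)
    rec
}

#' Default synthetic study specification
#'
#' Three species (one with two plasmids, one with one), four P450 families
#' at distinct sizes, two fragments, ten ferredoxins across all six types,
#' two OFOR pairs and eight decoys: a small but complete archaeal-like
#' community sufficient to exercise every pipeline stage.
#'
#' @param seed integer seed driving all randomness of [generate_study()].
#' @export
default_study_spec <- function(seed = 17L) {
    list(
        seed = as.integer(seed),
        species = list(
            list(name = "Haloarchaeon sp. S1",
                 replicons = list(list(id = "S1_chr", type = "chromosome"),
                                  list(id = "S1_p1", type = "plasmid"),
                                  list(id = "S1_p2", type = "plasmid"))),
            list(name = "Methanoarchaeon sp. S2",
                 replicons = list(list(id = "S2_chr", type = "chromosome"),
                                  list(id = "S2_p1", type = "plasmid"))),
            list(name = "Thermoarchaeon sp. S3",
                 replicons = list(list(id = "S3_chr", type = "chromosome")))),
        families = list(
            list(name = "FAM1", n_members = 5L, band = c(62, 70)),
            list(name = "FAM2", n_members = 4L, band = c(62, 70)),
            list(name = "FAM3", n_members = 3L, band = c(58, 66)),
            list(name = "FAM4", n_members = 2L, band = c(62, 70))),
        n_fragments = 2L,
        ferredoxins = list(
            list(type = "2Fe-2S", n = 3L), list(type = "3Fe-4S", n = 2L),
            list(type = "4Fe-4S", n = 1L), list(type = "7Fe-8S", n = 2L),
            list(type = "2[4Fe-4S]", n = 1L), list(type = "2[4Fe-4S]Alv", n = 1L)),
        n_ofor_pairs = 2L,
        n_decoys = 8L,
        p450_fdx_operon = TRUE,
        intra_operon_gap = c(20L, 120L),
        inter_operon_gap = c(300L, 900L),
        p_operon_continue = 0.45)
}

#' Generate a complete synthetic study
#'
#' Produces proteomes, a gene layout, replicon metadata and a ground-truth
#' table, deterministically from `spec$seed`. When `out_dir` is given, one
#' FASTA per replicon plus `genes.gff3`, `replicons.tsv` and `truth.tsv`
#' are written there.
#'
#' @param spec a [default_study_spec()]-shaped specification.
#' @param out_dir optional output directory.
#' @return list with `records`, `features`, `meta`, `truth` (protein roles,
#'   families, ferredoxin types/signatures, operon block per gene) and
#'   `family_seeds`.
#' @export
generate_study <- function(spec = default_study_spec(), out_dir = NULL) {
    .with_local_seed(spec$seed, .generate_study_impl(spec, out_dir))
}

.generate_study_impl <- function(spec, out_dir) {
    recs <- list(); truth <- list(); seeds <- character(0)
    fam_seed_objs <- list()

    prev_members <- character(0)
    for (f in spec$families) {
        fam <- generate_p450_family(f$name, f$n_members, f$band,
                                    other_seeds = seeds,
                                    other_members = prev_members)
        seeds <- c(seeds, fam$seed$sequence)
        prev_members <- c(prev_members, fam$records$sequence)
        fam_seed_objs[[f$name]] <- fam$seed
        recs[[length(recs) + 1L]] <- fam$records
        truth[[length(truth) + 1L]] <- data.frame(
            protein_id = fam$truth$protein_id, role = "p450_full",
            family = fam$truth$family, fdx_type = NA_character_,
            fdx_signature = NA_character_, stringsAsFactors = FALSE)
    }

    # fragments: truncated variants of the first family's seed (EXXR kept,
    # C-terminal heme motif lost, length < 350)
    if (spec$n_fragments > 0L) {
        base <- fam_seed_objs[[1]]$sequence
        frag_ids <- sprintf("FRAG_%02d", seq_len(spec$n_fragments))
        frs <- vapply(seq_len(spec$n_fragments), function(i)
            substr(mutate_to_identity(base, c(80, 90),
                                      fam_seed_objs[[1]]$protected), 1L, 300L), "")
        recs[[length(recs) + 1L]] <- protein_records(
            id = frag_ids, sequence = frs,
            description = "cytochrome P450 fragment (synthetic)")
        truth[[length(truth) + 1L]] <- data.frame(
            protein_id = frag_ids, role = "p450_fragment", family = NA_character_,
            fdx_type = NA_character_, fdx_signature = NA_character_,
            stringsAsFactors = FALSE)
    }

    k <- 0L
    for (fs in spec$ferredoxins) {
        for (i in seq_len(fs$n)) {
            k <- k + 1L
            id <- sprintf("FDX_%02d", k)
            sig <- default_fdx_signatures()[[fs$type]]
            recs[[length(recs) + 1L]] <- generate_ferredoxin(fs$type, sig, id)
            truth[[length(truth) + 1L]] <- data.frame(
                protein_id = id, role = "ferredoxin", family = NA_character_,
                fdx_type = fs$type, fdx_signature = paste(sig, collapse = "|"),
                stringsAsFactors = FALSE)
        }
    }

    if (spec$n_ofor_pairs > 0L) {
        for (i in seq_len(spec$n_ofor_pairs)) {
            ids <- sprintf("OFOR_%d%s", i, c("A", "B"))
            recs[[length(recs) + 1L]] <- protein_records(
                id = ids,
                sequence = c(.random_aa(380L, .AA_NO_CRG), .random_aa(310L, .AA_NO_CRG)),
                description = paste("2-oxoacid:ferredoxin oxidoreductase subunit",
                                    c("alpha", "beta"), "(synthetic)"))
            truth[[length(truth) + 1L]] <- data.frame(
                protein_id = ids, role = "ofor", family = NA_character_,
                fdx_type = NA_character_, fdx_signature = NA_character_,
                stringsAsFactors = FALSE)
        }
    }

    if (spec$n_decoys > 0L) {
        ids <- sprintf("DECOY_%02d", seq_len(spec$n_decoys))
        recs[[length(recs) + 1L]] <- protein_records(
            id = ids,
            sequence = vapply(seq_along(ids), function(i)
                .random_aa(sample(250:500, 1L), .AA_NO_CRG), ""),
            description = "hypothetical protein (synthetic)")
        truth[[length(truth) + 1L]] <- data.frame(
            protein_id = ids, role = "decoy", family = NA_character_,
            fdx_type = NA_character_, fdx_signature = NA_character_,
            stringsAsFactors = FALSE)
    }

    records <- do.call(rbind, recs)
    truth <- do.call(rbind, truth)

    # replicon metadata
    meta_rows <- list()
    for (sp in spec$species)
        for (rp in sp$replicons)
            meta_rows[[length(meta_rows) + 1L]] <- data.frame(
                replicon_id = rp$id, species = sp$name, replicon_type = rp$type,
                accession = sprintf("SYN_%s", rp$id), stringsAsFactors = FALSE)
    meta <- do.call(rbind, meta_rows)

    # distribute proteins over replicons; OFOR pairs stay together, and one
    # ferredoxin can be reserved to share an operon with a P450
    ids <- records$id
    pair_anchor <- ids[grepl("^OFOR_[0-9]+A$", ids)]
    pair_partner <- sub("A$", "B", pair_anchor)
    reserved_fdx <- if (isTRUE(spec$p450_fdx_operon) && any(truth$role == "ferredoxin"))
        truth$protein_id[truth$role == "ferredoxin"][1] else character(0)
    reserved_p450 <- if (length(reserved_fdx))
        truth$protein_id[truth$role == "p450_full"][1] else character(0)
    singles <- setdiff(ids, c(pair_partner, reserved_fdx, reserved_p450))
    order_single <- sample(singles)
    units <- lapply(order_single, function(x)
        if (x %in% pair_anchor) c(x, sub("A$", "B", x)) else x)
    if (length(reserved_p450))
        units <- append(units, list(c(reserved_p450, reserved_fdx)),
                        after = sample(length(units), 1L))
    unit_rep <- sample(meta$replicon_id, length(units), replace = TRUE)

    # lay out genes along each replicon
    feat_rows <- list(); operon_truth <- list()
    for (rid in meta$replicon_id) {
        here <- which(unit_rep == rid)
        if (length(here) == 0L) next
        pos <- 1L; block <- 1L; strand <- sample(c("+", "-"), 1L)
        first <- TRUE
        for (u in here) {
            for (j in seq_along(units[[u]])) {
                pid <- units[[u]][j]
                aa_len <- nchar(records$sequence[records$id == pid])
                glen <- 3L * aa_len + 3L
                keep_together <- j > 1L  # second element of a planted unit
                if (!first) {
                    cont <- keep_together ||
                        stats::runif(1) < spec$p_operon_continue
                    if (cont) {
                        gap <- sample(spec$intra_operon_gap[1]:spec$intra_operon_gap[2], 1L)
                    } else {
                        gap <- sample(spec$inter_operon_gap[1]:spec$inter_operon_gap[2], 1L)
                        block <- block + 1L
                        strand <- sample(c("+", "-"), 1L)
                    }
                    pos <- pos + gap
                }
                feat_rows[[length(feat_rows) + 1L]] <- data.frame(
                    gene_id = paste0("g_", pid), protein_id = pid,
                    replicon_id = rid, start = pos, end = pos + glen - 1L,
                    strand = strand, stringsAsFactors = FALSE)
                operon_truth[[length(operon_truth) + 1L]] <- data.frame(
                    gene_id = paste0("g_", pid), replicon_id = rid,
                    operon_block = sprintf("%s_b%03d", rid, block),
                    stringsAsFactors = FALSE)
                pos <- pos + glen
                first <- FALSE
            }
        }
    }
    features <- do.call(rbind, feat_rows)
    features <- features[order(features$replicon_id, features$start), ]
    rownames(features) <- NULL
    operon_truth <- do.call(rbind, operon_truth)

    # annotate records with their replicon context
    hit <- match(records$id, features$protein_id)
    records$replicon_id <- features$replicon_id[hit]
    records$species <- meta$species[match(records$replicon_id, meta$replicon_id)]
    records$replicon_type <- meta$replicon_type[match(records$replicon_id,
                                                      meta$replicon_id)]
    truth$species <- records$species[match(truth$protein_id, records$id)]
    truth$replicon_id <- records$replicon_id[match(truth$protein_id, records$id)]

    study <- list(records = records, features = features, meta = meta,
                  truth = truth, operon_truth = operon_truth,
                  family_seeds = fam_seed_objs)

    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (rid in meta$replicon_id) {
            sub <- records[records$replicon_id == rid, , drop = FALSE]
            if (nrow(sub))
                write_fasta(sub, file.path(out_dir, paste0(rid, ".fasta")))
        }
        write_gff3(features, file.path(out_dir, "genes.gff3"))
        write_replicon_table(meta, file.path(out_dir, "replicons.tsv"))
        write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    study
}
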