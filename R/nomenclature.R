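## CYP family/subfamily assignment following the International P450
## Nomenclature Committee convention: queries sharing >40% identity belong to
## the same family, >55% to the same subfamily; queries below the family
## threshold against every named reference found a new family. Threshold
## comparisons are inclusive (>= 40 / >= 55): the convention's prose leaves
## exactly-at-threshold undefined, and the inclusive reading is applied
## consistently here.

#' Classifier parameters
#'
#' @param family_threshold,subfamily_threshold percent-identity thresholds
#'   for family (default 40) and subfamily (default 55) co-membership;
#'   applied inclusively.
#' @param novel_family_prefix label prefix for de-novo families (default
#'   "CYPN"); official CYP numbers are allocated by the nomenclature
#'   committee, so novel families get a neutral prefix.
#' @return list of class `classifier_params`.
#' @export
classifier_params <- function(family_threshold = 40, subfamily_threshold = 55,
                              novel_family_prefix = "CYPN") {
    if (!(family_threshold > 0 && family_threshold < subfamily_threshold &&
          subfamily_threshold < 100))
        .stop2("arcp450_value_error",
               "need 0 < family_threshold < subfamily_threshold < 100")
    structure(list(family_threshold = family_threshold,
                   subfamily_threshold = subfamily_threshold,
                   novel_family_prefix = novel_family_prefix),
              class = "classifier_params")
}

#' Parse a CYP label into family / subfamily / member
#'
#' E.g. `CYP147A1` -> family "CYP147", subfamily "A", member 1; multi-letter
#' subfamilies (CYP197AK) are supported.
#'
#' @param name character vector of CYP labels.
#' @return data.frame with columns name, family, subfamily, member.
#' @export
parse_cyp_name <- function(name) {
    m <- regmatches(name, regexec("^(CYP[0-9]+)([A-Z]+)?([0-9]+)?$", name))
    bad <- vapply(m, length, 0L) == 0L
    if (any(bad))
        .stop2("arcp450_format_error", "unparseable CYP name(s): %s",
               paste(name[bad], collapse = ", "))
    data.frame(name = name,
               family = vapply(m, `[`, "", 2L),
               subfamily = vapply(m, function(x) ifelse(nzchar(x[3]), x[3], NA_character_), ""),
               member = vapply(m, function(x) ifelse(nzchar(x[4]), as.integer(x[4]), NA_integer_), 0L),
               stringsAsFactors = FALSE)
}

#' Build a reference database of named P450s
#'
#' The CYP label is taken from the record id when it parses, otherwise from
#' the first CYP-like token of the description (reference FASTA headers
#' carry CYP names).
#'
#' @param records protein record data.frame.
#' @return list of class `reference_db` with elements `records` and `names`
#'   (data.frame ref_id, cyp_name, family, subfamily, member).
#' @export
build_reference_db <- function(records) {
    tok <- ifelse(grepl("^CYP[0-9]+[A-Z]*[0-9]*$", records$id), records$id,
                  vapply(records$description, function(d) {
                      hit <- regmatches(d, regexpr("CYP[0-9]+[A-Z]+[0-9]+", d))
                      if (length(hit)) hit else NA_character_
                  }, "", USE.NAMES = FALSE))
    if (anyNA(tok))
        .stop2("arcp450_format_error", "reference(s) without parseable CYP name: %s",
               paste(records$id[is.na(tok)], collapse = ", "))
    parsed <- parse_cyp_name(tok)
    structure(list(records = records,
                   names = data.frame(ref_id = records$id, cyp_name = tok,
                                      family = parsed$family,
                                      subfamily = parsed$subfamily,
                                      member = parsed$member,
                                      stringsAsFactors = FALSE)),
              class = "reference_db")
}

#' Place one query against the named reference set
#'
#' The best reference by percent identity determines the placement: at or
#' above the subfamily threshold both family and subfamily are inherited; in
#' the family band only the family is inherited and the subfamily is left to
#' be lettered de novo; below the family threshold the query founds a novel
#' family. `conflict` is set when references from two different families
#' both reach the family threshold (the best hit still wins).
#'
#' @param query one-row protein record data.frame.
#' @param refdb a [build_reference_db()] object.
#' @param params a [classifier_params()] object.
#' @param aln an [align_params()] object.
#' @return one-row data.frame: protein_id, family, subfamily, best_ref_id,
#'   best_identity, novel_family, novel_subfamily, conflict.
#' @export
assign_against_reference <- function(query, refdb, params = classifier_params(),
                                     aln = align_params()) {
    if (!inherits(refdb, "reference_db") || nrow(refdb$records) == 0L)
        .stop2("arcp450_configuration_error", "empty or invalid reference database")
    idents <- vapply(refdb$records$sequence, function(s)
        pair_identity(query$sequence[1], s, aln), 0, USE.NAMES = FALSE)
    best <- which.max(idents)
    best_id <- idents[best]
    fam_hits <- unique(refdb$names$family[idents >= params$family_threshold])
    conflict <- length(fam_hits) > 1L
    if (best_id >= params$subfamily_threshold) {
        fam <- refdb$names$family[best]; sub <- refdb$names$subfamily[best]
        novel_fam <- FALSE; novel_sub <- FALSE
    } else if (best_id >= params$family_threshold) {
        fam <- refdb$names$family[best]; sub <- NA_character_
        novel_fam <- FALSE; novel_sub <- TRUE
    } else {
        fam <- NA_character_; sub <- NA_character_
        novel_fam <- TRUE; novel_sub <- TRUE
    }
    data.frame(protein_id = query$id[1], family = fam, subfamily = sub,
               best_ref_id = refdb$names$ref_id[best], best_identity = best_id,
               novel_family = novel_fam, novel_subfamily = novel_sub,
               conflict = conflict, stringsAsFactors = FALSE)
}

# deterministic connected components by single linkage at a threshold:
# components ordered by their smallest member id, members sorted within
.threshold_components <- function(ids, imat, threshold) {
    n <- length(ids)
    adj <- imat[ids, ids, drop = FALSE] >= threshold
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (s in order(ids)) {
        if (!is.na(comp[s])) next
        nc <- nc + 1L
        queue <- s
        while (length(queue)) {
            v <- queue[[1]]; queue <- queue[-1]
            if (!is.na(comp[v])) next
            comp[v] <- nc
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    lapply(seq_len(nc), function(k) sort(ids[comp == k]))
}

#' Cluster unplaced P450s into de-novo families
#'
#' Single-linkage connected components of the relation
#' `identity >= family_threshold`, mirroring the pairwise nomenclature rule
#' applied transitively. Components are ordered by smallest member id.
#' Chaining risk (a component whose minimum internal identity falls below
#' the threshold) is reported with a warning.
#'
#' @param ids protein ids to cluster.
#' @param imat identity matrix covering all `ids` (see [identity_matrix()]).
#' @param params a [classifier_params()] object.
#' @return list of character vectors, one per family.
#' @export
cluster_novel_families <- function(ids, imat, params = classifier_params()) {
    if (length(ids) == 0L) return(list())
    if (length(ids) == 1L) return(list(ids))
    comps <- .threshold_components(ids, imat, params$family_threshold)
    for (cc in comps) {
        if (length(cc) > 1L) {
            sub <- imat[cc, cc]
            if (min(sub[upper.tri(sub)]) < params$family_threshold)
                warning(sprintf("family component {%s} chained: minimum internal identity %.1f < %s",
                                paste(cc, collapse = ","),
                                min(sub[upper.tri(sub)]),
                                params$family_threshold), call. = FALSE)
        }
    }
    comps
}

#' Partition one family into subfamilies
#'
#' Single-linkage components at the subfamily threshold, lettered A, B, C,
#' ... (then AA, AB, ...) in component order.
#'
#' @param members ids of the family members.
#' @param imat identity matrix covering the members.
#' @param params a [classifier_params()] object.
#' @param first_letter_index 1-based index of the first letter to use
#'   (e.g. 2 to start at "B" when subfamily A already exists).
#' @return named list letter -> character vector of member ids.
#' @export
cluster_subfamilies <- function(members, imat, params = classifier_params(),
                                first_letter_index = 1L) {
    if (length(members) == 0L) return(list())
    comps <- if (length(members) == 1L) list(members) else
        .threshold_components(members, imat, params$subfamily_threshold)
    setNames(comps, .subfamily_letters(seq_along(comps) + first_letter_index - 1L))
}

# 1 -> A, 26 -> Z, 27 -> AA (spreadsheet-style)
.subfamily_letters <- function(i) {
    vapply(i, function(k) {
        s <- ""
        while (k > 0L) {
            r <- (k - 1L) %% 26L
            s <- paste0(LETTERS[r + 1L], s)
            k <- (k - 1L) %/% 26L
        }
        s
    }, "")
}

#' Assign CYP family and subfamily labels to a set of screened P450s
#'
#' End-to-end nomenclature: each query is placed against the reference set
#' (when one is given); queries in the family band get fresh subfamily
#' letters per family (continuing after the reference letters); queries
#' below the family threshold everywhere are clustered de novo into novel
#' families and subfamilies. Member numbers are assigned within each
#' subfamily in id order.
#'
#' @param queries protein record data.frame (full-length P450s).
#' @param refdb optional [build_reference_db()] object; `NULL` classifies
#'   everything de novo.
#' @param params a [classifier_params()] object.
#' @param aln an [align_params()] object.
#' @param imat optional precomputed identity matrix over `queries` (computed
#'   when needed otherwise).
#' @return data.frame of class `family_assignments`: protein_id, family,
#'   subfamily, label, best_ref_id, best_identity, novel_family, conflict.
#' @export
assign_families <- function(queries, refdb = NULL, params = classifier_params(),
                            aln = align_params(), imat = NULL) {
    if (nrow(queries) == 0L)
        .stop2("arcp450_value_error", "no queries to classify")
    if (is.null(refdb)) {
        ref_rows <- data.frame(protein_id = queries$id, family = NA_character_,
                               subfamily = NA_character_,
                               best_ref_id = NA_character_,
                               best_identity = NA_real_, novel_family = TRUE,
                               novel_subfamily = TRUE, conflict = FALSE,
                               stringsAsFactors = FALSE)
    } else {
        ref_rows <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i)
            assign_against_reference(queries[i, ], refdb, params, aln)))
    }

    need_mat <- any(ref_rows$novel_family) || any(ref_rows$novel_subfamily)
    if (need_mat && is.null(imat) && nrow(queries) >= 2L)
        imat <- identity_matrix(queries, aln)

    # de-novo families among the unplaced queries
    novel_ids <- ref_rows$protein_id[ref_rows$novel_family]
    if (length(novel_ids)) {
        fams <- cluster_novel_families(novel_ids, .as_imat(imat, novel_ids), params)
        existing <- if (is.null(refdb)) character(0) else unique(refdb$names$family)
        for (k in seq_along(fams)) {
            lab <- paste0(params$novel_family_prefix, k)
            if (lab %in% existing)
                .stop2("arcp450_naming_error",
                       "novel family label %s collides with the reference database", lab)
            ref_rows$family[match(fams[[k]], ref_rows$protein_id)] <- lab
        }
    }

    # subfamily lettering, family by family
    for (fam in unique(ref_rows$family)) {
        rows <- which(ref_rows$family == fam & ref_rows$novel_subfamily)
        if (length(rows) == 0L) next
        members <- ref_rows$protein_id[rows]
        used <- character(0)
        if (!is.null(refdb))
            used <- refdb$names$subfamily[refdb$names$family == fam]
        used <- c(used, ref_rows$subfamily[ref_rows$family == fam])
        used <- unique(used[!is.na(used)])
        first_idx <- .next_letter_index(used)
        subs <- cluster_subfamilies(members, .as_imat(imat, members), params,
                                    first_letter_index = first_idx)
        for (lt in names(subs))
            ref_rows$subfamily[match(subs[[lt]], ref_rows$protein_id)] <- lt
    }

    out <- name_assignments(ref_rows, params,
                            refdb_names = if (is.null(refdb)) NULL else refdb$names)
    class(out) <- c("family_assignments", class(out))
    out
}

.as_imat <- function(imat, ids) {
    if (length(ids) == 1L)
        return(matrix(100, 1, 1, dimnames = list(ids, ids)))
    if (is.null(imat))
        .stop2("arcp450_value_error", "identity matrix required")
    imat
}

# next free subfamily letter index given letters already in use
.next_letter_index <- function(used) {
    if (length(used) == 0L) return(1L)
    idx <- vapply(used, function(s) {
        k <- 0L
        for (ch in strsplit(s, "")[[1]]) k <- k * 26L + match(ch, LETTERS)
        k
    }, 0L)
    max(idx) + 1L
}

#' Finalize CYP labels (member numbering)
#'
#' Members are numbered 1..n within each (family, subfamily) in id order;
#' when the subfamily continues a reference subfamily, numbering continues
#' after the largest reference member number.
#'
#' @param assignments assignment data.frame (see [assign_families()]).
#' @param params a [classifier_params()] object.
#' @param refdb_names optional `names` table of a reference db, used to
#'   continue member numbering and to detect label collisions.
#' @return the assignments with a `label` column of unique CYP labels.
#' @export
name_assignments <- function(assignments, params = classifier_params(),
                             refdb_names = NULL) {
    assignments$label <- NA_character_
    key <- paste(assignments$family, assignments$subfamily)
    for (k in unique(key)) {
        rows <- which(key == k)
        rows <- rows[order(assignments$protein_id[rows])]
        start <- 0L
        if (!is.null(refdb_names)) {
            hit <- refdb_names$family == assignments$family[rows[1]] &
                !is.na(refdb_names$subfamily) &
                refdb_names$subfamily == assignments$subfamily[rows[1]]
            if (any(hit) && any(!is.na(refdb_names$member[hit])))
                start <- max(refdb_names$member[hit], na.rm = TRUE)
        }
        assignments$label[rows] <- paste0(assignments$family[rows[1]],
                                          assignments$subfamily[rows[1]],
                                          start + seq_along(rows))
    }
    if (anyDuplicated(assignments$label))
        .stop2("arcp450_naming_error", "duplicate finalized label(s)")
    assignments
}

#' Family membership counts
#'
#' @param assignments a [assign_families()] result.
#' @return data.frame family, n_members, n_subfamilies, sorted by descending
#'   member count (ties broken by family label).
#' @export
count_families <- function(assignments) {
    sp <- split(assignments, assignments$family)
    out <- data.frame(family = names(sp),
                      n_members = vapply(sp, nrow, 0L),
                      n_subfamilies = vapply(sp, function(d)
                          length(unique(d$subfamily)), 0L),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$n_members, out$family), , drop = FALSE]
}
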