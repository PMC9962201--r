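## Ferredoxin Fe-S cluster typing from cysteine-spacing grammars, subtype
## bookkeeping, and OFOR (2-oxoacid:ferredoxin oxidoreductase) subunit
## detection.
##
## A motif is an ordered run of cluster-ligating cysteines; its signature
## serialises the residue gaps between consecutive cysteines, e.g.
## "C-2-C-2-C-4-C" for CxxCxxCxxxxC. The rule set is declarative (cysteine
## count + per-gap spacing ranges per cluster class) so alternative grammars
## can be supplied; the shipped defaults encode the canonical bacterial-type
## 4Fe-4S / 3Fe-4S and plant/adrenodoxin-type 2Fe-2S motifs.

.FDX_TYPES <- c("2Fe-2S", "3Fe-4S", "4Fe-4S", "7Fe-8S", "2[4Fe-4S]",
                "2[4Fe-4S]Alv", "unclassified")

#' Default ferredoxin motif rules
#'
#' Per cluster class: the number of motif cysteines and the allowed range of
#' each inter-cysteine spacing. Classes are tried in the order given
#' (4-cysteine classes first, so a 3Fe-4S rule can never shadow a longer
#' motif). `alv_min_last_spacing` separates Alvin-type `2[4Fe-4S]` ferredoxins
#' (a long insertion before the last cysteine of the second cluster) from
#' the clostridial form.
#'
#' @return list of class `fdx_rules`.
#' @export
default_fdx_rules <- function() {
    structure(list(
        classes = list(
            cluster_4Fe4S = list(n_cys = 4L, spacing_min = c(2L, 2L, 3L),
                                 spacing_max = c(2L, 2L, 40L)),
            cluster_2Fe2S = list(n_cys = 4L, spacing_min = c(4L, 2L, 20L),
                                 spacing_max = c(6L, 2L, 40L)),
            cluster_3Fe4S = list(n_cys = 3L, spacing_min = c(2L, 3L),
                                 spacing_max = c(8L, 40L))),
        alv_min_last_spacing = 8L), class = "fdx_rules")
}

.validate_fdx_rules <- function(rules) {
    if (!is.list(rules) || is.null(rules$classes) || length(rules$classes) == 0L)
        .stop2("arcp450_configuration_error", "malformed ferredoxin rules")
    for (nm in names(rules$classes)) {
        cl <- rules$classes[[nm]]
        ok <- is.numeric(cl$n_cys) && cl$n_cys >= 2 &&
            length(cl$spacing_min) == cl$n_cys - 1 &&
            length(cl$spacing_max) == cl$n_cys - 1 &&
            all(cl$spacing_min >= 1) && all(cl$spacing_min <= cl$spacing_max)
        if (!ok)
            .stop2("arcp450_configuration_error",
                   "malformed ferredoxin rule class '%s'", nm)
    }
    invisible(rules)
}

#' Serialize / parse a cysteine-spacing signature
#'
#' @param spacings integer vector of residue gaps between consecutive motif
#'   cysteines.
#' @return `fdx_signature()`: the canonical string "C-g1-C-...-C";
#'   `parse_fdx_signature()`: the integer spacings.
#' @export
fdx_signature <- function(spacings) {
    paste0("C-", paste(as.integer(spacings), collapse = "-C-"), "-C")
}

#' @rdname fdx_signature
#' @param signature a signature string produced by [fdx_signature()].
#' @export
parse_fdx_signature <- function(signature) {
    if (!grepl("^C(-[0-9]+-C)+$", signature))
        .stop2("arcp450_format_error", "malformed signature: %s", signature)
    parts <- strsplit(signature, "-", fixed = TRUE)[[1]]
    as.integer(parts[parts != "C"])
}

#' Scan a protein for Fe-S cluster-binding motifs
#'
#' Greedy left-to-right matching: at each unconsumed cysteine the classes
#' are tried in rule order; for a flexible spacing range the nearest
#' conforming cysteine is taken. Accepted motifs do not overlap; scanning
#' resumes after the last cysteine of an accepted motif.
#'
#' @param sequence amino-acid string.
#' @param rules a [default_fdx_rules()]-shaped rule set.
#' @return data.frame with one row per motif: cluster_class, signature,
#'   first_cys (0-based), and list-columns cys_positions (0-based) and
#'   spacings.
#' @export
scan_fes_motifs <- function(sequence, rules = default_fdx_rules()) {
    if (!nzchar(sequence)) .stop2("arcp450_value_error", "empty sequence")
    .validate_fdx_rules(rules)
    cys <- as.integer(gregexpr("C", sequence, fixed = TRUE)[[1]])
    cys <- cys[cys > 0L] - 1L  # 0-based
    out <- list()
    i <- 1L
    while (i <= length(cys)) {
        matched <- NULL
        for (cl_name in names(rules$classes)) {
            cl <- rules$classes[[cl_name]]
            pos <- .match_motif_at(cys, i, cl)
            if (!is.null(pos)) {
                matched <- list(class = cl_name, pos = pos)
                break
            }
        }
        if (is.null(matched)) {
            i <- i + 1L
        } else {
            sp <- diff(cys[matched$pos]) - 1L
            out[[length(out) + 1L]] <- list(
                cluster_class = matched$class,
                cys_positions = cys[matched$pos],
                spacings = sp, signature = fdx_signature(sp))
            i <- matched$pos[length(matched$pos)] + 1L
        }
    }
    if (length(out) == 0L)
        return(data.frame(cluster_class = character(0), signature = character(0),
                          first_cys = integer(0), stringsAsFactors = FALSE))
    df <- data.frame(cluster_class = vapply(out, `[[`, "", "cluster_class"),
                     signature = vapply(out, `[[`, "", "signature"),
                     first_cys = vapply(out, function(x) x$cys_positions[1], 0L),
                     stringsAsFactors = FALSE)
    df$cys_positions <- lapply(out, `[[`, "cys_positions")
    df$spacings <- lapply(out, `[[`, "spacings")
    df
}

# try to realise one motif class anchored at cys index i; returns the chosen
# cysteine indices (into cys) or NULL
.match_motif_at <- function(cys, i, cl) {
    pos <- i
    for (k in seq_len(cl$n_cys - 1L)) {
        cur <- cys[pos[length(pos)]]
        lo <- cur + cl$spacing_min[k] + 1L
        hi <- cur + cl$spacing_max[k] + 1L
        cand <- which(cys >= lo & cys <= hi)
        cand <- cand[cand > pos[length(pos)]]
        if (length(cand) == 0L) return(NULL)
        pos <- c(pos, cand[1])  # nearest conforming cysteine
    }
    pos
}

#' Assign the ferredoxin Fe-S type from scanned motifs
#'
#' Composite types are resolved first: two 4Fe-4S motifs make a `2[4Fe-4S]`
#' (Alvin-type when the second motif's final spacing reaches
#' `alv_min_last_spacing`); one 3Fe-4S plus one 4Fe-4S motif (either order)
#' makes a 7Fe-8S. A single motif gives its cluster type; no motif gives
#' `unclassified`.
#'
#' @param motifs a [scan_fes_motifs()] result.
#' @param rules the rule set used for scanning.
#' @param protein_id id carried through to the call.
#' @return list of class `fdx_call`: protein_id, fdx_type, motifs,
#'   signature (composite signatures joined by "|"), subtype_id (NA until
#'   [assign_subtype()]).
#' @export
assign_fdx_type <- function(motifs, rules = default_fdx_rules(),
                            protein_id = NA_character_) {
    n4 <- sum(motifs$cluster_class == "cluster_4Fe4S")
    n3 <- sum(motifs$cluster_class == "cluster_3Fe4S")
    n2 <- sum(motifs$cluster_class == "cluster_2Fe2S")
    type <- "unclassified"; used <- motifs[0, ]
    if (n4 >= 2L) {
        used <- motifs[motifs$cluster_class == "cluster_4Fe4S", ][1:2, ]
        last_sp <- used$spacings[[2]][length(used$spacings[[2]])]
        type <- if (last_sp >= rules$alv_min_last_spacing) "2[4Fe-4S]Alv" else "2[4Fe-4S]"
    } else if (n4 >= 1L && n3 >= 1L) {
        used <- rbind(motifs[motifs$cluster_class == "cluster_3Fe4S", ][1, ],
                      motifs[motifs$cluster_class == "cluster_4Fe4S", ][1, ])
        used <- used[order(used$first_cys), ]
        type <- "7Fe-8S"
    } else if (nrow(motifs) == 1L) {
        type <- switch(motifs$cluster_class[1],
                       cluster_4Fe4S = "4Fe-4S", cluster_3Fe4S = "3Fe-4S",
                       cluster_2Fe2S = "2Fe-2S", "unclassified")
        used <- motifs
    } else if (nrow(motifs) > 1L) {
        # motif combination outside the recognised repertoire
        type <- "unclassified"
    }
    structure(list(protein_id = protein_id, fdx_type = type, motifs = used,
                   signature = if (nrow(used)) paste(used$signature, collapse = "|")
                               else NA_character_,
                   subtype_id = NA_integer_), class = "fdx_call")
}

#' Classify one or many proteins as ferredoxins
#'
#' @param records protein record data.frame.
#' @param rules a [default_fdx_rules()]-shaped rule set.
#' @return data.frame: protein_id, fdx_type, signature, n_motifs.
#' @export
classify_ferredoxins <- function(records, rules = default_fdx_rules()) {
    calls <- lapply(seq_len(nrow(records)), function(i) {
        m <- scan_fes_motifs(records$sequence[i], rules)
        assign_fdx_type(m, rules, protein_id = records$id[i])
    })
    data.frame(protein_id = vapply(calls, `[[`, "", "protein_id"),
               fdx_type = vapply(calls, `[[`, "", "fdx_type"),
               signature = vapply(calls, `[[`, "", "signature"),
               n_motifs = vapply(calls, function(x) nrow(x$motifs), 0L),
               stringsAsFactors = FALSE)
}

#' Ferredoxin subtype registry
#'
#' Maps (fdx_type, signature) to a subtype number. A user-supplied legacy
#' table (e.g. continuing previously published subtype numbers) seeds the
#' registry; novel signatures receive fresh sequential numbers per type.
#'
#' @param table optional data.frame with columns fdx_type, signature,
#'   subtype_id.
#' @return an environment of class `subtype_registry`.
#' @export
subtype_registry <- function(table = NULL) {
    reg <- new.env(parent = emptyenv())
    reg$map <- if (is.null(table))
        data.frame(fdx_type = character(0), signature = character(0),
                   subtype_id = integer(0), stringsAsFactors = FALSE)
    else {
        stopifnot(all(c("fdx_type", "signature", "subtype_id") %in% names(table)))
        if (anyDuplicated(table[c("fdx_type", "signature")]))
            .stop2("arcp450_duplication_error", "duplicate registry entries")
        data.frame(fdx_type = as.character(table$fdx_type),
                   signature = as.character(table$signature),
                   subtype_id = as.integer(table$subtype_id),
                   stringsAsFactors = FALSE)
    }
    class(reg) <- "subtype_registry"
    reg
}

#' Look up or mint a subtype number
#'
#' Known (type, signature) pairs return their registered number; novel pairs
#' are assigned the next sequential number for that type and persisted in
#' the registry.
#'
#' @param fdx_type,signature the call to key on (composite types key on the
#'   ordered pair of motif signatures joined by "|").
#' @param registry a [subtype_registry()].
#' @return the subtype number (integer).
#' @export
assign_subtype <- function(fdx_type, signature, registry) {
    if (fdx_type == "unclassified" || is.na(signature))
        .stop2("arcp450_value_error", "cannot assign a subtype to an unclassified call")
    hit <- registry$map$fdx_type == fdx_type & registry$map$signature == signature
    if (any(hit)) return(registry$map$subtype_id[which(hit)[1]])
    prev <- registry$map$subtype_id[registry$map$fdx_type == fdx_type]
    new_id <- if (length(prev)) max(prev) + 1L else 1L
    registry$map <- rbind(registry$map,
                          data.frame(fdx_type = fdx_type, signature = signature,
                                     subtype_id = new_id, stringsAsFactors = FALSE))
    new_id
}

#' Read / write a subtype registry TSV
#'
#' Columns: fdx_type, signature, subtype_id.
#' @param path TSV file.
#' @export
read_subtype_registry <- function(path) {
    subtype_registry(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_subtype_registry
#' @param registry a [subtype_registry()].
#' @export
write_subtype_registry <- function(registry, path) {
    write.table(registry$map, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Annotate ferredoxin calls with subtype numbers
#'
#' @param calls a [classify_ferredoxins()] result.
#' @param registry a [subtype_registry()] (updated in place for novel
#'   signatures).
#' @return `calls` with a subtype_id column (NA for unclassified proteins).
#' @export
annotate_subtypes <- function(calls, registry = subtype_registry()) {
    calls$subtype_id <- NA_integer_
    for (i in seq_len(nrow(calls))) {
        if (calls$fdx_type[i] == "unclassified") next
        calls$subtype_id[i] <- assign_subtype(calls$fdx_type[i],
                                              calls$signature[i], registry)
    }
    calls
}

#' Default OFOR description keywords
#'
#' Case-insensitive regular expressions; a protein must match `required`
#' plus one subunit pattern.
#' @export
default_ofor_keywords <- function() {
    list(required = "(2-?oxo(acid|glutarate)|pyruvate)[: ]?.*ferredoxin oxidoreductase",
         alpha = "(subunit )?alpha", beta = "(subunit )?beta")
}

#' Detect OFOR alpha/beta subunits and adjacent gene pairs
#'
#' Mirrors a manual annotation search: proteins whose descriptions match the
#' OFOR keyword rules are called as alpha or beta subunits, and a pair is
#' flagged adjacent when the two genes lie within `max_gene_gap` positions
#' of each other (in gene order) on the same replicon.
#'
#' @param records protein record data.frame (descriptions are searched).
#' @param features gene feature data.frame (see [gene_features()]), used for
#'   gene order; may be `NULL`, in which case no adjacency is computed.
#' @param keywords a [default_ofor_keywords()]-shaped list.
#' @param max_gene_gap maximum difference in gene rank for adjacency
#'   (default 1 = immediate neighbours).
#' @return data.frame: protein_id, subunit, partner_protein_id, adjacent.
#' @export
find_ofor <- function(records, features = NULL,
                      keywords = default_ofor_keywords(), max_gene_gap = 1L) {
    desc <- records$description
    is_ofor <- grepl(keywords$required, desc, ignore.case = TRUE, perl = TRUE)
    is_alpha <- is_ofor & grepl(keywords$alpha, desc, ignore.case = TRUE, perl = TRUE)
    is_beta <- is_ofor & grepl(keywords$beta, desc, ignore.case = TRUE, perl = TRUE) &
        !is_alpha
    if (!any(is_alpha | is_beta))
        return(data.frame(protein_id = character(0), subunit = character(0),
                          partner_protein_id = character(0), adjacent = logical(0),
                          stringsAsFactors = FALSE))
    calls <- data.frame(
        protein_id = records$id[is_alpha | is_beta],
        subunit = ifelse(is_alpha[is_alpha | is_beta], "alpha", "beta"),
        partner_protein_id = NA_character_, adjacent = FALSE,
        stringsAsFactors = FALSE)
    if (nrow(calls) == 0L || is.null(features)) return(calls)
    feats <- features[order(features$replicon_id, features$start), ]
    feats$rank <- stats::ave(seq_len(nrow(feats)), feats$replicon_id,
                             FUN = seq_along)
    loc <- feats[match(calls$protein_id, feats$protein_id),
                 c("replicon_id", "rank")]
    for (i in which(calls$subunit == "alpha")) {
        js <- which(calls$subunit == "beta" &
                    !is.na(loc$replicon_id) & !is.na(loc$replicon_id[i]) &
                    loc$replicon_id == loc$replicon_id[i] &
                    abs(loc$rank - loc$rank[i]) <= max_gene_gap)
        if (length(js)) {
            j <- js[which.min(abs(loc$rank[js] - loc$rank[i]))]
            calls$partner_protein_id[i] <- calls$protein_id[j]
            calls$partner_protein_id[j] <- calls$protein_id[i]
            calls$adjacent[i] <- TRUE; calls$adjacent[j] <- TRUE
        }
    }
    calls
}
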