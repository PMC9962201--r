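## Readers/writers for the external formats the pipeline touches.
##
## Conventions enforced here, once:
##   * protein sequences are uppercase, terminal '*' stops stripped,
##     nonstandard letters (B, Z, U, O, J) mapped to X with a warning;
##   * GFF3 coordinates are kept 1-based inclusive on disk; all internal
##     interval arithmetic is 0-based half-open (see coords_* helpers);
##   * replicon metadata lives in a TSV sidecar, not in FASTA headers,
##     because JGI/NCBI header dialects differ.

.AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")
.AA_NONSTANDARD <- c(B = "X", Z = "X", U = "X", O = "X", J = "X")

#' Construct a protein record table
#'
#' The common currency of the pipeline: one row per protein with its source
#' species and replicon context. Sequences are normalised (uppercased,
#' terminal stop stripped, nonstandard letters mapped to X).
#'
#' @param id character vector of unique accessions.
#' @param sequence amino-acid sequences (20 standard letters plus X after
#'   normalisation).
#' @param description free-text description (defaults to "").
#' @param species,replicon_id source annotations (defaults to `NA`).
#' @param replicon_type one of `"chromosome"`, `"plasmid"`, `"unknown"`.
#' @return data.frame with columns id, description, sequence, species,
#'   replicon_id, replicon_type.
#' @export
protein_records <- function(id, sequence, description = "", species = NA_character_,
                            replicon_id = NA_character_,
                            replicon_type = "unknown") {
    if (length(id) == 0L)
        .stop2("arcp450_value_error", "no records given")
    if (anyDuplicated(id))
        .stop2("arcp450_duplication_error", "duplicate protein id(s): %s",
               paste(unique(id[duplicated(id)]), collapse = ", "))
    sequence <- .normalise_aa(sequence, id)
    replicon_type <- as.character(replicon_type)
    bad <- !replicon_type %in% .REPLICON_TYPES
    if (any(bad))
        .stop2("arcp450_value_error", "unknown replicon_type: %s",
               paste(unique(replicon_type[bad]), collapse = ", "))
    data.frame(id = as.character(id), description = as.character(description),
               sequence = sequence, species = as.character(species),
               replicon_id = as.character(replicon_id),
               replicon_type = replicon_type,
               stringsAsFactors = FALSE)
}

.normalise_aa <- function(sequence, id = NULL) {
    sequence <- toupper(as.character(sequence))
    sequence <- sub("\\*+$", "", sequence)
    if (any(!nzchar(sequence))) {
        which_bad <- if (is.null(id)) which(!nzchar(sequence)) else id[!nzchar(sequence)]
        .stop2("arcp450_format_error", "empty sequence for: %s",
               paste(which_bad, collapse = ", "))
    }
    has_ns <- grepl("[BZUOJ]", sequence)
    if (any(has_ns)) {
        warning(sprintf("%d sequence(s) contain nonstandard letters (B/Z/U/O/J); mapped to X",
                        sum(has_ns)), call. = FALSE)
        sequence <- chartr("BZUOJ", "XXXXX", sequence)
    }
    bad <- grepl(sprintf("[^%s]", paste(.AA_STANDARD, collapse = "")), sequence)
    if (any(bad)) {
        which_bad <- if (is.null(id)) which(bad) else id[bad]
        .stop2("arcp450_format_error", "non-amino-acid letters in: %s",
               paste(which_bad, collapse = ", "))
    }
    sequence
}

#' Read a protein FASTA file
#'
#' One proteome per replicon is the expected layout; pass `replicon_id`
#' (and optionally the metadata table from [read_replicon_table()]) to
#' populate the replicon context of every record.
#'
#' @param path FASTA file.
#' @param replicon_id replicon the proteome belongs to, or `NA`.
#' @param meta optional replicon metadata data.frame; when given and
#'   `replicon_id` is found there, species and replicon_type are filled in.
#' @return data.frame as [protein_records()].
#' @export
read_fasta <- function(path, replicon_id = NA_character_, meta = NULL) {
    if (!file.exists(path))
        .stop2("arcp450_value_error", "no such file: %s", path)
    .validate_fasta_lines(path)
    aa <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    desc <- ifelse(grepl("\\s", names(aa)), sub("^\\S+\\s+", "", names(aa)), "")
    if (anyDuplicated(ids))
        .stop2("arcp450_duplication_error", "duplicate FASTA id(s) in %s: %s",
               path, paste(unique(ids[duplicated(ids)]), collapse = ", "))
    species <- NA_character_; rtype <- "unknown"
    if (!is.null(meta) && !is.na(replicon_id)) {
        hit <- match(replicon_id, meta$replicon_id)
        if (!is.na(hit)) {
            species <- meta$species[hit]
            rtype <- meta$replicon_type[hit]
        }
    }
    protein_records(id = ids, sequence = as.character(aa), description = desc,
                    species = species, replicon_id = replicon_id,
                    replicon_type = rtype)
}

# cheap structural scan so format errors can name a line number
.validate_fasta_lines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || !startsWith(trimws(lines[1]), ">"))
        .stop2("arcp450_format_error", "%s: line 1: expected FASTA header", path)
    is_hdr <- startsWith(lines, ">")
    hdr_at <- which(is_hdr)
    empty_hdr <- hdr_at[!nzchar(trimws(sub("^>", "", lines[hdr_at])))]
    if (length(empty_hdr))
        .stop2("arcp450_format_error", "%s: line %d: malformed (empty) header",
               path, empty_hdr[1])
    nxt <- c(hdr_at[-1], length(lines) + 1L)
    seq_len_per <- nxt - hdr_at - 1L
    no_seq <- hdr_at[seq_len_per <= 0L |
                     vapply(seq_along(hdr_at), function(k) {
                         body <- lines[seq.int(hdr_at[k] + 1L, length.out = seq_len_per[k])]
                         !any(nzchar(trimws(body)))
                     }, logical(1))]
    if (length(no_seq))
        .stop2("arcp450_format_error", "%s: line %d: record has empty sequence",
               path, no_seq[1])
    invisible(TRUE)
}

#' Write protein records as FASTA
#'
#' @param records data.frame from [protein_records()].
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
    aa <- Biostrings::BStringSet(setNames(records$sequence, ifelse(
        nzchar(records$description) & !is.na(records$description),
        paste(records$id, records$description), records$id)))
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Read gene features from GFF3
#'
#' Keeps CDS (or, lacking CDS, gene) features. Coordinates stay 1-based
#' inclusive exactly as in the file; the protein id is taken from the
#' `protein_id` attribute, falling back to `ID`.
#'
#' @param path GFF3 file.
#' @return data.frame with columns gene_id, protein_id, replicon_id, start,
#'   end, strand, sorted by (replicon_id, start).
#' @export
read_gff3 <- function(path) {
    if (!file.exists(path))
        .stop2("arcp450_value_error", "no such file: %s", path)
    g <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(g$type) %in% "CDS"
    if (!any(keep)) keep <- as.character(g$type) %in% "gene"
    g <- g[keep]
    if (length(g) == 0L)
        .stop2("arcp450_format_error", "%s: no CDS or gene features", path)
    strand <- as.character(BiocGenerics::strand(g))
    if (any(strand == "*"))
        .stop2("arcp450_format_error", "%s: feature(s) with missing strand", path)
    pid <- if (!is.null(g$protein_id)) as.character(g$protein_id) else rep(NA_character_, length(g))
    id <- if (!is.null(g$ID)) as.character(g$ID) else rep(NA_character_, length(g))
    pid <- ifelse(is.na(pid), id, pid)
    feats <- gene_features(gene_id = ifelse(is.na(id), pid, id), protein_id = pid,
                           replicon_id = as.character(GenomeInfoDb::seqnames(g)),
                           start = BiocGenerics::start(g), end = BiocGenerics::end(g),
                           strand = strand)
    feats
}

#' Construct (and validate) a gene feature table
#'
#' @param gene_id,protein_id identifiers; protein_id links to protein records.
#' @param replicon_id replicon of each gene.
#' @param start,end 1-based inclusive nucleotide coordinates.
#' @param strand "+" or "-".
#' @return data.frame sorted by (replicon_id, start).
#' @export
gene_features <- function(gene_id, protein_id, replicon_id, start, end, strand) {
    start <- as.integer(start); end <- as.integer(end)
    if (any(start < 1L) || any(start > end))
        .stop2("arcp450_coordinate_error",
               "invalid coordinates (need 1 <= start <= end)")
    if (!all(strand %in% c("+", "-")))
        .stop2("arcp450_format_error", "strand must be '+' or '-'")
    out <- data.frame(gene_id = as.character(gene_id),
                      protein_id = as.character(protein_id),
                      replicon_id = as.character(replicon_id),
                      start = start, end = end, strand = as.character(strand),
                      stringsAsFactors = FALSE)
    out[order(out$replicon_id, out$start), , drop = FALSE]
}

#' Write gene features as GFF3
#' @param features data.frame from [gene_features()].
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
    lines <- c("##gff-version 3",
               sprintf("%s\tarcp450\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=%s",
                       features$replicon_id, features$start, features$end,
                       features$strand, features$gene_id, features$protein_id))
    writeLines(lines, path)
    invisible(path)
}

## 0-based half-open <-> 1-based inclusive. All internal interval arithmetic
## uses the half-open form; files keep the GFF3 form.

#' @rdname coords
#' @param start,end 1-based inclusive coordinates.
#' @export
coords_to_0based <- function(start, end) {
    if (any(start > end)) .stop2("arcp450_coordinate_error", "start > end")
    list(start = start - 1L, end = end)
}

#' Coordinate convention converters
#'
#' @rdname coords
#' @param start0,end0 0-based half-open coordinates.
#' @export
coords_to_1based <- function(start0, end0) {
    if (any(start0 >= end0)) .stop2("arcp450_coordinate_error", "empty interval")
    list(start = start0 + 1L, end = end0)
}

#' Read the replicon metadata table
#'
#' Tab-separated with header columns replicon_id, species, replicon_type,
#' accession. replicon_type is parsed case-insensitively and must be
#' "chromosome" or "plasmid".
#'
#' @param path TSV file.
#' @return data.frame, one row per replicon.
#' @export
read_replicon_table <- function(path) {
    if (!file.exists(path))
        .stop2("arcp450_value_error", "no such file: %s", path)
    tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("replicon_id", "species", "replicon_type", "accession")
    if (!all(need %in% names(tab)))
        .stop2("arcp450_format_error", "%s: missing column(s): %s", path,
               paste(setdiff(need, names(tab)), collapse = ", "))
    replicon_meta(tab$replicon_id, tab$species, tab$replicon_type, tab$accession)
}

#' Construct (and validate) replicon metadata
#' @param replicon_id unique replicon identifiers.
#' @param species source species of each replicon.
#' @param replicon_type "chromosome" or "plasmid" (case-insensitive).
#' @param accession sequence database accession.
#' @export
replicon_meta <- function(replicon_id, species, replicon_type,
                          accession = NA_character_) {
    if (anyDuplicated(replicon_id))
        .stop2("arcp450_duplication_error", "duplicate replicon_id(s): %s",
               paste(unique(replicon_id[duplicated(replicon_id)]), collapse = ", "))
    rt <- tolower(as.character(replicon_type))
    bad <- !rt %in% c("chromosome", "plasmid")
    if (any(bad))
        .stop2("arcp450_value_error", "unknown replicon_type token(s): %s",
               paste(unique(replicon_type[bad]), collapse = ", "))
    data.frame(replicon_id = as.character(replicon_id),
               species = as.character(species), replicon_type = rt,
               accession = as.character(accession), stringsAsFactors = FALSE)
}

#' Write the replicon metadata table
#' @param meta data.frame from [replicon_meta()].
#' @param path output TSV.
#' @export
write_replicon_table <- function(meta, path) {
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Serialize a phylogenetic tree to Newick
#'
#' Leaf labels containing Newick metacharacters (whitespace, parentheses,
#' commas, colons, semicolons, quotes, brackets) are single-quoted; the
#' output re-parses with a reference Newick parser.
#'
#' @param tree an [ape::ape-package] `phylo` object.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
    if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
        length(tree$tip.label) == 0L)
        .stop2("arcp450_value_error", "empty or invalid tree")
    labels <- tree$tip.label
    needs_quote <- grepl("[][()\\s,:;'\"]", labels, perl = TRUE)
    quoted <- ifelse(needs_quote,
                     paste0("'", gsub("'", "''", labels), "'"), labels)
    # ape::write.tree sanitises labels, so serialize with placeholder tokens
    # and substitute the properly quoted labels afterwards
    tokens <- sprintf("ARCTIP%dPIT", seq_along(labels))
    tmp <- tree; tmp$tip.label <- tokens
    nwk <- ape::write.tree(tmp)
    for (k in seq_along(tokens))
        nwk <- sub(tokens[k], quoted[k], nwk, fixed = TRUE)
    if (!is.null(path)) {
        writeLines(nwk, path)
        return(invisible(nwk))
    }
    nwk
}
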