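## One-call orchestration of every stage, from loaded inputs to the full set
## of result tables, plus a manifest that makes a run self-describing. The
## exported stage functions are the primary interface; run_pipeline() wires
## them together in the canonical order:
##   screen -> classify -> ferredoxins/OFOR -> operons -> comparative tables
##   -> saturation -> tree.

#' Run configuration
#'
#' @param fasta named character vector of FASTA paths, one per replicon
#'   (names are replicon ids), or `NULL` when `records` is supplied
#'   directly to [run_pipeline()].
#' @param gff path to the gene-feature GFF3 (optional; operon stages are
#'   skipped without it).
#' @param replicons path to the replicon metadata TSV.
#' @param refdb optional path to a named-P450 reference FASTA.
#' @param registry optional path to a ferredoxin subtype registry TSV.
#' @param screen a [screen_params()] object.
#' @param aln an [align_params()] object.
#' @param classifier a [classifier_params()] object.
#' @param fdx_rules a [default_fdx_rules()]-shaped rule set.
#' @param max_gap_bp operon gap threshold (bp).
#' @param n_permutations,seed saturation-curve settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, gff = NULL, replicons = NULL,
                       refdb = NULL, registry = NULL,
                       screen = screen_params(), aln = align_params(),
                       classifier = classifier_params(),
                       fdx_rules = default_fdx_rules(), max_gap_bp = 150L,
                       n_permutations = 100L, seed = 1L) {
    for (p in c(fasta, gff, replicons, refdb, registry))
        if (!is.null(p) && !file.exists(p))
            .stop2("arcp450_configuration_error", "input does not exist: %s", p)
    structure(list(fasta = fasta, gff = gff, replicons = replicons,
                   refdb = refdb, registry = registry, screen = screen,
                   aln = aln, classifier = classifier, fdx_rules = fdx_rules,
                   max_gap_bp = max_gap_bp, n_permutations = n_permutations,
                   seed = seed), class = "run_config")
}

#' Run the full annotation and comparison pipeline
#'
#' Executes every stage and writes the result tables to `out_dir`:
#' screen.tsv, assignments.tsv, family_counts.tsv, fdx.tsv, ofor.tsv,
#' operons.tsv, operon_context.tsv, copresence.tsv, replicon_comparison.tsv,
#' saturation.tsv, tree.nwk and manifest.json. Re-running with identical
#' config and inputs reproduces identical tables.
#'
#' @param config a [run_config()] object.
#' @param out_dir output directory (created if needed).
#' @param records,features,meta pre-loaded inputs, overriding the paths in
#'   `config` (convenient for synthetic studies).
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir, records = NULL, features = NULL,
                         meta = NULL) {
    stage <- "load_inputs"
    result <- tryCatch({
        if (is.null(meta) && !is.null(config$replicons))
            meta <- read_replicon_table(config$replicons)
        if (is.null(records)) {
            if (is.null(config$fasta))
                .stop2("arcp450_configuration_error", "no proteomes given")
            recs <- lapply(seq_along(config$fasta), function(i)
                read_fasta(config$fasta[i],
                           replicon_id = names(config$fasta)[i], meta = meta))
            records <- do.call(rbind, recs)
            if (anyDuplicated(records$id))
                .stop2("arcp450_duplication_error",
                       "duplicate protein ids across proteomes")
        }
        if (is.null(features) && !is.null(config$gff))
            features <- read_gff3(config$gff)
        refdb <- if (!is.null(config$refdb))
            build_reference_db(read_fasta(config$refdb)) else NULL
        registry <- if (!is.null(config$registry))
            read_subtype_registry(config$registry) else subtype_registry()

        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        tsv <- function(x, name) {
            write.table(as.data.frame(x), file.path(out_dir, name),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }

        stage <- "p450_screen"
        screen <- screen_proteome(records, config$screen)
        tsv(screen$calls, "screen.tsv")
        full_ids <- screen$calls$protein_id[screen$calls$status == "full_length"]

        stage <- "nomenclature"
        queries <- records[records$id %in% full_ids, , drop = FALSE]
        imat <- if (nrow(queries) >= 2L) identity_matrix(queries, config$aln) else NULL
        assignments <- assign_families(queries, refdb, config$classifier,
                                       config$aln, imat = imat)
        tsv(assignments, "assignments.tsv")
        fam_counts <- count_families(assignments)
        tsv(fam_counts, "family_counts.tsv")

        stage <- "ferredoxin"
        # skip everything the screen claimed as P450 (full-length or
        # fragment): P450s are heme-thiolate proteins whose cysteines would
        # otherwise feed spurious Fe-S motif matches
        p450_like <- screen$calls$protein_id[screen$calls$status != "not_p450"]
        non_p450 <- records[!records$id %in% p450_like, , drop = FALSE]
        fdx <- classify_ferredoxins(non_p450, config$fdx_rules)
        fdx <- fdx[fdx$fdx_type != "unclassified", , drop = FALSE]
        fdx <- annotate_subtypes(fdx, registry)
        tsv(fdx, "fdx.tsv")
        ofor <- find_ofor(records, features)
        tsv(ofor, "ofor.tsv")

        stage <- "operons"
        operons <- NULL; context <- NULL
        if (!is.null(features)) {
            operons <- predict_operons(features, config$max_gap_bp)
            tsv(operons, "operons.tsv")
            in_feats <- full_ids[full_ids %in% features$protein_id]
            context <- p450_operon_context(operons, features, in_feats,
                                           fdx_calls = fdx, ofor_calls = ofor)
            tsv(context, "operon_context.tsv")
        }

        stage <- "comparative"
        species_map <- setNames(records$species, records$id)
        copresence <- copresence_counts(assignments, species_map)
        utils::write.table(cbind(family = rownames(copresence), as.data.frame(copresence)),
                           file.path(out_dir, "copresence.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        comparison <- NULL
        if (all(records$replicon_type[match(assignments$protein_id,
                                            records$id)] != "unknown")) {
            comparison <- replicon_family_comparison(assignments, records)
            tsv(comparison, "replicon_comparison.tsv")
        }
        saturation <- family_saturation(assignments, species_map,
                                        config$n_permutations, config$seed)
        tsv(saturation, "saturation.tsv")

        stage <- "phylo"
        tree <- NULL
        if (!is.null(imat) && nrow(imat) >= 3L) {
            tree <- nj_tree(identity_to_distance(imat))
            write_newick(tree, file.path(out_dir, "tree.nwk"))
        }

        stage <- "manifest"
        cfg_plain <- config
        cfg_plain$aln$submat <- NULL  # matrix omitted; named table recorded
        manifest <- list(
            package = "arcp450",
            version = as.character(utils::packageVersion("arcp450")),
            seed = config$seed,
            config = cfg_plain,
            n_records = nrow(records),
            outputs = list.files(out_dir, pattern = "\\.(tsv|nwk)$"))
        manifest$config_hash <- .config_hash(cfg_plain)
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, force = TRUE)

        list(records = records, features = features, meta = meta,
             screen = screen, assignments = assignments,
             family_counts = fam_counts, fdx = fdx, ofor = ofor,
             operons = operons, context = context, copresence = copresence,
             comparison = comparison, saturation = saturation, tree = tree)
    }, arcp450_error = function(e) {
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE)
    })
    invisible(result)
}

# stable hash of the (plain) config: md5 of its canonical JSON
.config_hash <- function(cfg) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
    unname(tools::md5sum(tmp))
}
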