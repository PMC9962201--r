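test_that("signatures serialize and parse losslessly", {
    expect_equal(fdx_signature(c(2, 2, 4)), "C-2-C-2-C-4-C")
    expect_equal(parse_fdx_signature("C-2-C-2-C-4-C"), c(2L, 2L, 4L))
    set.seed(61)
    for (k in 1:20) {
        sp <- sample(1:40, sample(1:4, 1), replace = TRUE)
        expect_equal(parse_fdx_signature(fdx_signature(sp)), sp)
    }
    expect_error(parse_fdx_signature("C2C"), class = "arcp450_format_error")
})

test_that("a planted bacterial-type motif is scanned with its signature", {
    # C xx C xx C xxxx C  -> spacings (2,2,4)
    s <- paste0("MAA", "CAACAACAAAAC", "AAA")
    m <- scan_fes_motifs(s)
    expect_equal(nrow(m), 1L)
    expect_equal(m$cluster_class, "cluster_4Fe4S")
    expect_equal(m$signature, "C-2-C-2-C-4-C")
    expect_equal(m$cys_positions[[1]], c(3L, 6L, 9L, 14L))
    expect_equal(m$spacings[[1]], c(2L, 2L, 4L))
})

test_that("cysteine-free sequences yield no motifs and unclassified calls", {
    s <- rand_decoy(120)
    expect_equal(nrow(scan_fes_motifs(s)), 0L)
    call <- assign_fdx_type(scan_fes_motifs(s), protein_id = "x")
    expect_equal(call$fdx_type, "unclassified")
})

test_that("two planted motifs are found without overlap", {
    block <- "CAACAACAAAC"  # (2,2,3)
    s <- paste0("MAAA", block, paste(rep("A", 30), collapse = ""), block, "AA")
    m <- scan_fes_motifs(s)
    expect_equal(nrow(m), 2L)
    expect_true(all(m$cluster_class == "cluster_4Fe4S"))
    # non-overlap: first motif ends before the second starts
    expect_lt(max(m$cys_positions[[1]]), min(m$cys_positions[[2]]))
    # window-enumeration oracle: every rule-conformant 4-cysteine window
    cys <- which(strsplit(s, "")[[1]] == "C") - 1L
    conformant <- 0L
    for (i in seq_along(cys)) {
        for (j in seq_along(cys)) for (k in seq_along(cys)) for (l in seq_along(cys)) {
            if (i < j && j < k && k < l) {
                sp <- diff(cys[c(i, j, k, l)]) - 1L
                if (sp[1] == 2 && sp[2] == 2 && sp[3] >= 3 && sp[3] <= 40)
                    conformant <- conformant + 1L
            }
        }
    }
    expect_gte(conformant, 2L)  # the two planted windows conform
})

test_that("composite Fe-S types resolve before single-motif types", {
    rules <- default_fdx_rules()
    two4 <- scan_fes_motifs(paste0("MA", "CAACAACAAAC",
                                   paste(rep("A", 20), collapse = ""),
                                   "CAACAACAAAC", "A"), rules)
    expect_equal(assign_fdx_type(two4, rules)$fdx_type, "2[4Fe-4S]")

    mix <- scan_fes_motifs(paste0("MA", "CAAAAAACAAAAAAAAAAAAAAAAAAAAAAC",
                                  paste(rep("A", 12), collapse = ""),
                                  "CAACAACAAAC", "A"), rules)
    expect_equal(sort(mix$cluster_class),
                 c("cluster_3Fe4S", "cluster_4Fe4S"))
    expect_equal(assign_fdx_type(mix, rules)$fdx_type, "7Fe-8S")

    single <- scan_fes_motifs("MACAAAAAACAAAAAAAAAAAAAAAAAAAAAACAA", rules)
    expect_equal(assign_fdx_type(single, rules)$fdx_type, "3Fe-4S")
})

test_that("Alvin-type 2[4Fe-4S] is split on the final spacing", {
    rules <- default_fdx_rules()
    alv <- generate_ferredoxin("2[4Fe-4S]Alv", id = "f1")
    expect_equal(classify_ferredoxins(alv, rules)$fdx_type, "2[4Fe-4S]Alv")
    std <- generate_ferredoxin("2[4Fe-4S]", id = "f2")
    expect_equal(classify_ferredoxins(std, rules)$fdx_type, "2[4Fe-4S]")
})

test_that("generated ferredoxins round-trip for every type", {
    set.seed(62)
    for (ty in names(default_fdx_signatures())) {
        rec <- generate_ferredoxin(ty, id = paste0("f_", ty))
        call <- classify_ferredoxins(rec)
        expect_equal(call$fdx_type, ty)
        expect_equal(call$signature,
                     paste(default_fdx_signatures()[[ty]], collapse = "|"))
    }
    expect_error(generate_ferredoxin("4Fe-4S", signatures = "C-9-C-9-C-9-C"),
                 class = "arcp450_value_error")
})

test_that("the subtype registry is stable, sequential and type-scoped", {
    legacy <- data.frame(fdx_type = "2Fe-2S", signature = "C-5-C-2-C-29-C",
                         subtype_id = 24L)
    reg <- subtype_registry(legacy)
    expect_equal(assign_subtype("2Fe-2S", "C-5-C-2-C-29-C", reg), 24L)
    # novel signature of the same type continues the numbering
    expect_equal(assign_subtype("2Fe-2S", "C-4-C-2-C-22-C", reg), 25L)
    # another type starts at 1
    expect_equal(assign_subtype("3Fe-4S", "C-6-C-28-C", reg), 1L)
    # idempotence
    expect_equal(assign_subtype("2Fe-2S", "C-4-C-2-C-22-C", reg), 25L)
    expect_error(assign_subtype("unclassified", NA, reg),
                 class = "arcp450_value_error")
})

test_that("registry round-trips through its TSV form", {
    reg <- subtype_registry()
    assign_subtype("2Fe-2S", "C-5-C-2-C-29-C", reg)
    assign_subtype("4Fe-4S", "C-2-C-2-C-3-C", reg)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_subtype_registry(reg, f)
    reg2 <- read_subtype_registry(f)
    expect_equal(reg2$map, reg$map)
    # identical sequences get identical subtype ids on re-annotation
    set.seed(63)
    recs <- rbind(generate_ferredoxin("2Fe-2S", id = "a"),
                  generate_ferredoxin("2Fe-2S", id = "b"))
    calls <- annotate_subtypes(classify_ferredoxins(recs), reg2)
    expect_equal(calls$subtype_id[1], calls$subtype_id[2])
})

test_that("OFOR subunits are detected and paired by gene adjacency", {
    set.seed(64)
    recs <- protein_records(
        id = c("a1", "b1", "b2", "x1"),
        sequence = replicate(4, rand_decoy(300)),
        description = c("2-oxoacid:ferredoxin oxidoreductase subunit alpha",
                        "2-oxoacid:ferredoxin oxidoreductase subunit beta",
                        "2-oxoacid:ferredoxin oxidoreductase subunit beta",
                        "aldolase"))
    # a1/b1 adjacent on chr; b2 alone on a plasmid
    feats <- gene_features(gene_id = c("g1", "g2", "g3"),
                           protein_id = c("a1", "b1", "b2"),
                           replicon_id = c("chr", "chr", "pls"),
                           start = c(1L, 1300L, 1L), end = c(1200L, 2400L, 900L),
                           strand = c("+", "+", "+"))
    calls <- find_ofor(recs, feats)
    expect_equal(sort(calls$protein_id), c("a1", "b1", "b2"))
    a1 <- calls[calls$protein_id == "a1", ]
    expect_true(a1$adjacent)
    expect_equal(a1$partner_protein_id, "b1")
    expect_false(calls$adjacent[calls$protein_id == "b2"])

    expect_equal(nrow(find_ofor(recs[4, , drop = FALSE], feats)), 0L)
})
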