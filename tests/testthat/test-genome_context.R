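test_that("operon prediction follows the strand/gap rule", {
    # two (+) genes, gap 49 <= 150: one operon
    f <- layout_features("r1", lengths = c(100L, 151L), gaps = c(49L),
                         strands = c("+", "+"))
    ops <- predict_operons(f, 150L)
    expect_equal(nrow(ops), 1L)
    expect_equal(ops$n_genes, 2L)

    # adjacent genes on opposite strands: two singletons
    f <- layout_features("r1", lengths = c(100L, 100L), gaps = c(10L),
                         strands = c("+", "-"))
    expect_equal(predict_operons(f, 150L)$n_genes, c(1L, 1L))

    # gaps (50, 500, 10, 10): operons of sizes 2 and 3
    f <- layout_features("r1", lengths = rep(200L, 5),
                         gaps = c(50L, 500L, 10L, 10L), strands = rep("+", 5))
    ops <- predict_operons(f, 150L)
    expect_equal(ops$n_genes, c(2L, 3L))
})

test_that("overlapping same-strand genes are treated as gap zero", {
    f <- layout_features("r1", lengths = c(100L, 100L), gaps = c(-20L),
                         strands = c("+", "+"))
    expect_warning(ops <- predict_operons(f, 150L), "overlapping")
    expect_equal(ops$n_genes, 2L)
})

test_that("every gene lands in exactly one operon, fewer operons at larger gaps", {
    set.seed(71)
    f <- layout_features("r1", lengths = sample(100:900, 30, replace = TRUE),
                         gaps = sample(c(10:200, 400:900), 29, replace = TRUE),
                         strands = sample(c("+", "-"), 30, replace = TRUE))
    counts <- vapply(c(0L, 50L, 150L, 500L, 1000L), function(g) {
        ops <- predict_operons(f, g)
        memb <- operon_membership(ops)
        expect_equal(sort(memb$gene_id), sort(f$gene_id))
        expect_equal(anyDuplicated(memb$gene_id), 0L)
        nrow(ops)
    }, 0L)
    expect_true(all(diff(counts) <= 0L))
})

test_that("P450 operon context flags co-transcribed redox partners", {
    set.seed(72)
    # operon 1: decoy -> P450 (no partner); operon 2: P450 + ferredoxin
    f <- layout_features("r1",
                         lengths = c(300L, 1200L, 900L, 1200L, 300L),
                         gaps = c(40L, 800L, 40L, 900L),
                         strands = c("+", "+", "-", "-", "-"))
    p450s <- f$protein_id[c(2, 4)]
    fdx <- data.frame(protein_id = f$protein_id[3], fdx_type = "2Fe-2S",
                      stringsAsFactors = FALSE)
    ops <- predict_operons(f, 150L)
    ctx <- p450_operon_context(ops, f, p450s, fdx_calls = fdx)
    expect_equal(nrow(ctx), 2L)
    expect_equal(ctx$has_ferredoxin, c(FALSE, TRUE))
    expect_false(any(ctx$has_ofor))
    expect_match(ctx$genes[1], "->")

    # no P450-containing operons -> empty table
    ctx0 <- p450_operon_context(ops, f, character(0))
    expect_equal(nrow(ctx0), 0L)
    # unlinked P450 id -> linkage error
    expect_error(p450_operon_context(ops, f, "ghost"),
                 class = "arcp450_linkage_error")
})

test_that("co-presence counts species sharing family pairs", {
    asg <- data.frame(
        protein_id = sprintf("p%d", 1:6),
        family = c("CYP109", "CYP197", "CYP109", "CYP109", "CYP197", "CYP147"),
        stringsAsFactors = FALSE)
    sp <- setNames(c("S1", "S1", "S2", "S3", "S3", "S3"), asg$protein_id)
    m <- copresence_counts(asg, sp)
    expect_equal(m["CYP109", "CYP197"], 2L)  # S1 and S3
    expect_equal(m["CYP109", "CYP109"], 3L)  # diagonal = species count
    expect_equal(m["CYP147", "CYP197"], 1L)
    expect_equal(m, t(m))
    # entry bounded by its diagonal pair
    for (f1 in rownames(m)) for (f2 in colnames(m))
        expect_lte(m[f1, f2], min(m[f1, f1], m[f2, f2]))
})

test_that("co-presence invariants hold on random synthetic inputs", {
    set.seed(73)
    for (k in 1:5) {
        n <- sample(10:40, 1)
        asg <- data.frame(protein_id = sprintf("p%d", seq_len(n)),
                          family = sample(sprintf("F%d", 1:5), n, replace = TRUE),
                          stringsAsFactors = FALSE)
        sp <- setNames(sample(sprintf("S%d", 1:6), n, replace = TRUE),
                       asg$protein_id)
        m <- copresence_counts(asg, sp)
        expect_equal(m, t(m))
        expect_true(all(m[upper.tri(m)] <= min(diag(m)[1], Inf)))
        for (f1 in rownames(m)) for (f2 in colnames(m))
            expect_lte(m[f1, f2], min(m[f1, f1], m[f2, f2]))
    }
})

test_that("plasmid/chromosome family comparison conserves totals", {
    set.seed(74)
    recs <- protein_records(id = sprintf("p%d", 1:6),
                            sequence = replicate(6, rand_decoy(60)),
                            replicon_id = "r",
                            replicon_type = c("plasmid", "plasmid", "chromosome",
                                              "chromosome", "chromosome", "plasmid"))
    asg <- data.frame(protein_id = recs$id,
                      family = c("F1", "F1", "F1", "F2", "F2", "F2"),
                      stringsAsFactors = FALSE)
    tab <- replicon_family_comparison(asg, recs)
    expect_equal(sum(tab$plasmid_count) + sum(tab$chromosome_count), nrow(asg))
    expect_equal(tab$plasmid_count[tab$family == "F1"], 2L)
    expect_equal(tab$chromosome_count[tab$family == "F2"], 2L)

    recs$replicon_type[1] <- "unknown"
    expect_error(replicon_family_comparison(asg, recs),
                 class = "arcp450_linkage_error")
})

test_that("saturation curve is exact on the enumerable worked example", {
    asg <- data.frame(protein_id = sprintf("p%d", 1:4),
                      family = c("A", "B", "B", "C"), stringsAsFactors = FALSE)
    sp <- setNames(c("S1", "S1", "S2", "S3"), asg$protein_id)
    # exact means over all 3! orderings: k=1 (2+1+1)/3, k=2 (2+3+2+2+3+2)/6
    cur <- family_saturation(asg, sp, exhaustive = TRUE)
    expect_equal(cur$mean_cumulative_families, c(4/3, 7/3, 3))
    expect_equal(attr(cur, "n_permutations"), 6L)
})

test_that("saturation curve is monotone, seeded and ends at the family total", {
    set.seed(75)
    n <- 30
    asg <- data.frame(protein_id = sprintf("p%d", 1:n),
                      family = sample(sprintf("F%d", 1:7), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    sp <- setNames(sample(sprintf("S%d", 1:8), n, replace = TRUE), asg$protein_id)
    c1 <- family_saturation(asg, sp, n_permutations = 40, seed = 9)
    c2 <- family_saturation(asg, sp, n_permutations = 40, seed = 9)
    expect_equal(c1, c2)
    expect_true(all(diff(c1$mean_cumulative_families) >= 0))
    expect_equal(c1$mean_cumulative_families[nrow(c1)],
                 length(unique(asg$family)))
    # degenerate cases: one shared family -> flat at 1; unique families -> diagonal
    asg1 <- data.frame(protein_id = c("a", "b"), family = "F",
                       stringsAsFactors = FALSE)
    expect_equal(family_saturation(asg1, c(a = "S1", b = "S2"),
                                   exhaustive = TRUE)$mean_cumulative_families,
                 c(1, 1))
    asg2 <- data.frame(protein_id = c("a", "b", "c"), family = c("F1", "F2", "F3"),
                       stringsAsFactors = FALSE)
    expect_equal(family_saturation(asg2, c(a = "S1", b = "S2", c = "S3"),
                                   exhaustive = TRUE)$mean_cumulative_families,
                 c(1, 2, 3))
})
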