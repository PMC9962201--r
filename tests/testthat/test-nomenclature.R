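test_that("CYP labels parse into family, subfamily and member", {
    p <- parse_cyp_name(c("CYP147A1", "CYP1002B4", "CYP197AK3", "CYP51"))
    expect_equal(p$family, c("CYP147", "CYP1002", "CYP197", "CYP51"))
    expect_equal(p$subfamily, c("A", "B", "AK", NA))
    expect_equal(p$member, c(1L, 4L, 3L, NA))
    expect_error(parse_cyp_name("P450x"), class = "arcp450_format_error")
})

test_that("reference placement follows the 40/55 identity rules", {
    set.seed(51)
    ref_seqs <- replicate(3, planted_p450(420))
    refdb <- build_reference_db(protein_records(
        id = c("CYP147A1", "CYP109G2", "CYP197C1"), sequence = ref_seqs))

    # identical to a reference: family and subfamily inherited
    q <- protein_records(id = "q1", sequence = ref_seqs[1])
    a <- assign_against_reference(q, refdb)
    expect_equal(a$family, "CYP147")
    expect_equal(a$subfamily, "A")
    expect_equal(a$best_identity, 100)
    expect_false(a$novel_family)

    # family band (~45%): family inherited, subfamily left for lettering
    set.seed(52)
    mid <- mutate_to_identity(ref_seqs[2], c(44, 46))
    a <- assign_against_reference(protein_records(id = "q2", sequence = mid), refdb)
    expect_equal(a$family, "CYP109")
    expect_true(a$novel_subfamily)
    expect_false(a$novel_family)
    expect_true(a$best_identity >= 40 && a$best_identity < 55)

    # below 40 everywhere: novel family
    set.seed(53)
    far <- mutate_to_identity(ref_seqs[3], c(25, 30))
    a <- assign_against_reference(protein_records(id = "q3", sequence = far), refdb)
    expect_true(a$novel_family)
    expect_true(is.na(a$family))

    expect_error(assign_against_reference(q, list()),
                 class = "arcp450_configuration_error")
})

test_that("single-linkage family clustering chains through the threshold", {
    imat <- matrix(c(100, 45, 20,
                     45, 100, 45,
                     20, 45, 100), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    expect_warning(fams <- cluster_novel_families(c("A", "B", "C"), imat),
                   "chained")
    expect_length(fams, 1L)
    expect_equal(fams[[1]], c("A", "B", "C"))

    # all below the threshold: one family each
    imat2 <- matrix(30, 3, 3, dimnames = dimnames(imat)); diag(imat2) <- 100
    expect_length(cluster_novel_families(c("A", "B", "C"), imat2), 3L)

    # all mutually >= 60: one family, no chaining warning
    imat3 <- matrix(60, 3, 3, dimnames = dimnames(imat)); diag(imat3) <- 100
    expect_no_warning(fams3 <- cluster_novel_families(c("A", "B", "C"), imat3))
    expect_length(fams3, 1L)
})

test_that("subfamily clustering letters components in order", {
    ids <- c("a1", "a2", "b1", "b2")
    imat <- matrix(45, 4, 4, dimnames = list(ids, ids))
    imat[1:2, 1:2] <- 80; imat[3:4, 3:4] <- 80; diag(imat) <- 100
    subs <- cluster_subfamilies(ids, imat)
    expect_equal(names(subs), c("A", "B"))
    expect_equal(subs$A, c("a1", "a2"))
    expect_equal(subs$B, c("b1", "b2"))
    # singleton family
    expect_equal(cluster_subfamilies("solo", imat[1, 1, drop = FALSE]),
                 list(A = "solo"))
    # continuation after existing reference letters
    subs2 <- cluster_subfamilies(ids, imat, first_letter_index = 2L)
    expect_equal(names(subs2), c("B", "C"))
})

test_that("de-novo assignment recovers planted families with CYPN labels", {
    set.seed(54)
    f1 <- generate_p450_family("X1", 3, band = c(62, 70))
    f2 <- generate_p450_family("X2", 2, band = c(62, 70),
                               other_seeds = f1$seed$sequence)
    queries <- rbind(f1$records, f2$records)
    asg <- assign_families(queries)
    expect_equal(sort(unique(asg$family)), c("CYPN1", "CYPN2"))
    expect_equal(unname(table(asg$family)[asg$family[match(f1$truth$protein_id,
                                                           asg$protein_id)][1]]), 3L)
    # partition property: one family and one subfamily per query
    expect_false(any(is.na(asg$family)))
    expect_false(any(is.na(asg$subfamily)))
    expect_false(anyDuplicated(asg$protein_id) > 0)
    # labels unique and well-formed
    expect_false(anyDuplicated(asg$label) > 0)
    expect_true(all(grepl("^CYPN[0-9]+[A-Z]+[0-9]+$", asg$label)))
})

test_that("a reference classified against its own database maps to itself", {
    set.seed(55)
    refs <- protein_records(id = c("CYP147A1", "CYP109G2"),
                            sequence = replicate(2, planted_p450(400)))
    refdb <- build_reference_db(refs)
    for (i in 1:2) {
        a <- assign_against_reference(refs[i, ], refdb)
        expect_equal(paste0(a$family, a$subfamily),
                     sub("[0-9]+$", "", refs$id[i]))
    }
})

test_that("family counts sum to the assigned total and sort by size", {
    asg <- data.frame(protein_id = sprintf("p%d", 1:5),
                      family = c("CYPN1", "CYPN1", "CYPN1", "CYPN2", "CYPN2"),
                      subfamily = c("A", "A", "B", "A", "A"),
                      stringsAsFactors = FALSE)
    ct <- count_families(asg)
    expect_equal(ct$n_members, c(3L, 2L))
    expect_equal(ct$n_subfamilies, c(2L, 1L))
    expect_equal(sum(ct$n_members), nrow(asg))
})

test_that("raising the family threshold never merges families", {
    set.seed(56)
    ids <- sprintf("s%d", 1:6)
    m <- matrix(runif(36, 20, 90), 6, 6, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 100
    n_fams <- vapply(c(30, 40, 50, 60), function(thr) {
        suppressWarnings(length(cluster_novel_families(
            ids, m, classifier_params(family_threshold = thr,
                                      subfamily_threshold = thr + 10))))
    }, 0L)
    expect_true(all(diff(n_fams) >= 0L))
})
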