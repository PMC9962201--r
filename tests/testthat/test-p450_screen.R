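test_that("planted motifs are found at their positions", {
    # EALR at 0-based position 1; CLG in the C-terminal region
    s <- paste0("MEALR", rand_decoy(40), paste(rep("A", 20), collapse = ""), "CLG", "AA")
    hits <- scan_p450_motifs(s)
    expect_true(any(hits$motif_name == "EXXR" & hits$start == 1L &
                    hits$matched == "EALR"))
    expect_true(any(hits$motif_name == "CXG" & hits$matched == "CLG"))
})

test_that("sequences without motif letters yield no hits", {
    expect_equal(nrow(scan_p450_motifs(rand_decoy(200))), 0L)
})

test_that("overlapping EXXR occurrences are all reported", {
    # sliding-window oracle over every 4-mer
    set.seed(8)
    for (k in 1:20) {
        s <- rand_seq(80, c("E", "A", "R", "K"))
        hits <- scan_p450_motifs(s, screen_params(cxg_search_region = 1))
        exxr <- hits$start[hits$motif_name == "EXXR"]
        chars <- strsplit(s, "")[[1]]
        oracle <- which(chars[1:(length(chars) - 3)] == "E" &
                        chars[4:length(chars)] == "R") - 1L
        expect_equal(exxr, oracle)
        expect_false(is.unsorted(exxr))
    }
})

test_that("CXG is restricted to the configured C-terminal region", {
    # CIG early (position 5), none late: must not count
    s <- paste0("AAAA", "CIG", rand_decoy(393))
    hits <- scan_p450_motifs(s)
    expect_false(any(hits$motif_name == "CXG"))
    hits_all <- scan_p450_motifs(s, screen_params(cxg_search_region = 1))
    expect_true(any(hits_all$motif_name == "CXG"))
})

test_that("full-length calls need both motifs, order and length", {
    set.seed(31)
    ok <- planted_p450(400)
    call <- classify_p450(list(id = "x", sequence = ok))
    expect_equal(call$status, "full_length")
    expect_length(call$reasons, 0L)

    short <- substr(planted_p450(400), 1, 349)  # still has EALR, loses CIG
    call <- classify_p450(list(id = "x", sequence = short))
    expect_equal(call$status, "fragment")
    expect_true(any(grepl("length<350", call$reasons)))

    no_exxr <- paste0(rand_decoy(380), "CIG", rand_decoy(10))
    call <- classify_p450(list(id = "x", sequence = no_exxr))
    expect_equal(call$status, "fragment")
    expect_true("missing EXXR" %in% call$reasons)

    none <- rand_decoy(400)
    expect_equal(classify_p450(list(id = "x", sequence = none))$status, "not_p450")
    expect_equal(classify_p450(list(id = "x", sequence = none),
                               candidate = TRUE)$status, "fragment")
})

test_that("a 349-aa sequence with both motifs is a fragment by length alone", {
    set.seed(40)
    s <- planted_p450(349)
    call <- classify_p450(list(id = "x", sequence = s))
    expect_equal(call$status, "fragment")
    expect_equal(call$reasons, "length<350")
    expect_equal(classify_p450(list(id = "x", sequence = planted_p450(350)))$status,
                 "full_length")
})

test_that("motif order is enforced only when configured", {
    set.seed(41)
    # CIG before EALR, both in valid regions of a 400-aa sequence
    s <- strsplit(rand_decoy(400), "")[[1]]
    s[245:247] <- c("C", "I", "G")  # inside C-terminal 40%
    s[390:393] <- c("E", "A", "L", "R")
    s <- paste(s, collapse = "")
    expect_equal(classify_p450(list(id = "x", sequence = s))$status, "fragment")
    relaxed <- screen_params(require_order = FALSE)
    expect_equal(classify_p450(list(id = "x", sequence = s), relaxed)$status,
                 "full_length")
})

test_that("proteome screening counts planted composition exactly", {
    set.seed(12)
    recs <- protein_records(
        id = sprintf("r%02d", 1:17),
        sequence = c(replicate(10, planted_p450(sample(360:450, 1))),
                     replicate(2, substr(planted_p450(400), 1, 300)),
                     replicate(5, rand_decoy(sample(200:400, 1)))))
    sc <- screen_proteome(recs)
    expect_equal(unname(sc$summary), c(10L, 2L, 5L))
    expect_equal(sum(sc$summary), nrow(recs))
})

test_that("raising min_length never increases the full-length count", {
    set.seed(13)
    recs <- protein_records(
        id = sprintf("r%02d", 1:12),
        sequence = replicate(12, planted_p450(sample(300:500, 1))))
    cuts <- c(250L, 350L, 420L, 500L)
    n_full <- vapply(cuts, function(ml)
        unname(screen_proteome(recs, screen_params(min_length = ml))$summary["full_length"]),
        0L)
    expect_true(all(diff(n_full) <= 0L))
})
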