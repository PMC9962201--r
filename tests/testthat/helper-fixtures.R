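# shared fixture builders; everything is generated in code, no data files

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

rand_seq <- function(n, alphabet = AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a sequence guaranteed to pass the P450 screen (EALR then CIG, >= 350 aa)
planted_p450 <- function(len = 400L) {
    s <- strsplit(rand_seq(len), "")[[1]]
    e_at <- round(0.3 * len); c_at <- round(0.9 * len)
    s[e_at:(e_at + 3)] <- c("E", "A", "L", "R")
    s[c_at:(c_at + 2)] <- c("C", "I", "G")
    paste(s, collapse = "")
}

# motif-free background (no R -> no EXXR, no G -> no CXG, no C -> no Fe-S)
rand_decoy <- function(n) rand_seq(n, setdiff(AA20, c("C", "R", "G")))

# Rand index between two partitions given as membership vectors
rand_index <- function(a, b) {
    stopifnot(length(a) == length(b))
    n <- length(a)
    same_a <- outer(a, a, "==")[upper.tri(diag(n))]
    same_b <- outer(b, b, "==")[upper.tri(diag(n))]
    mean(same_a == same_b)
}

# build a gene feature table from per-replicon gap/length/strand vectors
layout_features <- function(replicon, lengths, gaps, strands) {
    start <- integer(length(lengths))
    pos <- 1L
    for (i in seq_along(lengths)) {
        if (i > 1L) pos <- pos + gaps[i - 1L]
        start[i] <- pos
        pos <- pos + lengths[i]
    }
    gene_features(gene_id = sprintf("%s_g%02d", replicon, seq_along(lengths)),
                  protein_id = sprintf("%s_p%02d", replicon, seq_along(lengths)),
                  replicon_id = replicon, start = start,
                  end = start + lengths - 1L, strand = strands)
}
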