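test_that("candidate mapping reports exact placements on both strands", {
  withr::with_seed(41, {
    cand <- random_dna(22)
    contig <- paste0(random_dna(30), cand, random_dna(30))
    contig2 <- paste0(random_dna(10),
                      as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(cand))), random_dna(10))
    cands <- data.frame(id = "c1", sequence = cand)
    contigs <- data.frame(id = c("t1", "t2", "t3"),
                          sequence = c(contig, contig2, random_dna(80)))
    hits <- map_candidates_to_contigs(cands, contigs)
    expect_equal(nrow(hits), 2)
    h1 <- hits[hits$contig_id == "t1", ]
    expect_equal(c(h1$start, h1$end, h1$strand), c("30", "52", "+"))
    h2 <- hits[hits$contig_id == "t2", ]
    expect_equal(c(h2$start, h2$end, h2$strand), c("10", "32", "-"))
  })
})

test_that("mapping is strand-consistent under reverse complement of the contig", {
  withr::with_seed(42, {
    cand <- random_dna(22)
    contig <- paste0(random_dna(25), cand, random_dna(15))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(contig)))
    cands <- data.frame(id = "c1", sequence = cand)
    fwd <- map_candidates_to_contigs(cands, data.frame(id = "t", sequence = contig))
    rev <- map_candidates_to_contigs(cands, data.frame(id = "t", sequence = rc))
    expect_equal(fwd$strand, "+"); expect_equal(rev$strand, "-")
    L <- nchar(contig)
    expect_equal(rev$start, L - fwd$end)         # mirrored interval
    expect_equal(rev$end, L - fwd$start)
  })
})

test_that("precursor screen demands two distinct, non-overlapping candidates", {
  base <- data.frame(contig_id = "t", identity = 1, strand = "+")
  pass <- rbind(cbind(base, candidate_id = "a", start = 5, end = 27),
                cbind(base, candidate_id = "b", start = 40, end = 62))
  expect_equal(screen_precursor_contigs(pass), "t")
  overlap <- rbind(cbind(base, candidate_id = "a", start = 5, end = 27),
                   cbind(base, candidate_id = "b", start = 26, end = 48))
  expect_length(screen_precursor_contigs(overlap), 0)
  same <- rbind(cbind(base, candidate_id = "a", start = 5, end = 27),
                cbind(base, candidate_id = "a", start = 40, end = 62))
  expect_length(screen_precursor_contigs(same), 0)
})

test_that("duplex calling requires opposite arms and inter-arm pairing", {
  withr::with_seed(43, {
    arm <- random_dna(22)
    star <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
    contig <- paste0(random_dna(12), arm, random_dna(9), star, random_dna(12))
    f <- fold_hairpin(contig)
    hits <- data.frame(candidate_id = c("m", "s"), contig_id = "t",
                       start = c(12, 43), end = c(34, 65),
                       strand = "+", identity = 1)
    call <- call_duplex(f, hits)
    expect_equal(call$verdict, "duplex")
    expect_gte(call$n_pairs_between, 0.6 * 22)

    # both hits on the 5' arm -> rejected
    same_arm <- data.frame(candidate_id = c("m", "s"), contig_id = "t",
                           start = c(12, 13), end = c(30, 34),
                           strand = "+", identity = 1)
    expect_equal(call_duplex(f, same_arm)$verdict, "rejected")

    # opposite arms but hardly any pairing between the two hit intervals:
    # a second, unrelated hairpin on the same contig
    arm2 <- random_dna(22)
    star2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm2)))
    contig2 <- paste0(arm, random_dna(6), star, arm2, random_dna(6), star2)
    f2 <- fold_hairpin(contig2, max_len = 200)
    # hits: the first hairpin's mature and the second hairpin's star
    hits2 <- data.frame(candidate_id = c("m", "x"), contig_id = "t",
                        start = c(0, 78), end = c(22, 100),
                        strand = "+", identity = 1)
    c2 <- call_duplex(f2, hits2)
    expect_equal(c2$verdict, "rejected")
  })
})

test_that("find_precursors recovers a planted duplex end to end", {
  withr::with_seed(44, {
    arm <- random_dna(22)
    star <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
    contig <- paste0(random_dna(15), arm, random_dna(10), star, random_dna(15))
    cands <- data.frame(id = c("mat", "str", "junk"),
                        sequence = c(arm, star, random_dna(22)))
    contigs <- data.frame(id = "t1", sequence = contig)
    res <- find_precursors(cands, contigs)
    expect_equal(res$screened, "t1")
    expect_equal(res$duplexes$verdict, "duplex")
    expect_setequal(c(res$duplexes$mirna_id, res$duplexes$star_id),
                    c("mat", "str"))
  })
})

test_that("short contigs are skipped with a warning on read", {
  fa <- tempfile(fileext = ".fa")
  write_fasta(c("long", "short"), c(random_dna(60), random_dna(30)), fa)
  expect_warning(ct <- read_contigs(fa), "shorter")
  expect_equal(ct$id, "long")
})
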