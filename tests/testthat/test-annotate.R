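test_that("build_pssm follows the log-odds formula with pseudocount 0.25", {
  p <- build_pssm(c("AAC", "AAC", "CAC"), "f")
  # column 1 has bases {A, A, C}: score(A) = log2((2.25/4)/0.25) = log2(2.25)
  expect_equal(unname(p$matrix[1, "A"]), log2(2.25))
  expect_equal(unname(p$matrix[1, "C"]), log2((1.25 / 4) / 0.25))
  expect_equal(unname(p$matrix[1, "G"]), log2((0.25 / 4) / 0.25))
  expect_equal(p$consensus, "AAC")

  single <- build_pssm("TGAGGTAGTAGGTTGTATAGT", "let7-like")
  expect_equal(single$consensus, "TGAGGTAGTAGGTTGTATAGT")

  expect_error(build_pssm(character(), "empty"), "empty family")
  expect_error(build_pssm(c("ACGT", "ACG"), "ragged"), "ragged")
})

test_that("scan_profiles labels by identity with offset scanning", {
  withr::with_seed(21, {
    cons1 <- random_dna(22); cons2 <- random_dna(22)
  })
  profiles <- build_pssm_set(list(famA = cons1, famB = cons2))

  mismatch3 <- paste0(substr(cons1, 1, 19),
                      chartr("ACGT", "GTAC", substr(cons1, 20, 22)))
  shifted <- paste0(substr(cons1, 3, 22), "A")   # 2-nt 5' shift + untemplated A
  rs <- read_set(c("exact", "mm3", "shifted"),
                 c(cons1, mismatch3, shifted),
                 matrix(c(1, 1, 1), ncol = 1, dimnames = list(NULL, "L1")))
  ann <- scan_profiles(rs, profiles)
  expect_equal(ann$category[1], "known:famA")
  expect_equal(ann$identity[1], 1.0)
  expect_equal(ann$category[2], "unassigned")    # 19/22 < 0.90
  expect_equal(ann$category[3], "known:famA")    # offset scan absorbs the shift
  expect_equal(ann$identity[3], 1.0)             # untemplated A not compared
})

test_that("scan_profiles at identity 1.0 equals an exact window-match oracle", {
  withr::with_seed(22, {
    consensi <- vapply(1:5, function(i) random_dna(22), "")
    profiles <- build_pssm_set(setNames(as.list(consensi), paste0("f", 1:5)))
    reads <- c(consensi[2],                         # exact
               substr(consensi[3], 2, 22),          # exact sub-window
               vapply(1:10, function(i) random_dna(22), ""))
    rs <- read_set(paste0("r", seq_along(reads)), reads,
                   matrix(rep(1, length(reads)), ncol = 1,
                          dimnames = list(NULL, "L1")))
    ann <- scan_profiles(rs, profiles, min_identity = 1.0)
    oracle <- vapply(reads, function(rd) {
      any(vapply(consensi, function(cs) {
        hit <- FALSE
        for (o in -3:3) {
          k <- seq_len(nchar(rd)); pos <- k + o
          keep <- pos >= 1 & pos <= nchar(cs)
          if (sum(keep) < 16) next
          if (all(substring(rd, k[keep], k[keep]) ==
                  substring(cs, pos[keep], pos[keep]))) hit <- TRUE
        }
        hit
      }, TRUE))
    }, TRUE, USE.NAMES = FALSE)
    expect_equal(ann$category != "unassigned", oracle)
  })
})

test_that("mask_mature masks the interval, is idempotent, and validates input", {
  hp <- strrep("ACGT", 20)
  refs <- reference_set("hairpin", "h1", hp,
                        mature_coords = data.frame(hairpin_id = "h1",
                                                   start = 10, end = 32))
  mh <- mask_mature(refs)
  expect_equal(nchar(mh$h1$sequence), 80)
  expect_equal(substr(mh$h1$sequence, 11, 32), strrep("N", 22))
  expect_false(grepl("N", substr(mh$h1$sequence, 1, 10)))
  # idempotence: masking the masked sequence changes nothing
  refs2 <- reference_set("hairpin", "h1", mh$h1$sequence,
                         mature_coords = data.frame(hairpin_id = "h1",
                                                    start = 10, end = 32))
  expect_equal(mask_mature(refs2)$h1$sequence, mh$h1$sequence)

  full <- reference_set("hairpin", "h2", hp,
                        mature_coords = data.frame(hairpin_id = "h2",
                                                   start = 0, end = 80))
  expect_warning(mask_mature(full), "fully masked")
  expect_error(mask_mature(reference_set("hairpin", "h3", hp)), "mature_coords")
})

test_that("scan_star finds star reads only in the unmasked hairpin portion", {
  withr::with_seed(23, {
    mature <- random_dna(22)
    loop <- random_dna(10)
    star <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mature)))
    hp <- paste0("ACGTA", mature, loop, star, "TCGAT")
    refs <- reference_set("hairpin", "h1", hp,
                          mature_coords = data.frame(hairpin_id = "h1",
                                                     start = 5, end = 27))
    masked <- mask_mature(refs)
    inside_mask <- substr(hp, 8, 27)             # fully inside the mature
    straddle <- substr(hp, 17, 38)               # half mask, half loop/star
    rs <- read_set(c("star", "masked", "straddle"),
                   c(star, inside_mask, straddle),
                   matrix(c(1, 1, 1), ncol = 1, dimnames = list(NULL, "L1")))
    ann <- scan_star(rs, masked)
    expect_equal(ann$category[1], "star:h1")
    expect_equal(ann$category[2], "unassigned")  # N matches nothing
    expect_equal(ann$category[3], "unassigned")  # ~50% N columns
  })
})

test_that("contaminant annotation is exact-match with fixed precedence", {
  withr::with_seed(24, {
    rrna <- random_dna(300)
    endo <- random_dna(1000)
    shared <- random_dna(22)
    refs <- list(
      rRNA = reference_set("rRNA", "r1", paste0(rrna, shared)),
      endosymbiont = reference_set("endosymbiont", "e1", paste0(endo, shared)))
    exact <- substr(endo, 100, 121)
    mm <- paste0(substr(exact, 1, 10), "A", substr(exact, 12, 22))
    if (substr(exact, 11, 11) == "A") mm <- paste0(substr(exact, 1, 10), "C",
                                                   substr(exact, 12, 22))
    rs <- read_set(c("endo", "both", "mm"),
                   c(exact, shared, mm),
                   matrix(c(1, 1, 1), ncol = 1, dimnames = list(NULL, "L1")))
    ann <- annotate_contaminants(rs, refs)
    expect_equal(ann$category[1], "endosymbiont")
    expect_equal(ann$category[2], "rRNA")        # precedence over endosymbiont
    expect_equal(ann$category[3], "unassigned")  # 1 mismatch fails identity 1.0
  })
})

test_that("annotate_reads gives every read exactly one category", {
  withr::with_seed(25, {
    cons <- random_dna(22)
    profiles <- build_pssm_set(list(famA = cons))
    refs <- list(rRNA = reference_set("rRNA", "r1", random_dna(200)))
    rs <- read_set(c("known", "junk", "artefact"),
                   c(cons, random_dna(22),
                     paste0(random_dna(26), strrep("T", 10))),
                   matrix(c(10, 10, 1), ncol = 1, dimnames = list(NULL, "L1")))
    ann <- annotate_reads(rs, refs, profiles, NULL)
    expect_equal(ann$category,
                 c("known:famA", "unassigned", "artefact"))
    expect_equal(anyDuplicated(ann$id), 0L)
  })
})
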