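test_that("align_pair computes identity and coverage as defined", {
  a <- "TGTGATGTGCATGTGGGCTTTC"                  # 22-mer
  al <- align_pair(a, a)
  expect_equal(al$identity, 1.0)
  expect_equal(al$coverage, 1.0)

  # one substitution mid-sequence: 21 matches over 22 columns
  b <- paste0(substr(a, 1, 10), "C", substr(a, 12, 22))
  expect_false(substr(a, 11, 11) == "C")
  al2 <- align_pair(a, b)
  expect_equal(al2$identity, 21 / 22)
  expect_equal(al2$coverage, 1.0)

  # a 19-mer exact substring of a 23-mer: shorter fully covered
  long <- "TTGTGATGTGCATGTGGGCTTTC"
  short <- substr(long, 3, 21)
  al3 <- align_pair(short, long)
  expect_equal(al3$identity, 1.0)
  expect_equal(al3$coverage, 1.0)

  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("align_pair is symmetric in identity and coverage", {
  withr::with_seed(7, {
    for (k in 1:10) {
      a <- random_dna(sample(19:30, 1)); b <- random_dna(sample(19:30, 1))
      ab <- align_pair(a, b); ba <- align_pair(b, a)
      expect_equal(ab$identity, ba$identity)
      expect_equal(ab$coverage, ba$coverage)
    }
  })
})

test_that("cluster_reads is single-linkage over the identity/coverage thresholds", {
  # A~B and B~C pass, A vs C alone would fail -> one cluster by transitivity
  core <- "ACGTTGCAGGTCAATCGGTACGTCAGT"          # 27 nt
  A <- substr(core, 1, 21)
  B <- substr(core, 4, 24)
  C <- substr(core, 7, 27)
  expect_gte(align_pair(A, B)$coverage, 0.8)
  expect_lt(align_pair(A, C)$coverage, 0.8)
  rs <- read_set(c("A", "B", "C"), c(A, B, C),
                 matrix(c(10, 5, 1), ncol = 1, dimnames = list(NULL, "L1")))
  cl <- cluster_reads(rs)
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters[[1]]$members, c("A", "B", "C"))
  expect_equal(cl$clusters[[1]]$representative, "A")

  # two dissimilar reads -> two singletons
  withr::with_seed(11, rs2 <- read_set(c("x", "y"),
                                       c(random_dna(22), random_dna(22)),
                                       matrix(c(1, 1), ncol = 1,
                                              dimnames = list(NULL, "L1"))))
  cl2 <- cluster_reads(rs2)
  expect_length(cl2$clusters, 2)
})

test_that("clustering equals the brute-force all-pairs oracle and ignores input order", {
  reads <- make_variant_reads(n_cores = 8, n_variants = 12, seed = 5)
  expect_gte(nrow(reads), 50)
  oracle <- brute_force_partition(reads)
  cl <- cluster_reads(reads)
  mine <- setNames(cl$membership$cluster_id, cl$membership$member_id)
  expect_equal(partition_signature(mine[reads$id], reads$id),
               partition_signature(oracle, reads$id))
  # partition property: disjoint cover
  expect_setequal(cl$membership$member_id, reads$id)
  expect_equal(anyDuplicated(cl$membership$member_id), 0L)

  # permuting the input yields the same partition
  perm <- withr::with_seed(9, sample(nrow(reads)))
  reads_p <- as_read_set_for_test(as.data.frame(reads)[perm, ], "L1")
  cl_p <- cluster_reads(reads_p)
  mine_p <- setNames(cl_p$membership$cluster_id, cl_p$membership$member_id)
  expect_equal(partition_signature(mine_p[reads$id], reads$id),
               partition_signature(mine[reads$id], reads$id))
})

test_that("cluster representatives carry summed counts and break ties lexicographically", {
  rs <- read_set(c("a", "b"),
                 c("CCGTACGTACGTACGTACGTAC", "ACGTACGTACGTACGTACGTAC"),
                 matrix(c(5, 5), ncol = 1, dimnames = list(NULL, "L1")))
  cl <- cluster_reads(rs)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$representative_sequence,
               "ACGTACGTACGTACGTACGTAC")        # tie -> smaller sequence
  reps <- cluster_representatives(cl)
  expect_equal(total_counts(reps), 10)
})
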