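test_that("shannon_index matches closed forms and vegan", {
  expect_equal(shannon_index(c(10, 10, 10, 10))$H_prime, log(4))
  expect_equal(shannon_index(42)$H_prime, 0)
  expect_equal(shannon_index(c(3, 1))$H_prime,
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_error(shannon_index(c(0, 0)), "positive")

  skip_if_not_installed("vegan")
  withr::with_seed(51, {
    for (k in 1:5) {
      counts <- sample(1:1000, sample(3:20, 1))
      expect_equal(shannon_index(counts)$H_prime,
                   unname(vegan::diversity(counts, index = "shannon")),
                   tolerance = 1e-12)
    }
  })
})

test_that("shannon_index is permutation-invariant and maximal at uniformity", {
  withr::with_seed(52, {
    counts <- sample(1:500, 12)
    expect_equal(shannon_index(counts)$H_prime,
                 shannon_index(sample(counts))$H_prime)
    expect_lte(shannon_index(counts)$H_prime, log(12))
  })
})

test_that("reads-qPCR correlation matches the textbook two-pass formula", {
  pairs <- data.frame(reads = c(200, 400, 900, 1500, 5000),
                      qpcr = c(200, 400, 900, 1500, 5000))
  expect_equal(correlate_reads_qpcr(pairs)$R, 1)

  p2 <- data.frame(reads = c(101, 102, 103), qpcr = c(1, 2, 4))
  ct <- correlate_reads_qpcr(p2)
  # closed form for x = 1,2,3 / y = 1,2,4
  expect_equal(ct$R, 3 / sqrt(2 * 4.666667), tolerance = 1e-6)

  withr::with_seed(53, {
    x <- runif(20, 101, 1e5); y <- 2 * x + rnorm(20, 0, 1000)
    ct2 <- correlate_reads_qpcr(data.frame(reads = x, qpcr = y))
    n <- 20
    mx <- mean(x); my <- mean(y)
    r2pass <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(ct2$R, r2pass, tolerance = 1e-12)
    tt <- r2pass * sqrt((n - 2) / (1 - r2pass^2))
    expect_equal(ct2$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
  })
})

test_that("the 'more than 100 reads' filter is strict at the boundary", {
  pairs <- data.frame(reads = c(100, 101, 500, 1000, 2000),
                      qpcr = c(1, 2, 3, 4, 5))
  ct <- correlate_reads_qpcr(pairs)
  expect_equal(ct$n_used, 4)                     # 100 excluded, 101 included
  expect_error(correlate_reads_qpcr(pairs[1:3, ]), "fewer than 3")
  flat <- data.frame(reads = c(101, 102, 103), qpcr = c(2, 2, 2))
  expect_error(correlate_reads_qpcr(flat), "zero variance")
})

test_that("rest_ratio_test recovers the efficiency-corrected ratio", {
  # treated target 2 cycles above control, reference unchanged, E = 2
  et <- rest_ratio_test(list(control = c(20, 20, 20), treated = c(22, 22, 22)),
                        list(control = c(15, 15, 15), treated = c(15, 15, 15)))
  expect_equal(et$ratio, 0.25)
  expect_true(et$exhaustive)

  # identical groups: ratio 1, p ~ 1
  et2 <- rest_ratio_test(list(control = c(20, 21, 20), treated = c(20, 21, 20)),
                         list(control = c(15, 15, 16), treated = c(15, 15, 16)))
  expect_equal(et2$ratio, 1)
  expect_gte(et2$p_value, 0.9)

  expect_error(rest_ratio_test(list(control = 1:3, treated = 1:3),
                               list(control = 1:3, treated = 1:3),
                               E_target = 2.5), "efficiency")
})

test_that("sampled reallocations agree with exhaustive enumeration", {
  withr::with_seed(54, {
    tc <- rnorm(8, 20); tt <- rnorm(8, 21)
    rc <- rnorm(8, 15); rt <- rnorm(8, 15)
    target <- list(control = tc, treated = tt)
    ref <- list(control = rc, treated = rt)
    ex <- rest_ratio_test(target, ref, n_randomizations = 2e4) # 12870 exact
    expect_true(ex$exhaustive)
    sm <- rest_ratio_test(target, ref, n_randomizations = 4000, seed = 2)
    expect_false(sm$exhaustive)
    mcse <- sqrt(ex$p_value * (1 - ex$p_value) / 4000)
    expect_lt(abs(sm$p_value - ex$p_value), 3 * mcse + 1e-9)
    expect_equal(sm$ratio, ex$ratio)
  })
})

test_that("compare_libraries reports per-library fractions summing to one", {
  cm <- matrix(c(70, 10, 20, 80, 0, 20), ncol = 2,
               dimnames = list(NULL, c("WB", "Ov")))
  tab <- candidate_table(c("a", "b", "c"),
                         c("ACGTACGTACGTACGTACGTAC",
                           "CCGTACGTACGTACGTACGTAC",
                           "GCGTACGTACGTACGTACGTAC"),
                         c("known", "specific_candidate", "contaminant"),
                         c("c1", "c2", "c3"), cm)
  comp <- compare_libraries(tab)
  expect_equal(comp$fractions["known miRNA", "WB"], 0.7)
  expect_equal(comp$fractions["specific candidate", "WB"], 0.1)
  expect_equal(comp$fractions["other small RNAs", "WB"], 0.2)
  expect_equal(colSums(comp$fractions), c(WB = 1, Ov = 1))
  expect_error(compare_libraries(tab, libraries = "WB"), "at least 2")
})

test_that("qpcr_abundance inverts the simulated Ct model exactly at zero noise", {
  ab <- c(g1 = 200, g2 = 2000, g3 = 40000)
  qt <- simulate_qpcr(ab, noise_sd = 0, seed = 3)
  qa <- qpcr_abundance(qt)
  # copies per 1000 U6 with U6 fixed at 1e5: 1000 * ab / 1e5
  expect_equal(setNames(qa$qpcr, qa$gene), 1000 * ab / 1e5, tolerance = 1e-9)
  pairs <- data.frame(reads = ab[qa$gene], qpcr = qa$qpcr)
  expect_equal(correlate_reads_qpcr(pairs, min_reads = 1)$R, 1, tolerance = 1e-9)
})
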